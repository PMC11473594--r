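#' Cluster-value update for a single ablated probe
#'
#' Given precomputed per-cluster sums and availability counts, returns the
#' updated cluster value after ablating one probe. Mode `"zero"` sets the
#' probe's beta to zero but keeps it in the denominator
#' (`(sum - beta) / count`); mode `"remove"` drops it from the average
#' (`(sum - beta) / (count - 1)`, or 0 when the cluster empties). Only the
#' probe's own cluster changes; samples where the probe is missing are
#' unaffected.
#'
#' @param sums,counts per-sample vectors of the probe's cluster sum and
#'   availability count.
#' @param beta_p per-sample beta values of the probe (`NA` where missing).
#' @param mode `"zero"` or `"remove"`.
#' @return per-sample updated cluster values.
#' @export
ablate_cluster_update <- function(sums, counts, beta_p, mode = c("zero", "remove")) {
  mode <- match.arg(mode)
  avail <- !is.na(beta_p)
  b <- ifelse(avail, beta_p, 0)
  new_sum <- sums - b
  new_cnt <- counts - as.numeric(avail) * (mode == "remove")
  old <- ifelse(counts > 0, sums / counts, 0)
  new <- ifelse(new_cnt > 0, new_sum / new_cnt, 0)
  ifelse(avail, new, old)
}

#' Set-to-zero ablation scan of every clock CpG
#'
#' Quantifies each clock CpG's contribution to the mortality association: for
#' every CpG shared between the clock and the beta matrix, the CpG is ablated
#' (set to zero by default, or removed), predictions are recomputed through an
#' incremental cluster-average update, deltas are re-standardized (by default
#' with the ablated predictions' own SD), the full Cox model is refit with
#' the updated standardized delta, and the FDR q-value of the standardized
#' delta term is recorded. The impact of a CpG is the fold change
#' `ablated_q / base_q`; CpGs whose removal makes the association less
#' significant (impact > 1) are mortality CpGs, those making it more
#' significant are anti-mortality CpGs.
#'
#' The incremental update is exact: it reproduces a naive full recomputation
#' of cluster values, predictions, standardized deltas and Cox q-values. The
#' per-probe refits are independent, so results are merged deterministically
#' by probe id and the scan is reproducible bit-for-bit.
#'
#' @param beta samples x probes matrix (aligned with `table` rows).
#' @param clock a [clock_definition].
#' @param table cohort data frame with `surv_age`, `status` and the model
#'   covariates (everything in `terms` except `s_delta`, which the scan
#'   computes).
#' @param mode `"zero"` (beta zeroed, denominator unchanged; default) or
#'   `"remove"` (probe dropped from the average).
#' @param freeze_sd if `TRUE`, standardize ablated deltas with the base
#'   model's delta SD instead of recomputing it per ablation.
#' @param terms model terms; must start with `"s_delta"`.
#' @param annotation optional data frame `probe_id`, `gene` mapping probes to
#'   gene symbols.
#' @param ties tie handling passed to the Cox fits.
#' @return an `ablation_scan` object: `records` (one [data.frame] row per
#'   CpG: `rank`, `probe_id`, `cluster_id`, `ablated_q`, `impact`,
#'   `log10_impact`, `class`, `gene`, `failed`, sorted by descending impact),
#'   `base_q`, `base_fit`, `mode`, `freeze_sd`.
#' @export
ablation_scan <- function(beta, clock, table,
                          mode = c("zero", "remove"), freeze_sd = FALSE,
                          terms = c("s_delta", "N", "L", "M", "NI",
                                    "Sex", "Age", "Cohort", "Timepoint"),
                          annotation = NULL, ties = c("efron", "breslow")) {
  mode <- match.arg(mode)
  ties <- match.arg(ties)
  if (!identical(terms[1], "s_delta")) stop("terms must start with 's_delta'")
  if (nrow(beta) != nrow(table)) stop("beta and cohort table row mismatch")
  validate_beta(beta)

  st <- clock_state(beta, clock)
  w <- clock$cluster_weights
  vals <- st$sums / st$counts
  vals[st$counts == 0] <- 0
  pred0 <- drop(vals %*% w) + clock$intercept
  age <- table$Age
  if (is.null(age)) stop("cohort table lacks 'Age'")
  delta0 <- pred0 - age
  sd0 <- stats::sd(delta0)
  if (!is.finite(sd0) || sd0 == 0) stop("zero variance in base deltas")

  tab <- table
  tab$s_delta <- delta0 / sd0
  base_fit <- fit_cox(tab, terms = terms, ties = ties)
  X <- base_fit$X
  y <- base_fit$y
  ctrl <- survival::coxph.control()
  # base q recomputed through the identical refit path the scan uses, so a
  # no-op ablation (unmeasured probe) reproduces it bit for bit
  refit_q <- function(X) {
    f <- survival::coxph.fit(X, y, strata = NULL, offset = NULL,
                             init = NULL, control = ctrl, weights = NULL,
                             method = ties, rownames = NULL)
    p <- 2 * stats::pnorm(-abs(f$coefficients / sqrt(diag(f$var))))
    unname(stats::p.adjust(p, method = "fdr")[1])
  }
  base_q <- refit_q(X)

  probes <- st$probes
  cl_idx <- match(clock$cluster_of[probes], st$clusters)
  rec_q <- numeric(length(probes))
  failed <- logical(length(probes))

  for (j in seq_along(probes)) {
    ci <- cl_idx[j]
    bp <- st$beta[, j]                      # zeros already where missing
    av <- st$avail[, j]
    cnt <- st$counts[, ci]
    sm <- st$sums[, ci]
    old_val <- vals[, ci]
    if (mode == "zero") {
      new_val <- ifelse(av, (sm - bp) / cnt, old_val)
    } else {
      nc <- cnt - av
      new_val <- ifelse(av, ifelse(nc > 0, (sm - bp) / nc, 0), old_val)
    }
    dpred <- w[ci] * (new_val - old_val)
    delta <- delta0 + dpred
    sdl <- if (freeze_sd) sd0 else stats::sd(delta)
    if (!is.finite(sdl) || sdl == 0) {
      failed[j] <- TRUE
      rec_q[j] <- NA_real_
      next
    }
    X[, 1] <- delta / sdl
    f <- tryCatch(
      suppressWarnings(
        survival::coxph.fit(X, y, strata = NULL, offset = NULL,
                            init = NULL, control = ctrl, weights = NULL,
                            method = ties, rownames = NULL)),
      error = function(e) NULL)
    if (is.null(f) || anyNA(f$coefficients) || f$iter >= ctrl$iter.max) {
      failed[j] <- TRUE
      rec_q[j] <- NA_real_
      next
    }
    se <- sqrt(diag(f$var))
    p <- 2 * stats::pnorm(-abs(f$coefficients / se))
    rec_q[j] <- stats::p.adjust(p, method = "fdr")[1]
  }
  if (any(failed)) {
    warning(sum(failed), " probe refit(s) failed; recorded as failed")
  }

  records <- data.frame(probe_id = probes,
                        cluster_id = unname(clock$cluster_of[probes]),
                        ablated_q = rec_q,
                        impact = rec_q / base_q,
                        log10_impact = log10(rec_q / base_q),
                        failed = failed,
                        row.names = NULL)
  records <- classify(records, base_q)
  if (!is.null(annotation)) {
    records$gene <- annotation$gene[match(records$probe_id, annotation$probe_id)]
  } else {
    records$gene <- NA_character_
  }
  ord <- order(-records$impact, records$probe_id)
  records <- records[ord, , drop = FALSE]
  records$rank <- seq_len(nrow(records))
  rownames(records) <- NULL
  records <- records[, c("rank", "probe_id", "cluster_id", "ablated_q",
                         "impact", "log10_impact", "class", "gene", "failed")]
  structure(list(records = records, base_q = base_q, base_fit = base_fit,
                 mode = mode, freeze_sd = freeze_sd),
            class = "ablation_scan")
}

#' @export
print.ablation_scan <- function(x, ...) {
  r <- x$records
  cat(sprintf("Ablation scan (mode '%s'): %d CpGs, base q = %.3g\n",
              x$mode, nrow(r), x$base_q))
  cat(sprintf("  mortality: %d, anti-mortality: %d, neutral: %d, failed: %d\n",
              sum(r$class == "mortality"), sum(r$class == "anti-mortality"),
              sum(r$class == "neutral"), sum(r$failed)))
  cat("Top CpGs by impact:\n")
  print(utils::head(r[, c("rank", "probe_id", "ablated_q", "impact", "class", "gene")], 5),
        row.names = FALSE)
  invisible(x)
}

#' @export
summary.ablation_scan <- function(object, ...) object$records

#' Classify CpGs as mortality / anti-mortality / neutral
#'
#' A CpG whose ablation raises the FDR of the standardized-delta term
#' (makes the mortality association less significant) drove the association:
#' a mortality CpG. One whose ablation lowers the FDR is anti-mortality;
#' an exactly unchanged FDR is neutral.
#'
#' @param records data frame with an `ablated_q` column.
#' @param base_q FDR of the standardized-delta term in the full model.
#' @return `records` with a `class` column added.
#' @export
classify <- function(records, base_q) {
  records$class <- ifelse(is.na(records$ablated_q), NA_character_,
                   ifelse(records$ablated_q > base_q, "mortality",
                   ifelse(records$ablated_q < base_q, "anti-mortality", "neutral")))
  records
}

#' Top annotated genes of a CpG class
#'
#' Walks the classified, impact-sorted records of one class (mortality:
#' descending impact; anti-mortality: ascending), keeps the first `k` records
#' that carry a gene annotation, and returns the unique gene symbols in that
#' order. Unannotated CpGs are skipped, not counted.
#'
#' @param scan an `ablation_scan` (or its `records` data frame, already
#'   carrying `gene`).
#' @param k number of annotated records to take (default 250).
#' @param class `"mortality"` or `"anti-mortality"`.
#' @return character vector of unique gene symbols, impact order preserved.
#' @export
top_annotated <- function(scan, k = 250, class = c("mortality", "anti-mortality")) {
  class <- match.arg(class)
  records <- if (inherits(scan, "ablation_scan")) scan$records else scan
  r <- records[!is.na(records$class) & records$class == class, , drop = FALSE]
  ord <- if (class == "mortality") order(-r$impact, r$probe_id)
         else order(r$impact, r$probe_id)
  r <- r[ord, , drop = FALSE]
  r <- r[!is.na(r$gene) & r$gene != "" & r$gene != "N/A", , drop = FALSE]
  if (nrow(r) < k) {
    warning("only ", nrow(r), " annotated ", class, " CpGs available (k = ", k, ")")
  }
  unique(r$gene[seq_len(min(k, nrow(r)))])
}

#' Hypergeometric over-representation analysis
#'
#' One-sided hypergeometric tail test `P(X >= overlap)` of a gene list
#' against each gene set, with BH adjustment across sets. Gene sets are
#' intersected with the universe; the list must be a subset of the universe.
#'
#' @param gene_list character vector of genes of interest.
#' @param gene_sets named list of character vectors (e.g. from [read_gmt()]).
#' @param universe character vector of all eligible genes.
#' @param q_threshold sets at or below this BH q are flagged (default 0.05).
#' @return data frame `set`, `overlap`, `set_size`, `list_size`,
#'   `universe_size`, `p`, `q`, `significant`, ordered by p.
#' @export
ora <- function(gene_list, gene_sets, universe, q_threshold = 0.05) {
  universe <- unique(universe)
  gene_list <- unique(gene_list)
  if (length(universe) == 0L) stop("empty universe")
  if (length(gene_list) == 0L) stop("empty gene list")
  if (!all(gene_list %in% universe)) stop("gene list must be a subset of the universe")
  res <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    ov <- length(intersect(gene_list, set))
    # P(X >= ov), X ~ Hypergeom(set_size successes, rest, draws = |list|)
    p <- stats::phyper(ov - 1, length(set), length(universe) - length(set),
                       length(gene_list), lower.tail = FALSE)
    data.frame(set = nm, overlap = ov, set_size = length(set),
               list_size = length(gene_list), universe_size = length(universe),
               p = p)
  })
  out <- do.call(rbind, res)
  out$q <- adjust_fdr(out$p)
  out$significant <- out$q <= q_threshold
  out[order(out$p, out$set), , drop = FALSE]
}

#' Read / write GMT gene-set files
#'
#' GMT: one set per line, tab-separated `name<TAB>description<TAB>gene...`.
#'
#' @param path file path.
#' @return named list of character gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(l, 1, 40))
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' @rdname read_gmt
#' @param gene_sets named list of character vectors.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, "na", gene_sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
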
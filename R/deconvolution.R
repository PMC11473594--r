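#' Reference-based cell-type deconvolution by simplex-constrained least squares
#'
#' Each sample's methylation profile over the reference probes is modeled as a
#' convex mixture of cell-type signatures: fractions minimize the squared
#' residual subject to nonnegativity and sum-to-one. The solver is an exact
#' exhaustive active-set method: for every candidate set of cell types allowed
#' to be nonzero it solves the equality-constrained least-squares KKT system
#' and keeps the feasible solution with the smallest residual (ties broken by
#' minimum norm). With the handful of cell types a methylation reference
#' carries this is exact to solver tolerance, not approximate.
#'
#' @param beta samples x probes matrix (values in `[0,1]`, `NA` allowed; a
#'   sample's missing probes are dropped from its fit).
#' @param reference probes x cell-types numeric matrix of mean beta
#'   signatures, values in `[0,1]`.
#' @return samples x cell-types matrix of fractions (rows on the simplex).
#' @export
estimate_fractions <- function(beta, reference) {
  if (!is.matrix(reference) || is.null(colnames(reference)) || is.null(rownames(reference))) {
    stop("reference must be a probes x cell-types matrix with dimnames")
  }
  if (ncol(reference) < 2L) stop("reference needs >=2 cell types")
  shared <- intersect(colnames(beta), rownames(reference))
  if (length(shared) == 0L) stop("no shared probes between beta and reference")
  A_full <- reference[shared, , drop = FALSE]
  if (qr(A_full)$rank < ncol(A_full)) stop("reference cell-type signatures are collinear")
  B <- beta[, shared, drop = FALSE]
  out <- matrix(NA_real_, nrow(B), ncol(A_full),
                dimnames = list(rownames(B), colnames(A_full)))
  for (i in seq_len(nrow(B))) {
    ok <- !is.na(B[i, ])
    if (!any(ok)) stop("sample '", rownames(B)[i], "' has no available reference probes")
    out[i, ] <- solve_simplex_ls(A_full[ok, , drop = FALSE], B[i, ok])
  }
  out
}

# Exact simplex-constrained LS: min ||A x - b||^2  s.t.  x >= 0, sum(x) = 1.
# Enumerates free-coordinate sets; each candidate solves the KKT system of
# the equality-constrained problem restricted to the free set.
solve_simplex_ls <- function(A, b, tol = 1e-8) {
  k <- ncol(A)
  AtA <- crossprod(A)
  Atb <- crossprod(A, b)
  best <- NULL
  best_obj <- Inf
  best_norm <- Inf
  for (code in seq_len(2^k - 1L)) {
    free <- which(bitwAnd(code, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
    m <- length(free)
    kkt <- rbind(cbind(2 * AtA[free, free, drop = FALSE], rep(1, m)),
                 c(rep(1, m), 0))
    rhs <- c(2 * Atb[free], 1)
    sol <- tryCatch(solve(kkt, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    x_free <- sol[seq_len(m)]
    if (any(x_free < -tol)) next
    x <- numeric(k)
    x[free] <- pmax(x_free, 0)
    x <- x / sum(x)
    obj <- sum((A %*% x - b)^2)
    nrm <- sum(x^2)
    if (obj < best_obj - tol^2 ||
        (abs(obj - best_obj) <= tol^2 && nrm < best_norm)) {
      best <- x
      best_obj <- obj
      best_norm <- nrm
    }
  }
  if (is.null(best)) stop("simplex least-squares solver found no feasible solution")
  best
}

#' Two-stage hierarchical deconvolution
#'
#' Stage 1 resolves the broad composition (epithelial, fibroblast, immune);
#' stage 2 resolves the immune compartment into blood subtypes (CD8T, CD4T, B,
#' optionally NK, monocyte, neutrophil). Final subtype fractions are the
#' stage-2 composition scaled by the stage-1 immune fraction, so all final
#' fractions still sum to 1. Aggregated Cox covariates follow the standard
#' definitions: lymphocyte `L = CD8T + B + CD4T`, non-immune
#' `NI = fibroblast + epithelial`; neutrophil (`N`) and monocyte (`M`) pass
#' through. NK, when present in the reference, is reported separately and is
#' deliberately excluded from `L` and `NI`.
#'
#' @param beta samples x probes matrix.
#' @param ref_stage1 probes x 3 reference with a column named `immune`
#'   (plus `epithelial`, `fibroblast`).
#' @param ref_stage2 probes x subtypes reference containing at least
#'   `CD8T`, `CD4T`, `B`, `monocyte`, `neutrophil`.
#' @param immune_col name of the stage-1 immune column.
#' @return a `proportion_table` data frame: `sample_id`, per-cell-type raw
#'   fractions, and aggregates `N`, `L`, `M`, `NI`.
#' @export
hierarchical_fractions <- function(beta, ref_stage1, ref_stage2,
                                   immune_col = "immune") {
  if (!immune_col %in% colnames(ref_stage1)) {
    stop("stage-1 reference lacks an '", immune_col, "' column")
  }
  f1 <- estimate_fractions(beta, ref_stage1)
  f2 <- estimate_fractions(beta, ref_stage2)
  immune <- f1[, immune_col]
  sub <- f2 * immune                      # stage-2 composition x immune mass
  raw <- cbind(f1[, setdiff(colnames(f1), immune_col), drop = FALSE], sub)
  aggregate_covariates(raw, sample_ids = rownames(beta))
}

#' Aggregate raw cell fractions into Cox covariates
#'
#' @param fractions samples x cell-types matrix with columns including
#'   `CD8T`, `CD4T`, `B`, `monocyte`, `neutrophil`, `fibroblast`,
#'   `epithelial` (and optionally `NK`).
#' @param sample_ids optional sample ids (default rownames).
#' @return a `proportion_table` data frame with the raw fractions plus
#'   `N`, `L`, `M`, `NI`.
#' @export
aggregate_covariates <- function(fractions, sample_ids = rownames(fractions)) {
  need <- c("CD8T", "CD4T", "B", "monocyte", "neutrophil",
            "fibroblast", "epithelial")
  miss <- setdiff(need, colnames(fractions))
  if (length(miss)) stop("missing required cell type(s): ", paste(miss, collapse = ", "))
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(nrow(fractions)))
  out <- data.frame(sample_id = sample_ids,
                    as.data.frame(fractions, row.names = NULL),
                    check.names = FALSE)
  out$N <- fractions[, "neutrophil"]
  out$L <- fractions[, "CD8T"] + fractions[, "B"] + fractions[, "CD4T"]
  out$M <- fractions[, "monocyte"]
  out$NI <- fractions[, "fibroblast"] + fractions[, "epithelial"]
  class(out) <- c("proportion_table", "data.frame")
  out
}

#' Read/write reference signature matrices (TSV, probes x cell types)
#' @param path file path; first column `probe_id`, remaining columns cell types.
#' @return probes x cell-types numeric matrix.
#' @export
read_reference <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  if (any(m < 0 | m > 1, na.rm = TRUE)) stop("reference values must be in [0,1]")
  m
}

#' @rdname read_reference
#' @param reference probes x cell-types matrix.
#' @export
write_reference <- function(reference, path) {
  df <- data.frame(probe_id = rownames(reference), reference, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
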
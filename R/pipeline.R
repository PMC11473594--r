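#' Read a phenotype table
#'
#' CSV/TSV with columns `sample_id, age, sex, cohort, wave, surv_age, status`
#' plus optional precomputed fraction covariates `N, L, M, NI`. Columns are
#' mapped onto the model's covariate names (`Age`, `Sex`, `Cohort`,
#' `Timepoint`).
#'
#' @param path file path.
#' @return cohort data frame.
#' @export
read_phenotype <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "age", "sex", "cohort", "wave", "surv_age", "status")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("phenotype lacks column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(sample_id = as.character(df$sample_id),
                    Age = df$age, Sex = as.character(df$sex),
                    Cohort = as.character(df$cohort),
                    Timepoint = as.character(df$wave),
                    surv_age = df$surv_age, status = df$status)
  for (v in c("N", "L", "M", "NI")) if (v %in% names(df)) out[[v]] <- df[[v]]
  check_cohort_table(out, character(0))
  out
}

#' Write a phenotype table (inverse of [read_phenotype()])
#' @param table cohort data frame.
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_phenotype <- function(table, path) {
  df <- data.frame(sample_id = table$sample_id, age = table$Age,
                   sex = table$Sex, cohort = table$Cohort,
                   wave = table$Timepoint, surv_age = table$surv_age,
                   status = table$status)
  for (v in c("N", "L", "M", "NI")) if (v %in% names(table)) df[[v]] <- table[[v]]
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate pipeline inputs
#'
#' Schema checks without failing: beta range and missingness, status domain,
#' clock consistency, and clock/array probe overlap statistics.
#'
#' @param clock_path,beta_path,phenotype_path input file paths.
#' @return a list report: per-file `ok` flag, violation messages, and
#'   overlap counts.
#' @export
validate_inputs <- function(clock_path, beta_path, phenotype_path) {
  report <- list(violations = character(0))
  try_read <- function(label, reader, path) {
    tryCatch(reader(path), error = function(e) {
      structure(paste0(label, ": ", conditionMessage(e)), class = "violation")
    })
  }
  objs <- list(clock = try_read("clock", read_clock_definition, clock_path),
               beta = try_read("beta", read_beta_matrix, beta_path),
               phenotype = try_read("phenotype", read_phenotype, phenotype_path))
  for (o in objs) {
    if (inherits(o, "violation")) {
      report$violations <- c(report$violations, unclass(o))
    }
  }
  pick <- function(nm) if (inherits(objs[[nm]], "violation")) NULL else objs[[nm]]
  clock <- pick("clock"); beta <- pick("beta"); pheno <- pick("phenotype")
  if (!is.null(beta)) {
    report$n_samples <- nrow(beta)
    report$n_probes <- ncol(beta)
    report$missing_fraction <- mean(is.na(beta))
  }
  if (!is.null(beta) && !is.null(clock)) {
    ov <- intersect(clock$probe_ids, colnames(beta))
    report$clock_probes <- length(clock$probe_ids)
    report$overlap_probes <- length(ov)
    report$overlap_fraction <- length(ov) / length(clock$probe_ids)
    # a probe counts as measured if any sample observes it
    measured <- ov[colSums(!is.na(beta[, ov, drop = FALSE])) > 0]
    report$measured_fraction <- length(measured) / length(clock$probe_ids)
  }
  if (!is.null(beta) && !is.null(pheno)) {
    if (!setequal(rownames(beta), pheno$sample_id)) {
      report$violations <- c(report$violations,
                             "beta and phenotype sample ids do not match")
    }
  }
  report$ok <- length(report$violations) == 0L
  report
}

#' Run the full mortality-association pipeline
#'
#' Stages: clock application under missingness -> cell-type deconvolution
#' (skipped when the phenotype already carries `N`, `L`, `M`, `NI`) -> Cox
#' association of standardized delta age -> delta stratification and
#' marginal survival curves -> per-CpG ablation scan -> classification and
#' over-representation analysis (when annotation and gene sets are given).
#' All tables are written tab-separated with a header; a JSON manifest
#' records the configuration, seed and input hashes so the run can be
#' reproduced from the manifest alone.
#'
#' @param clock a [clock_definition] or path.
#' @param beta samples x probes matrix or path.
#' @param phenotype cohort data frame (see [read_phenotype()]) or path.
#' @param out_dir output directory (created).
#' @param ref_stage1,ref_stage2 optional reference signature matrices or
#'   paths; required when the phenotype lacks fraction covariates.
#' @param annotation optional probe->gene data frame or TSV path.
#' @param gene_sets optional named list of gene sets or GMT path.
#' @param mode ablation mode, `"zero"` or `"remove"`.
#' @param freeze_sd freeze the base delta SD during the scan.
#' @param top_k annotated CpGs per class for the enrichment stage.
#' @param seed RNG seed recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return invisibly, a list with the in-memory stage results
#'   (`predictions`, `proportions`, `fit`, `strat_fit`, `curves`, `scan`,
#'   `enrichment`, `manifest`).
#' @export
run_pipeline <- function(clock, beta, phenotype, out_dir,
                         ref_stage1 = NULL, ref_stage2 = NULL,
                         annotation = NULL, gene_sets = NULL,
                         mode = "zero", freeze_sd = FALSE, top_k = 250,
                         seed = 1) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines("FAILED", file.path(out_dir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage("validate", {
    if (is.character(clock)) clock <- read_clock_definition(clock)
    if (is.character(beta)) beta <- read_beta_matrix(beta)
    if (is.character(phenotype)) phenotype <- read_phenotype(phenotype)
    if (is.character(ref_stage1)) ref_stage1 <- read_reference(ref_stage1)
    if (is.character(ref_stage2)) ref_stage2 <- read_reference(ref_stage2)
    if (is.character(annotation)) {
      annotation <- utils::read.table(annotation, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE)
    }
    if (is.character(gene_sets)) gene_sets <- read_gmt(gene_sets)
    check_cohort_table(phenotype, character(0))
    if (!setequal(rownames(beta), phenotype$sample_id)) {
      stop("beta and phenotype sample ids do not match")
    }
    beta <- beta[phenotype$sample_id, , drop = FALSE]
  })

  pred <- stage("predict", {
    p <- clock_ages(beta, clock, phenotype$Age)
    write_predictions(p, file.path(out_dir, "predictions.tsv"))
    p
  })

  tab <- phenotype
  tab$s_delta <- pred$s_delta
  proportions <- NULL
  if (!all(c("N", "L", "M", "NI") %in% names(tab))) {
    proportions <- stage("deconvolve", {
      if (is.null(ref_stage1) || is.null(ref_stage2)) {
        stop("phenotype lacks N/L/M/NI and no reference signatures were given")
      }
      pr <- hierarchical_fractions(beta, ref_stage1, ref_stage2)
      utils::write.table(pr, file.path(out_dir, "proportions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      pr
    })
    tab$N <- proportions$N; tab$L <- proportions$L
    tab$M <- proportions$M; tab$NI <- proportions$NI
  }

  fit <- stage("associate", {
    f <- fit_cox(tab)
    utils::write.table(summary(f), file.path(out_dir, "forest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    f
  })

  strat_out <- stage("stratify", {
    strata <- stratify_sdelta(tab$s_delta)
    sf <- tryCatch(fit_cox_categorical(tab, strata = strata),
                   error = function(e) NULL)
    curves <- marginal_survival(fit, strata)
    utils::write.table(as.data.frame(curves), file.path(out_dir, "curves.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(strata = strata, fit = sf, curves = curves)
  })

  scan <- stage("ablate", {
    sc <- ablation_scan(beta, clock, tab, mode = mode, freeze_sd = freeze_sd,
                        annotation = annotation)
    utils::write.table(summary(sc), file.path(out_dir, "ablation_scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sc
  })

  enrichment <- NULL
  if (!is.null(annotation) && !is.null(gene_sets)) {
    enrichment <- stage("enrich", {
      universe <- unique(stats::na.omit(annotation$gene))
      res <- lapply(c("mortality", "anti-mortality"), function(cl) {
        genes <- suppressWarnings(top_annotated(scan, k = top_k, class = cl))
        if (!length(genes)) return(NULL)
        cbind(class = cl, ora(genes, gene_sets, universe))
      })
      res <- do.call(rbind, res)
      utils::write.table(res, file.path(out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      res
    })
  }

  manifest <- list(
    package = "clockscan",
    version = as.character(utils::packageVersion("clockscan")),
    r_version = as.character(getRversion()),
    seed = seed,
    config = list(mode = mode, freeze_sd = freeze_sd, top_k = top_k,
                  terms = fit$terms, ties = fit$ties,
                  conf_level = fit$conf_level),
    inputs = list(n_samples = nrow(beta), n_probes = ncol(beta),
                  clock = clock$name, clock_probes = length(clock$probe_ids)),
    outputs = list.files(out_dir, pattern = "\\.tsv$"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(predictions = pred, proportions = proportions, fit = fit,
                 strata = strat_out$strata, strat_fit = strat_out$fit,
                 curves = strat_out$curves, scan = scan,
                 enrichment = enrichment, manifest = manifest))
}

#' Write a synthetic cohort as a pipeline fixture set
#'
#' Materializes a [simulate_cohort()] result as the plain-text files the
#' pipeline consumes: clock JSON, masked beta TSV, phenotype CSV, reference
#' TSVs, annotation TSV, gene-set GMT, and a truth-ledger JSON.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory.
#' @param with_fractions include the true `N/L/M/NI` columns in the
#'   phenotype (skips the deconvolution stage downstream).
#' @return `dir`, invisibly.
#' @export
write_cohort_fixtures <- function(cohort, dir, with_fractions = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_clock_definition(cohort$clock, file.path(dir, "clock.json"))
  write_beta_matrix(cohort$beta, file.path(dir, "beta.tsv"))
  tab <- cohort$table
  if (!with_fractions) tab <- tab[, setdiff(names(tab), c("N", "L", "M", "NI"))]
  write_phenotype(tab, file.path(dir, "phenotype.csv"))
  write_reference(cohort$references$stage1, file.path(dir, "reference_stage1.tsv"))
  write_reference(cohort$references$stage2, file.path(dir, "reference_stage2.tsv"))
  utils::write.table(cohort$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  genes <- unique(stats::na.omit(cohort$annotation$gene))
  write_gmt(simulate_gene_sets(genes, seed = cohort$truth$config$seed),
            file.path(dir, "gene_sets.gmt"))
  jsonlite::write_json(
    list(driver_ids = cohort$truth$driver_ids,
         b_true = cohort$truth$b_true,
         retained = cohort$truth$retained,
         seed = cohort$truth$config$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
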
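#' Validate a methylation beta matrix
#'
#' Beta values are methylation fractions in `[0, 1]`; missingness (a probe not
#' measured on the platform, or dropped for a sample) is encoded as `NA`, the
#' language's explicit missing marker. The availability mask is `!is.na()`.
#' Values outside `[0, 1]` are rejected, not clamped: arrays deliver fractions,
#' so out-of-range cells indicate an upstream processing error.
#'
#' @param beta numeric matrix, samples in rows (rownames = sample ids), probes
#'   in columns (colnames = probe ids).
#' @return `beta`, invisibly, if valid; otherwise an error.
#' @export
validate_beta <- function(beta) {
  if (!is.matrix(beta) || !is.numeric(beta)) stop("beta must be a numeric matrix")
  if (is.null(rownames(beta)) || is.null(colnames(beta))) {
    stop("beta must carry sample rownames and probe colnames")
  }
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(beta))
    stop(sprintf("beta value out of [0,1] at sample '%s', probe '%s': %g (%d offending cells)",
                 rownames(beta)[i[1]], colnames(beta)[i[2]], beta[bad[1]], length(bad)))
  }
  invisible(beta)
}

#' Read a beta matrix from TSV/CSV
#'
#' First column is the sample id; remaining columns are probes. Empty cells
#' and `NA` are missing. Gzipped files are accepted transparently.
#'
#' @param path file path (`.tsv`, `.csv`, optionally `.gz`).
#' @return validated numeric matrix (samples x probes) with `NA` for missing.
#' @export
read_beta_matrix <- function(path) {
  if (!file.exists(path)) stop("beta file not found: ", path)
  sep <- if (grepl("\\.csv(\\.gz)?$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          check.names = FALSE, na.strings = c("", "NA"))
  if (ncol(df) < 2L) stop("beta file needs a sample_id column plus >=1 probe column")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  if (anyDuplicated(rownames(m))) stop("duplicate sample ids in beta file")
  if (anyDuplicated(colnames(m))) stop("duplicate probe ids in beta file")
  validate_beta(m)
  m
}

#' Write a beta matrix to TSV
#'
#' @param beta samples x probes numeric matrix.
#' @param path output path; `.gz` suffix writes gzip.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path) {
  validate_beta(beta)
  df <- data.frame(sample_id = rownames(beta), beta, check.names = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Restrict a beta matrix to the probes a platform measures
#'
#' Emulates running an EPIC-trained clock on 450K data: probes outside the
#' retained set become missing for every sample; retained probes are unchanged.
#' Probes in `retained_probe_ids` that the matrix does not contain are ignored.
#'
#' @param beta samples x probes matrix.
#' @param retained_probe_ids character vector of probes the platform measures;
#'   may be any subset, including empty.
#' @return the masked beta matrix (same dimensions).
#' @export
apply_platform_mask <- function(beta, retained_probe_ids) {
  validate_beta(beta)
  drop <- !(colnames(beta) %in% retained_probe_ids)
  beta[, drop] <- NA_real_
  beta
}
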
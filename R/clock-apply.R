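#' Per-cluster mean methylation under arbitrary missingness
#'
#' Collapses the beta matrix into the clock's cluster averages. Missing inputs
#' are removed from the averaging: each cell is the mean of the *available*
#' probe values in that cluster for that sample, and a cluster with no probe
#' available is set to 0. Probes the clock references but the matrix does not
#' contain are treated exactly like per-sample missing values.
#'
#' @param beta samples x probes numeric matrix, `NA` = missing.
#' @param clock a [clock_definition].
#' @return numeric matrix samples x clusters (columns ordered like
#'   `clock$cluster_weights`).
#' @export
compute_cluster_values <- function(beta, clock) {
  stopifnot(inherits(clock, "clock_definition"))
  validate_beta(beta)
  st <- clock_state(beta, clock)
  vals <- st$sums / st$counts
  vals[st$counts == 0] <- 0
  vals
}

# Internal: per-sample, per-cluster sums and availability counts over the
# clock's probes. The ablation scan updates these incrementally, so they are
# computed once here.
clock_state <- function(beta, clock) {
  clusters <- names(clock$cluster_weights)
  present <- intersect(clock$probe_ids, colnames(beta))
  b <- beta[, present, drop = FALSE]
  avail <- !is.na(b)
  b0 <- b
  b0[!avail] <- 0
  # probe -> cluster indicator, probes x clusters
  z <- matrix(0, nrow = length(present), ncol = length(clusters),
              dimnames = list(present, clusters))
  z[cbind(seq_along(present), match(clock$cluster_of[present], clusters))] <- 1
  sums <- b0 %*% z
  counts <- (avail * 1) %*% z
  list(sums = sums, counts = counts, beta = b0, avail = avail,
       probes = present, clusters = clusters)
}

#' Predict epigenetic age from cluster values
#'
#' `prediction = intercept + sum_k weight_k * cluster_value_k` per sample.
#'
#' @param cluster_values samples x clusters matrix as returned by
#'   [compute_cluster_values()]; columns must match the clock's clusters.
#' @param clock a [clock_definition].
#' @return named numeric vector of predicted ages.
#' @export
predict_epigenetic_age <- function(cluster_values, clock) {
  stopifnot(inherits(clock, "clock_definition"))
  w <- clock$cluster_weights
  if (ncol(cluster_values) != length(w)) {
    stop("cluster dimension mismatch: ", ncol(cluster_values), " vs ", length(w))
  }
  if (!is.null(colnames(cluster_values))) {
    if (!setequal(colnames(cluster_values), names(w))) {
      stop("cluster names do not match the clock")
    }
    cluster_values <- cluster_values[, names(w), drop = FALSE]
  }
  drop(cluster_values %*% w) + clock$intercept
}

#' Standardize delta age
#'
#' Delta age is predicted minus chronological age; because a clock's output
#' scale is arbitrary, deltas are normalized by dividing by their sample
#' standard deviation (divisor n-1), giving the dimensionless standardized
#' delta whose cohort SD is exactly 1.
#'
#' @param predicted numeric vector of predicted ages.
#' @param chronological numeric vector of chronological ages, same length.
#' @param sample_ids optional ids; defaults to names of `predicted` or seq.
#' @return An `age_prediction` data frame with columns `sample_id`,
#'   `predicted_age`, `chronological_age`, `delta`, `s_delta`.
#' @export
standardize_delta <- function(predicted, chronological, sample_ids = NULL) {
  if (length(predicted) != length(chronological)) stop("length mismatch")
  if (length(predicted) < 2L) stop("need >=2 samples to standardize deltas")
  delta <- predicted - chronological
  s <- stats::sd(delta)
  if (!is.finite(s) || s == 0) {
    stop("all delta ages are identical: standard deviation is zero")
  }
  if (is.null(sample_ids)) {
    sample_ids <- if (!is.null(names(predicted))) names(predicted)
                  else as.character(seq_along(predicted))
  }
  structure(
    data.frame(sample_id = sample_ids,
               predicted_age = as.numeric(predicted),
               chronological_age = as.numeric(chronological),
               delta = as.numeric(delta),
               s_delta = as.numeric(delta / s),
               row.names = NULL),
    class = c("age_prediction", "data.frame"))
}

#' Apply a clock to a beta matrix
#'
#' Convenience wrapper: cluster averaging under missingness, linear
#' prediction, and delta standardization in one step.
#'
#' @param beta samples x probes matrix.
#' @param clock a [clock_definition].
#' @param chronological_age numeric vector of ages, aligned with rows of
#'   `beta`.
#' @return an `age_prediction` data frame (see [standardize_delta()]).
#' @export
clock_ages <- function(beta, clock, chronological_age) {
  pred <- predict_epigenetic_age(compute_cluster_values(beta, clock), clock)
  standardize_delta(pred, chronological_age, sample_ids = rownames(beta))
}

#' Accuracy metrics for age prediction
#'
#' R-squared is the squared Pearson correlation between predicted and
#' chronological age; MAE and RMSE are the mean absolute and root mean
#' squared prediction errors in years.
#'
#' @param predicted,chronological equal-length numeric vectors, n >= 2.
#' @return named list `list(R2, MAE, RMSE)`; `R2` is `NA` when either vector
#'   has zero variance.
#' @export
accuracy_metrics <- function(predicted, chronological) {
  if (length(predicted) != length(chronological)) stop("length mismatch")
  if (length(predicted) < 2L) stop("need n >= 2")
  err <- predicted - chronological
  r2 <- if (stats::sd(predicted) == 0 || stats::sd(chronological) == 0) NA_real_
        else stats::cor(predicted, chronological)^2
  list(R2 = r2, MAE = mean(abs(err)), RMSE = sqrt(mean(err^2)))
}

#' Write age predictions to TSV
#' @param pred an `age_prediction` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(pred, path) {
  utils::write.table(pred, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
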
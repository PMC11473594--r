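#' Fit the mortality-association proportional-hazards model
#'
#' Fits `Surv(SurvAge, Status) ~ terms` by Cox partial likelihood with the
#' Efron tie correction (Breslow available via `ties`). The time variable is
#' age at death or censoring, with chronological age at last measurement also
#' entering as a covariate — the model is implemented exactly as written, with
#' no left truncation. Character/factor covariates get treatment contrasts
#' with the lexicographically first level as reference. Per-term hazard
#' ratios, Wald confidence intervals, Wald p-values and Benjamini-Hochberg
#' q-values (adjusted across the terms of this one model, matching a forest
#' plot's per-row FDR) are tabulated, and the Breslow baseline cumulative
#' hazard is stored for survival-curve marginalization.
#'
#' @param table data frame with columns `surv_age` (years at death/censoring,
#'   > 0), `status` (0 alive / 1 deceased) and every covariate in `terms`.
#' @param terms character vector of covariate column names; `character(0)`
#'   fits the null (covariate-free) model, whose baseline hazard is the
#'   Nelson-Aalen estimator.
#' @param ties `"efron"` (default) or `"breslow"` partial-likelihood tie
#'   handling.
#' @param conf_level Wald CI level (default 0.95).
#' @return an object of class `cox_assoc` with elements `table` (term, n,
#'   coef, hr, ci_low, ci_high, p, q), `coefficients`, `lp` (linear
#'   predictors), `baseline` (Breslow cumulative hazard steps), `n`,
#'   `n_events`, and the underlying `survival::coxph` fit (`fit`).
#' @export
fit_cox <- function(table, terms = c("s_delta", "N", "L", "M", "NI",
                                     "Sex", "Age", "Cohort", "Timepoint"),
                    ties = c("efron", "breslow"), conf_level = 0.95) {
  ties <- match.arg(ties)
  check_cohort_table(table, terms)
  y <- survival::Surv(table$surv_age, table$status)
  n <- nrow(table)
  n_events <- sum(table$status)
  if (n_events < 1L) stop("no events: cannot fit a proportional-hazards model")

  if (length(terms) == 0L) {
    base <- breslow_cumhaz(table$surv_age, table$status, lp = rep(0, n))
    out <- list(fit = NULL, coefficients = numeric(0),
                table = data.frame(term = character(0), n = integer(0),
                                   coef = numeric(0), hr = numeric(0),
                                   ci_low = numeric(0), ci_high = numeric(0),
                                   p = numeric(0), q = numeric(0)),
                lp = rep(0, n), baseline = base, X = NULL, y = y,
                terms = terms, ties = ties, conf_level = conf_level,
                n = n, n_events = n_events)
    class(out) <- "cox_assoc"
    return(out)
  }

  X <- cox_design(table, terms)
  const <- apply(X, 2, function(col) length(unique(col)) == 1L)
  if (any(const)) {
    stop("constant covariate(s): ", paste(colnames(X)[const], collapse = ", "))
  }
  fit <- survival::coxph(y ~ X, ties = ties)
  if (anyNA(stats::coef(fit))) {
    stop("Cox model unidentifiable (collinear covariates): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  }
  if (!is.null(fit$info) && grepl("infinite", paste(fit$info, collapse = " "))) {
    stop("Cox model did not converge (possible separation / monotone likelihood)")
  }
  beta <- stats::coef(fit)
  names(beta) <- colnames(X)
  se <- sqrt(diag(fit$var))
  if (any(!is.finite(se)) || any(se > 1e3)) {
    stop("Cox fit unstable (possible separation: a coefficient diverges)")
  }
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  q <- adjust_fdr(p)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  lp <- drop(X %*% beta)
  out <- list(fit = fit, coefficients = beta,
              table = data.frame(term = colnames(X), n = n, coef = beta,
                                 hr = exp(beta),
                                 ci_low = exp(beta - zq * se),
                                 ci_high = exp(beta + zq * se),
                                 p = p, q = q, row.names = NULL),
              lp = lp, baseline = breslow_cumhaz(table$surv_age, table$status, lp),
              X = X, y = y, terms = terms, ties = ties,
              conf_level = conf_level, n = n, n_events = n_events)
  class(out) <- "cox_assoc"
  out
}

# Design matrix with treatment contrasts, no intercept column; reference
# level of factors is the lexicographically first.
cox_design <- function(table, terms) {
  df <- table[, terms, drop = FALSE]
  for (v in terms) {
    if (is.character(df[[v]]) || is.logical(df[[v]]) || is.factor(df[[v]])) {
      df[[v]] <- factor(df[[v]], levels = sort(unique(as.character(df[[v]]))))
      if (nlevels(df[[v]]) < 2L) stop("factor '", v, "' has <2 observed levels")
    }
  }
  mm <- stats::model.matrix(~ ., data = df)
  mm[, -1, drop = FALSE]
}

check_cohort_table <- function(table, terms) {
  need <- c("surv_age", "status", terms)
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("cohort table lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(table$status %in% c(0, 1))) stop("status must be 0 (alive) or 1 (deceased)")
  if (any(table$surv_age <= 0)) stop("surv_age must be positive")
  invisible(TRUE)
}

#' @export
print.cox_assoc <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit: n = %d, events = %d, ties = %s\n",
              x$n, x$n_events, x$ties))
  if (nrow(x$table)) {
    tb <- x$table
    tb$hr <- signif(tb$hr, 4); tb$ci_low <- signif(tb$ci_low, 4)
    tb$ci_high <- signif(tb$ci_high, 4)
    tb$p <- signif(tb$p, 3); tb$q <- signif(tb$q, 3)
    print(tb[, c("term", "n", "hr", "ci_low", "ci_high", "p", "q")],
          row.names = FALSE)
  } else cat("  (null model: no covariates)\n")
  invisible(x)
}

#' @export
summary.cox_assoc <- function(object, ...) object$table

#' @export
coef.cox_assoc <- function(object, ...) object$coefficients

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values across a family of p-values (`p.adjust` with the `"fdr"`
#' method).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values, same order as `p`.
#' @export
adjust_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "fdr")
}

#' Breslow cumulative baseline hazard
#'
#' `H0(t) = sum over event times tj <= t of d_j / sum(risk set exp(lp))`.
#' With all linear predictors zero this is exactly the Nelson-Aalen estimator.
#'
#' @param time event/censoring times.
#' @param status 0/1 event indicator.
#' @param lp linear predictors (`X %*% beta`, uncentered).
#' @return data frame `time`, `hazard` (cumulative), one row per distinct
#'   event time.
#' @export
breslow_cumhaz <- function(time, status, lp = rep(0, length(time))) {
  stopifnot(length(time) == length(status), length(lp) == length(time))
  et <- sort(unique(time[status == 1]))
  w <- exp(lp)
  inc <- vapply(et, function(t) {
    sum(status == 1 & time == t) / sum(w[time >= t])
  }, numeric(1))
  data.frame(time = et, hazard = cumsum(inc))
}

#' Stratify standardized delta age
#'
#' Bins standardized deltas into `[-3,0)`, `[0,3)`, `[3,6]`. Values outside
#' `[-3, 6]` are assigned to the nearest terminal bin with a warning.
#'
#' @param s_delta numeric vector of standardized deltas (finite).
#' @return factor with levels `"[-3,0)"`, `"[0,3)"`, `"[3,6]"`.
#' @export
stratify_sdelta <- function(s_delta) {
  if (any(!is.finite(s_delta))) stop("s_delta must be finite")
  n_out <- sum(s_delta < -3 | s_delta > 6)
  if (n_out > 0) {
    warning(n_out, " value(s) outside [-3, 6] assigned to the nearest terminal bin")
  }
  lev <- c("[-3,0)", "[0,3)", "[3,6]")
  idx <- ifelse(s_delta < 0, 1L, ifelse(s_delta < 3, 2L, 3L))
  factor(lev[idx], levels = lev)
}

#' Cox model with stratified delta age as a categorical covariate
#'
#' Replaces the continuous standardized delta by its stratum, yielding
#' per-stratum hazard ratios against the reference `"[-3,0)"` bin with
#' FDR-adjusted significance. Empty strata are dropped (with a warning).
#'
#' @param table cohort data frame (see [fit_cox()]); must contain `s_delta`
#'   unless `strata` is supplied.
#' @param strata optional precomputed factor from [stratify_sdelta()].
#' @param covariates additional model terms (default the standard covariate
#'   set).
#' @inheritParams fit_cox
#' @return a `cox_assoc`; stratum rows are named `sdelta_stratum<level>`.
#' @export
fit_cox_categorical <- function(table, strata = NULL,
                                covariates = c("N", "L", "M", "NI",
                                               "Sex", "Age", "Cohort", "Timepoint"),
                                ties = c("efron", "breslow"), conf_level = 0.95) {
  if (is.null(strata)) strata <- stratify_sdelta(table$s_delta)
  strata <- droplevels(factor(strata))
  if (nlevels(factor(strata)) < 2L) {
    stop("only one stratum present: no contrast to estimate")
  }
  lev <- levels(strata)
  ref <- if ("[-3,0)" %in% lev) "[-3,0)" else lev[1]
  if (!identical(lev[1], ref)) strata <- stats::relevel(strata, ref = ref)
  tab2 <- table
  tab2$sdelta_stratum <- strata
  fit_cox(tab2, terms = c("sdelta_stratum", covariates),
          ties = ties, conf_level = conf_level)
}

#' Marginal adjusted survival curves per stratum
#'
#' For each stratum, the marginal curve is the pointwise average of each
#' member sample's model-predicted survival
#' `S_i(t) = exp(-H0(t) * exp(lp_i))`, with `H0` the Breslow baseline of the
#' fitted model. The median survival age is the first grid age at which the
#' marginal curve drops to 0.5 or below; a curve that never crosses 0.5
#' reports `NA` (not reached).
#'
#' @param fit a `cox_assoc` from [fit_cox()].
#' @param strata factor assigning each of the fit's samples to a stratum.
#' @return a `survival_curves` data frame (`stratum`, `age`, `survival`) with
#'   a `medians` attribute (named vector of median survival ages).
#' @export
marginal_survival <- function(fit, strata) {
  stopifnot(inherits(fit, "cox_assoc"))
  strata <- factor(strata)
  if (length(strata) != fit$n) stop("strata length must match the fitted samples")
  H <- fit$baseline
  grid <- H$time
  curves <- lapply(levels(strata), function(lv) {
    idx <- which(strata == lv)
    if (!length(idx)) return(NULL)
    risk <- exp(fit$lp[idx])
    s <- vapply(H$hazard, function(h) mean(exp(-h * risk)), numeric(1))
    data.frame(stratum = lv, age = grid, survival = s)
  })
  out <- do.call(rbind, curves)
  medians <- vapply(split(out, out$stratum), function(d) {
    i <- which(d$survival <= 0.5)
    if (length(i)) d$age[min(i)] else NA_real_
  }, numeric(1))
  structure(out, medians = medians[levels(droplevels(strata))],
            class = c("survival_curves", "data.frame"))
}

#' @export
print.survival_curves <- function(x, ...) {
  med <- attr(x, "medians")
  cat("Marginal adjusted survival curves\n")
  for (lv in names(med)) {
    cat(sprintf("  %-8s median survival age: %s\n", lv,
                if (is.na(med[lv])) "not reached" else format(med[lv])))
  }
  invisible(x)
}
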
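#' Simulation configuration
#'
#' Defines the synthetic study conditions: a cohort of older adults (ages
#' spanning 67.8-90.6 years, two cohorts, four measurement waves), a
#' cluster-averaged clock over `n_probes` CpGs, a platform that measures only
#' a `retention` fraction of the clock's probes, blood-like cell mixtures,
#' and right-censored survival whose hazard is multiplicative in
#' `exp(b_true * s_delta)` on the age timescale. All defaults are fixed;
#' every field is overridable.
#'
#' @param n_samples cohort size.
#' @param n_probes number of clock CpGs.
#' @param n_clusters number of clock clusters.
#' @param age_range chronological age range (years) sampled uniformly.
#' @param baseline_range per-probe baseline methylation range.
#' @param slope_mean,slope_sd cluster-level age-slope magnitude distribution
#'   (beta units per standardized age); sign follows the cluster weight.
#' @param probe_baseline_sd within-cluster SD of probe baselines around the
#'   cluster baseline (clusters are correlated CpGs).
#' @param probe_slope_rel_sd relative within-cluster spread of probe slopes.
#' @param noise_sd per-probe beta noise SD.
#' @param biol_sd SD (years) of the latent person-level aging offset that the
#'   clock reads out; this is what gives deltas realistic spread.
#' @param n_drivers number of planted driver CpGs (each moved into its own
#'   singleton cluster).
#' @param driver_frac driver signal SD as a fraction of the non-driver delta
#'   SD; 1 means the driver carries as much delta variance as everything else
#'   combined.
#' @param driver_beta_sd SD of the driver CpG's beta-scale signal.
#' @param b_true true log hazard ratio per SD of standardized delta.
#' @param covariate_loghr named vector of extra true log-HRs; supported name:
#'   `Sex` (applied to males).
#' @param baseline_hazard list: `dist` (`"weibull"` or `"exponential"`) with
#'   `shape`/`scale` or `rate`.
#' @param follow_up per-person administrative follow-up (years after entry).
#' @param censor_age hard administrative censoring age (years).
#' @param retention fraction of clock probes the platform measures.
#' @param mixture_alpha Dirichlet concentrations for the cell mixture
#'   (blood-like by default: neutrophil-dominated, trace epithelial and
#'   fibroblast).
#' @param n_ref_probes reference probes per deconvolution stage.
#' @param annotation_rate fraction of clock CpGs carrying a gene annotation.
#' @param seed base RNG seed; stage streams are derived from it.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_samples = 1000, n_probes = 2000, n_clusters = 100,
                              age_range = c(67.8, 90.6),
                              baseline_range = c(0.2, 0.8),
                              slope_mean = 0.04, slope_sd = 0.015,
                              probe_baseline_sd = 0.02,
                              probe_slope_rel_sd = 0.1,
                              noise_sd = 0.03, biol_sd = 3,
                              n_drivers = 1, driver_frac = 1,
                              driver_beta_sd = 0.12,
                              b_true = log(1.21),
                              covariate_loghr = c(Sex = 0.25),
                              baseline_hazard = list(dist = "weibull",
                                                     shape = 8, scale = 97),
                              follow_up = 12, censor_age = 105,
                              retention = 0.5,
                              mixture_alpha = c(CD8T = 2, CD4T = 4, B = 1.5,
                                                NK = 1, monocyte = 2,
                                                neutrophil = 9,
                                                fibroblast = 0.25,
                                                epithelial = 0.25),
                              n_ref_probes = 60,
                              annotation_rate = 0.8,
                              seed = 1) {
  cfg <- list(n_samples = n_samples, n_probes = n_probes, n_clusters = n_clusters,
              age_range = age_range, baseline_range = baseline_range,
              slope_mean = slope_mean, slope_sd = slope_sd,
              probe_baseline_sd = probe_baseline_sd,
              probe_slope_rel_sd = probe_slope_rel_sd,
              noise_sd = noise_sd, biol_sd = biol_sd,
              n_drivers = n_drivers, driver_frac = driver_frac,
              driver_beta_sd = driver_beta_sd, b_true = b_true,
              covariate_loghr = covariate_loghr,
              baseline_hazard = baseline_hazard,
              follow_up = follow_up, censor_age = censor_age,
              retention = retention, mixture_alpha = mixture_alpha,
              n_ref_probes = n_ref_probes, annotation_rate = annotation_rate,
              seed = seed)
  stopifnot(n_samples >= 2, n_probes >= 1, n_clusters >= 1,
            n_probes >= n_clusters, n_drivers >= 0, n_drivers <= n_probes,
            retention >= 0, retention <= 1, noise_sd >= 0,
            diff(age_range) > 0)
  class(cfg) <- "simulation_config"
  cfg
}

# Stage-keyed substream seed (kept well below 2^31).
substream <- function(seed, stage) {
  offs <- c(clock = 1L, drivers = 2L, methylation = 3L, mask = 4L,
            survival = 5L, reference = 6L, annotation = 7L)
  (as.integer(seed) %% 200000000L) * 10L + offs[[stage]]
}

#' Simulate a cluster-averaged clock
#'
#' Probes are partitioned into clusters (every cluster nonempty), cluster
#' weights are drawn standard normal, per-probe age slopes are drawn with
#' magnitude `|N(slope_mean, slope_sd)|` and sign matching the cluster weight
#' (so hyper- and hypomethylating CpGs both occur), and the weights and
#' intercept are then calibrated analytically so that the noise-free clock
#' output equals chronological age over the configured range.
#'
#' @param config a [simulation_config].
#' @param seed RNG seed (default: derived from `config$seed`).
#' @return list: `clock` (a [clock_definition]), `baseline` and `slope`
#'   (named per-probe generation parameters).
#' @export
simulate_clock <- function(config, seed = substream(config$seed, "clock")) {
  set.seed(seed)
  p <- config$n_probes
  k <- config$n_clusters
  probe_ids <- sprintf("cg%07d", seq_len(p))
  cluster_ids <- sprintf("cl%04d", seq_len(k))
  # every cluster gets one probe, the rest are assigned at random
  assign <- c(seq_len(k), sample.int(k, p - k, replace = TRUE))
  assign <- assign[sample.int(p)]
  w0 <- stats::rnorm(k)
  w0[abs(w0) < 0.05] <- 0.05 * sign(w0[abs(w0) < 0.05] + 1e-12)
  # clusters are sets of correlated CpGs: probes share a cluster-level
  # baseline and age slope up to small per-probe deviations, so that
  # averaging a random subset of a cluster changes its mean only slightly
  base_c <- stats::runif(k, config$baseline_range[1], config$baseline_range[2])
  slope_c <- abs(stats::rnorm(k, config$slope_mean, config$slope_sd)) * sign(w0)
  baseline <- pmin(pmax(base_c[assign] + stats::rnorm(p, 0, config$probe_baseline_sd),
                        0.05), 0.95)
  slope <- slope_c[assign] * (1 + stats::rnorm(p, 0, config$probe_slope_rel_sd))
  mid <- mean(config$age_range)
  half <- diff(config$age_range) / 2
  # calibration: prediction = intercept + sum_c w_c (bbar_c + sbar_c * z),
  # z = (age - mid)/half; rescale so the z-coefficient equals half.
  bbar <- tapply(baseline, assign, mean)
  sbar <- tapply(slope, assign, mean)
  K <- sum(w0 * sbar)
  if (is.finite(half / K) && K != 0) {
    w <- w0 * (half / K)
  } else {
    w <- w0            # no age signal to calibrate against (zero slopes)
  }
  intercept <- mid - sum(w * bbar)
  clock <- clock_definition(probe_ids, cluster_ids[assign],
                            stats::setNames(w, cluster_ids),
                            intercept = intercept, name = "synthetic_clock")
  list(clock = clock,
       baseline = stats::setNames(baseline, probe_ids),
       slope = stats::setNames(slope, probe_ids))
}

#' Plant driver CpGs into a clock
#'
#' Selects `n_drivers` probes and rewires each into its own singleton cluster
#' whose weight is chosen analytically so that the driver's contribution to
#' the delta-age SD equals `driver_frac` times the expected non-driver delta
#' SD (biological offset plus masked measurement noise). The driver probe's
#' age slope is zeroed and its baseline set to 0.5; the intercept is adjusted
#' so calibration is preserved. The driver's beta values will carry a latent
#' standard-normal mortality-linked signal scaled by `driver_beta_sd`.
#'
#' @param sim_clock output of [simulate_clock()].
#' @param config a [simulation_config].
#' @param seed RNG seed.
#' @return list like [simulate_clock()] plus `driver_ids` and
#'   `driver_weight`.
#' @export
plant_drivers <- function(sim_clock, config,
                          seed = substream(config$seed, "drivers")) {
  if (config$n_drivers == 0L) {
    return(c(sim_clock, list(driver_ids = character(0), driver_weight = numeric(0))))
  }
  set.seed(seed)
  clock <- sim_clock$clock
  drivers <- sample(clock$probe_ids, config$n_drivers)
  cluster_of <- clock$cluster_of
  weights <- clock$cluster_weights
  baseline <- sim_clock$baseline
  slope <- sim_clock$slope

  # expected non-driver delta SD: biological offset + masked noise through
  # the cluster averages, sigma_bg^2 = sum_c w_c^2 sd^2 / m_c
  sizes <- table(cluster_of[setdiff(clock$probe_ids, drivers)])
  m <- pmax(1, round(config$retention * as.numeric(sizes[names(weights)])))
  m[is.na(m)] <- 1
  sigma_bg <- sqrt(config$biol_sd^2 +
                   sum(weights^2 * config$noise_sd^2 / m))
  w_d <- config$driver_frac * sigma_bg /
         (config$driver_beta_sd * sqrt(config$n_drivers))

  intercept <- clock$intercept
  for (i in seq_along(drivers)) {
    d <- drivers[i]
    cl <- sprintf("driver%02d", i)
    cluster_of[d] <- cl
    weights[cl] <- w_d
    baseline[d] <- 0.5
    slope[d] <- 0
    intercept <- intercept - w_d * 0.5
  }
  # a driver pulled out of a singleton cluster leaves it empty: drop it
  weights <- weights[names(weights) %in% unique(cluster_of)]
  clock2 <- clock_definition(clock$probe_ids, cluster_of[clock$probe_ids],
                             weights, intercept = intercept, name = clock$name)
  list(clock = clock2, baseline = baseline, slope = slope,
       driver_ids = drivers, driver_weight = rep(w_d, length(drivers)))
}

rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  sw <- g / rowSums(g)
  colnames(sw) <- names(alpha)
  sw
}

#' Synthetic reference signatures for two-stage deconvolution
#'
#' Stage-1 probes discriminate epithelial / fibroblast / immune (all immune
#' subtypes share a value per stage-1 probe); stage-2 probes discriminate the
#' blood subtypes, with the non-immune types assigned the prior-weighted
#' immune centroid there (the approximation the two-stage method itself
#' rests on). The stage-1 `immune` column is the prior-weighted centroid of
#' the subtype signatures.
#'
#' @param config a [simulation_config].
#' @param seed RNG seed.
#' @return list: `stage1` (probes x 3), `stage2` (probes x 6), `full`
#'   (all reference probes x 8 cell types, used by the generator), and
#'   `prior` (subtype composition prior).
#' @export
make_reference_signatures <- function(config,
                                      seed = substream(config$seed, "reference")) {
  set.seed(seed)
  nr <- config$n_ref_probes
  subs <- c("CD8T", "CD4T", "B", "NK", "monocyte", "neutrophil")
  broad <- c("epithelial", "fibroblast")
  alpha <- config$mixture_alpha
  prior <- alpha[subs] / sum(alpha[subs])

  p1 <- sprintf("ref1_%04d", seq_len(nr))
  p2 <- sprintf("ref2_%04d", seq_len(nr))
  # stage-1 probes: one value per broad type; subtypes share the immune value
  s1_broad <- matrix(stats::runif(nr * 2, 0.05, 0.95), nr, 2,
                     dimnames = list(p1, broad))
  s1_immune <- stats::runif(nr, 0.05, 0.95)
  # stage-2 probes: one value per subtype; epithelial/fibroblast take the
  # prior-weighted subtype centroid
  s2_sub <- matrix(stats::runif(nr * length(subs), 0.05, 0.95), nr, length(subs),
                   dimnames = list(p2, subs))
  s2_centroid <- drop(s2_sub %*% prior)

  full <- rbind(
    cbind(s1_broad, matrix(s1_immune, nr, length(subs),
                           dimnames = list(p1, subs))),
    cbind(matrix(s2_centroid, nr, 2, dimnames = list(p2, broad)), s2_sub))
  stage1 <- cbind(s1_broad, immune = s1_immune)
  list(stage1 = stage1, stage2 = s2_sub, full = full[, c(broad, subs)],
       prior = prior)
}

#' Simulate a methylation cohort for a clock
#'
#' Beta values follow
#' `clamp01(baseline_j + slope_j * z_i + noise)`, where `z_i` is the
#' standardized *effective* age — chronological age plus a latent
#' person-level aging offset (SD `biol_sd` years) that the calibrated clock
#' reads out as delta age. Driver probes instead carry
#' `0.5 + driver_beta_sd * m_i` with `m_i` the latent standard-normal
#' mortality factor. Cell fractions are Dirichlet; reference probes mix the
#' cell-type signatures accordingly. Clamping to `[0,1]` happens after noise
#' (a documented small bias at the extremes).
#'
#' @param config a [simulation_config].
#' @param planted output of [plant_drivers()] (or [simulate_clock()] when no
#'   drivers are wanted).
#' @param reference output of [make_reference_signatures()].
#' @param seed RNG seed.
#' @return list: `beta` (samples x clock+reference probes, fully observed),
#'   `age`, `sex`, `cohort`, `wave`, `fractions` (true mixtures),
#'   `biol_offset`, `driver_signal`.
#' @export
simulate_methylation <- function(config, planted, reference,
                                 seed = substream(config$seed, "methylation")) {
  set.seed(seed)
  n <- config$n_samples
  clock <- planted$clock
  probes <- clock$probe_ids
  sample_ids <- sprintf("s%05d", seq_len(n))

  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  sex <- sample(c("F", "M"), n, replace = TRUE)
  cohort <- sample(c("C1921", "C1936"), n, replace = TRUE)
  wave <- sample(paste0("W", 1:4), n, replace = TRUE)
  fractions <- rdirichlet(n, config$mixture_alpha)
  rownames(fractions) <- sample_ids
  g <- stats::rnorm(n, 0, config$biol_sd)          # latent aging offset, years
  m_sig <- stats::rnorm(n)                          # latent driver signal

  mid <- mean(config$age_range)
  half <- diff(config$age_range) / 2
  z <- (age + g - mid) / half
  beta_clock <- outer(rep(1, n), planted$baseline[probes]) +
    outer(z, planted$slope[probes]) +
    matrix(stats::rnorm(n * length(probes), 0, config$noise_sd), n)
  colnames(beta_clock) <- probes
  if (length(planted$driver_ids)) {
    for (d in planted$driver_ids) {
      beta_clock[, d] <- 0.5 + config$driver_beta_sd * m_sig +
        stats::rnorm(n, 0, config$noise_sd / 3)
    }
  }
  ref_sig <- reference$full
  beta_ref <- fractions[, colnames(ref_sig)] %*% t(ref_sig) +
    matrix(stats::rnorm(n * nrow(ref_sig), 0, config$noise_sd), n)
  beta <- cbind(beta_clock, beta_ref)
  beta[beta < 0] <- 0
  beta[beta > 1] <- 1
  rownames(beta) <- sample_ids
  list(beta = beta, age = age, sex = sex, cohort = cohort, wave = wave,
       fractions = fractions, biol_offset = g, driver_signal = m_sig)
}

#' Simulate right-censored survival on the age timescale
#'
#' Event ages are drawn by inverse transform from the configured baseline
#' cumulative hazard `H0` with multiplier `exp(eta)`, conditional on survival
#' to the entry age: `H0(T) = H0(entry) + E / exp(eta)`, `E ~ Exp(1)`.
#' Censoring is administrative at `min(entry + follow_up, censor_age)`.
#'
#' @param config a [simulation_config].
#' @param s_delta standardized delta ages (finite).
#' @param entry_age chronological age at last measurement (0 for
#'   unconditional draws).
#' @param covariate_lp extra linear predictor (e.g. a sex effect), default 0.
#' @param seed RNG seed.
#' @return data frame `surv_age`, `status`.
#' @export
simulate_survival <- function(config, s_delta, entry_age = 0, covariate_lp = 0,
                              seed = substream(config$seed, "survival")) {
  if (any(!is.finite(s_delta))) stop("s_delta must be finite")
  set.seed(seed)
  n <- length(s_delta)
  entry_age <- rep_len(entry_age, n)
  covariate_lp <- rep_len(covariate_lp, n)
  eta <- config$b_true * s_delta + covariate_lp
  bh <- config$baseline_hazard
  H <- switch(bh$dist,
              weibull = function(t) (t / bh$scale)^bh$shape,
              exponential = function(t) bh$rate * t,
              stop("unknown baseline hazard: ", bh$dist))
  Hinv <- switch(bh$dist,
                 weibull = function(h) bh$scale * h^(1 / bh$shape),
                 exponential = function(h) h / bh$rate)
  if (bh$dist == "weibull" && (bh$shape <= 0 || bh$scale <= 0)) {
    stop("invalid Weibull parameters")
  }
  if (bh$dist == "exponential" && bh$rate <= 0) stop("invalid exponential rate")
  ev <- Hinv(H(entry_age) + stats::rexp(n) / exp(eta))
  cens <- pmin(entry_age + config$follow_up, config$censor_age)
  data.frame(surv_age = pmin(ev, cens), status = as.integer(ev <= cens))
}

#' Simulate a complete synthetic cohort with known ground truth
#'
#' Runs the full generative chain — clock, driver planting, reference
#' signatures, methylation, platform mask, clock application, survival — and
#' returns everything the analysis pipeline consumes plus a truth ledger
#' sufficient to score every recovery test. Planted drivers are always
#' retained by the platform mask; the retained clock-probe count is exactly
#' `floor(retention * n_probes)`.
#'
#' @param config a [simulation_config].
#' @return a `synthetic_cohort` list: `beta` (masked), `beta_full`, `clock`,
#'   `table` (cohort table with true fraction covariates and the analysis
#'   `s_delta`), `predictions`, `references`, `annotation`, `truth`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  sim <- simulate_clock(config)
  planted <- plant_drivers(sim, config)
  ref <- make_reference_signatures(config)
  meth <- simulate_methylation(config, planted, ref)

  set.seed(substream(config$seed, "mask"))
  n_keep <- floor(config$retention * config$n_probes)
  drivers <- planted$driver_ids
  pool <- setdiff(planted$clock$probe_ids, drivers)
  retained <- c(drivers, sample(pool, max(0, n_keep - length(drivers))))
  beta <- apply_platform_mask(meth$beta,
                              c(retained, rownames(ref$full)))

  pred <- clock_ages(beta[, planted$clock$probe_ids, drop = FALSE],
                     planted$clock, meth$age)
  lp_cov <- ifelse(meth$sex == "M",
                   unname(config$covariate_loghr["Sex"]), 0)
  lp_cov[is.na(lp_cov)] <- 0
  surv <- simulate_survival(config, pred$s_delta, entry_age = meth$age,
                            covariate_lp = lp_cov)

  fr <- meth$fractions
  table <- data.frame(sample_id = rownames(beta),
                      Age = meth$age, Sex = meth$sex, Cohort = meth$cohort,
                      Timepoint = meth$wave,
                      N = fr[, "neutrophil"],
                      L = fr[, "CD8T"] + fr[, "B"] + fr[, "CD4T"],
                      M = fr[, "monocyte"],
                      NI = fr[, "fibroblast"] + fr[, "epithelial"],
                      s_delta = pred$s_delta,
                      surv_age = surv$surv_age, status = surv$status,
                      row.names = NULL)

  set.seed(substream(config$seed, "annotation"))
  probes <- planted$clock$probe_ids
  gene <- sprintf("GENE%05d", sample.int(round(length(probes) * 0.9),
                                         length(probes), replace = TRUE))
  gene[stats::runif(length(probes)) > config$annotation_rate] <- NA_character_
  annotation <- data.frame(probe_id = probes, gene = gene)

  structure(
    list(beta = beta, beta_full = meth$beta, clock = planted$clock,
         table = table, predictions = pred,
         references = ref[c("stage1", "stage2")],
         annotation = annotation,
         truth = list(driver_ids = drivers,
                      driver_weight = planted$driver_weight,
                      b_true = config$b_true,
                      retained = retained,
                      fractions = fr,
                      biol_offset = meth$biol_offset,
                      driver_signal = meth$driver_signal,
                      baseline = planted$baseline, slope = planted$slope,
                      config = config)),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf("Synthetic cohort: %d samples, %d clock probes (%d retained), %d events\n",
              nrow(x$beta), length(x$clock$probe_ids),
              length(x$truth$retained), sum(x$table$status)))
  cat(sprintf("  true log-HR per SD: %.4f; drivers: %s\n", cfg$b_true,
              if (length(x$truth$driver_ids)) paste(x$truth$driver_ids, collapse = ", ")
              else "none"))
  invisible(x)
}

#' Simulate gene sets over a gene universe
#'
#' Draws `n_sets` random gene sets plus, optionally, one set enriched in a
#' given gene list (for power checks of the over-representation test).
#'
#' @param universe character vector of gene symbols.
#' @param n_sets number of random sets.
#' @param set_size size of each set.
#' @param enriched_in optional gene list; when given, one extra set
#'   (`"enriched_set"`) draws half its members from this list.
#' @param seed RNG seed.
#' @return named list of character vectors (GMT-compatible).
#' @export
simulate_gene_sets <- function(universe, n_sets = 20, set_size = 50,
                               enriched_in = NULL, seed = 1) {
  set.seed(seed)
  sets <- lapply(seq_len(n_sets), function(i) sample(universe, min(set_size, length(universe))))
  names(sets) <- sprintf("random_set_%02d", seq_len(n_sets))
  if (!is.null(enriched_in) && length(enriched_in)) {
    k <- min(set_size %/% 2, length(enriched_in))
    sets$enriched_set <- unique(c(sample(enriched_in, k),
                                  sample(universe, set_size - k)))
  }
  sets
}
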
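min_table <- function(time, status, x) {
  data.frame(sample_id = seq_along(time), surv_age = time, status = status,
             x = x, Age = 70)
}

test_that("a covariate with symmetric event patterns gets coefficient zero", {
  # two groups, identical event-time patterns
  tab <- min_table(time = c(1, 2, 3, 1, 2, 3),
                   status = c(1, 1, 0, 1, 1, 0),
                   x = c(0, 0, 0, 1, 1, 1))
  fit <- fit_cox(tab, terms = "x")
  expect_equal(unname(coef(fit)), 0, tolerance = 1e-8)
  expect_equal(fit$table$hr, 1, tolerance = 1e-8)
})

test_that("fitted coefficient maximizes the exact partial likelihood (n=5 toy)", {
  tab <- min_table(time = c(2.1, 3.7, 1.4, 5.2, 4.4),
                   status = c(1, 1, 1, 0, 1),
                   x = c(0.5, -1.2, 0.3, 1.8, -0.7))
  fit <- fit_cox(tab, terms = "x", ties = "breslow")
  oracle <- grid_cox_oracle(tab$surv_age, tab$status, tab$x)
  expect_equal(unname(coef(fit)), oracle, tolerance = 2e-4)
})

test_that("degenerate model inputs are rejected", {
  tab <- min_table(time = 1:6, status = c(1, 1, 1, 0, 0, 1), x = rep(2, 6))
  expect_error(fit_cox(tab, terms = "x"), "constant")
  tab2 <- min_table(time = 1:6, status = rep(0, 6), x = rnorm(6))
  expect_error(fit_cox(tab2, terms = "x"), "no events")
  tab3 <- min_table(time = 1:6, status = c(1, 1, 1, 0, 0, 1), x = rnorm(6))
  tab3$status[2] <- 2
  expect_error(fit_cox(tab3, terms = "x"), "status")
})

test_that("FDR adjustment is Benjamini-Hochberg step-up", {
  expect_equal(adjust_fdr(0.03), 0.03)
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(c(1, 1)), c(1, 1))
  expect_error(adjust_fdr(c(0.1, 1.2)), "\\[0,1\\]")
  set.seed(41)
  for (i in 1:20) {
    p <- runif(sample(2:50, 1))^sample(1:3, 1)
    expect_equal(adjust_fdr(p), bh_stepup_oracle(p))
  }
})

test_that("q-values never undercut p-values and respect CI bracketing", {
  set.seed(42)
  tab <- min_table(time = rexp(80, 0.1), status = rbinom(80, 1, 0.6),
                   x = rnorm(80))
  tab$y <- rnorm(80); tab$z <- rnorm(80)
  fit <- fit_cox(tab, terms = c("x", "y", "z"))
  expect_true(all(fit$table$q >= fit$table$p - 1e-12))
  expect_true(all(fit$table$ci_low <= fit$table$hr & fit$table$hr <= fit$table$ci_high))
})

test_that("delta stratification uses [-3,0), [0,3), [3,6] with terminal-bin clamping", {
  expect_equal(as.character(stratify_sdelta(c(-1.2, 0, 2.9, 3, 5.9))),
               c("[-3,0)", "[0,3)", "[0,3)", "[3,6]", "[3,6]"))
  expect_warning(out <- stratify_sdelta(c(7.1, -4)), "terminal")
  expect_equal(as.character(out), c("[3,6]", "[-3,0)"))
})

test_that("categorical fit contrasts strata against the lowest-delta group", {
  set.seed(43)
  n <- 2000
  s <- c(runif(n / 2, -2.5, 0), runif(n / 2 - 100, 0, 3), runif(100, 3, 6))
  lam <- 0.08 * ifelse(s >= 3, 2, 1)             # planted 2x hazard on top bin
  ev <- rexp(n, lam)
  tab <- data.frame(sample_id = 1:n, surv_age = pmin(ev, 15),
                    status = as.integer(ev <= 15), s_delta = s, Age = 70)
  fit <- fit_cox_categorical(tab, covariates = character(0))
  hr_top <- fit$table$hr[grepl("\\[3,6\\]", fit$table$term)]
  expect_gt(hr_top, 1.5)
  expect_lt(hr_top, 2.6)
  expect_error(fit_cox_categorical(tab[tab$s_delta < 0, ], covariates = character(0)),
               "one stratum")
})

test_that("identical outcome strata give hazard ratio one", {
  tab <- data.frame(sample_id = 1:8,
                    surv_age = rep(c(1, 2, 3, 4), 2),
                    status = rep(c(1, 1, 0, 1), 2),
                    s_delta = rep(c(-1, 4), each = 4), Age = 70)
  fit <- fit_cox_categorical(tab, covariates = character(0))
  expect_equal(fit$table$hr, 1, tolerance = 1e-6)
})

test_that("Breslow baseline with null covariates is the Nelson-Aalen estimator", {
  time <- c(1, 2, 3, 4); status <- c(1, 1, 1, 1)
  H <- breslow_cumhaz(time, status)
  expect_equal(H$hazard, cumsum(c(1 / 4, 1 / 3, 1 / 2, 1)))
  # against survival's own Nelson-Aalen on a larger censored set
  set.seed(44)
  t2 <- rexp(60, 0.2); s2 <- rbinom(60, 1, 0.7)
  H2 <- breslow_cumhaz(t2, s2)
  sf <- survival::survfit(survival::Surv(t2, s2) ~ 1, ctype = 1)
  expect_equal(H2$hazard, sf$cumhaz[sf$n.event > 0], tolerance = 1e-12)
})

test_that("marginal curves reproduce the hand-computed worked example", {
  tab <- data.frame(sample_id = 1:4, surv_age = 1:4, status = 1,
                    s_delta = 0, Age = 70)
  fit <- fit_cox(tab, terms = character(0))
  curves <- marginal_survival(fit, strata = factor(rep("all", 4)))
  expect_equal(curves$survival[curves$age == 2], exp(-(1 / 4 + 1 / 3)),
               tolerance = 1e-12)
  expect_equal(curves$survival[curves$age == 3], exp(-(1 / 4 + 1 / 3 + 1 / 2)),
               tolerance = 1e-12)
  expect_equal(unname(attr(curves, "medians")["all"]), 3)
})

test_that("marginal curves are proper survival curves", {
  set.seed(45)
  n <- 150
  tab <- data.frame(sample_id = 1:n, surv_age = rexp(n, 0.1) + 1,
                    status = rbinom(n, 1, 0.6), s_delta = rnorm(n), Age = 70)
  tab$surv_age <- pmin(tab$surv_age, 20)
  tab$status[tab$surv_age == 20] <- 0
  fit <- fit_cox(tab, terms = "s_delta")
  strata <- factor(ifelse(tab$s_delta > 0, "hi", "lo"))
  curves <- marginal_survival(fit, strata)
  for (lv in levels(strata)) {
    s <- curves$survival[curves$stratum == lv]
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s >= 0 & s <= 1))
  }
  # a stratum of identical covariate rows: marginal curve = individual curve
  tab2 <- tab; tab2$s_delta <- 1.3
  fit2 <- fit_cox(tab, terms = "s_delta")
  st2 <- factor(rep("same", n))
  c_ind <- exp(-fit2$baseline$hazard * exp(fit2$lp[1]))
  same_rows <- marginal_survival(
    structure(modifyList(fit2, list(lp = rep(fit2$lp[1], n))), class = "cox_assoc"),
    st2)
  expect_equal(same_rows$survival, c_ind, tolerance = 1e-12)
})

test_that("all-censored strata never cross the median", {
  tab <- data.frame(sample_id = 1:10, surv_age = 1:10,
                    status = c(rep(1, 5), rep(0, 5)),
                    s_delta = rep(c(-1, 1), each = 5), Age = 70)
  fit <- fit_cox(tab, terms = character(0))
  # stratum "cens" members all censored and late: survival stays high there
  curves <- marginal_survival(fit, factor(rep(c("ev", "cens"), each = 5)))
  med <- attr(curves, "medians")
  expect_true(is.na(med["cens"]) || med["cens"] > med["ev"])
})

test_that("small-sample fits match the grid oracle across many random datasets", {
  set.seed(46)
  n_ok <- 0
  for (rep in 1:25) {
    d <- random_cox_dataset(n = 4 + (rep %% 5), seed = 4600 + rep)
    tab <- min_table(d$time, d$status, d$x)
    fit <- tryCatch(suppressWarnings(fit_cox(tab, terms = "x", ties = "breslow")),
                    error = function(e) NULL)
    if (is.null(fit)) next                     # separation: legitimately rejected
    if (abs(coef(fit)) > 4.5) next             # outside the oracle grid
    oracle <- grid_cox_oracle(d$time, d$status, d$x)
    expect_lt(abs(unname(coef(fit)) - oracle), 1e-3)
    n_ok <- n_ok + 1
  }
  expect_gte(n_ok, 15)
})
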
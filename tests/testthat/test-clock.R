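test_that("clock definition enforces its invariants", {
  expect_s3_class(toy_clock(), "clock_definition")
  # smallest valid clock: 2 probes, 1 cluster
  c1 <- clock_definition(c("p1", "p2"), c("k", "k"), c(k = 1), intercept = 0)
  expect_length(c1$cluster_weights, 1)
  expect_error(clock_definition(c("p1", "p1"), c("k", "k"), c(k = 1)),
               "duplicate probe")
  expect_error(clock_definition(c("p1", "p2"), c("k", "z"), c(k = 1)),
               "unknown cluster")
  expect_error(clock_definition(c("p1", "p2"), c("k", "k"), c(k = 1, empty = 2)),
               "no probes")
  expect_error(clock_definition(c("p1", "p2"), c("k", "k"), c(k = NaN)),
               "non-finite")
})

test_that("clock definitions round-trip through JSON and TSV dialects", {
  set.seed(42)
  n <- 1000
  probes <- sprintf("cg%06d", sample.int(9e5, n))
  clusters <- sprintf("cl%03d", c(1:50, sample.int(50, n - 50, replace = TRUE)))
  w <- stats::setNames(rnorm(50), sprintf("cl%03d", 1:50))
  clock <- clock_definition(probes, clusters, w, intercept = 12.34, name = "rt")

  json <- withr::local_tempfile(fileext = ".json")
  write_clock_definition(clock, json)
  back <- read_clock_definition(json)
  expect_equal(back$probe_ids, clock$probe_ids)
  expect_equal(back$cluster_of, clock$cluster_of)
  expect_equal(back$cluster_weights, clock$cluster_weights)
  expect_equal(back$intercept, clock$intercept)
  expect_identical(back$name, clock$name)

  # TSV + sidecar dialect
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(probe_id = clock$probe_ids,
                         cluster_id = unname(clock$cluster_of)),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(name = "rt", intercept = 12.34,
                            form = "linear_cluster_mean",
                            cluster_weights = as.list(w)),
                       sub("\\.tsv$", ".json", tsv), auto_unbox = TRUE, digits = NA)
  back2 <- read_clock_definition(tsv)
  expect_equal(back2$cluster_weights, clock$cluster_weights)
  expect_equal(back2$cluster_of, clock$cluster_of)
})

test_that("cluster averaging removes missing inputs and zeroes empty clusters", {
  cl <- toy_clock()
  b <- toy_beta()
  v <- compute_cluster_values(b, cl)
  expect_equal(v["s1", "k1"], 0.3)            # mean(0.2, 0.4)
  expect_equal(v["s1", "k2"], 0.3)            # mean(0.1, 0.3, 0.5)
  expect_equal(v["s2", "k1"], 0.6)            # missing cgB dropped
  expect_equal(v["s2", "k2"], 0.2)            # only cgC available
  # all probes of a cluster missing -> 0
  b2 <- b
  b2["s2", c("cgC", "cgD", "cgE")] <- NA
  expect_equal(compute_cluster_values(b2, cl)["s2", "k2"], 0)
  # probes absent from the matrix behave like missing values
  b3 <- b[, c("cgA", "cgC"), drop = FALSE]
  v3 <- compute_cluster_values(b3, cl)
  expect_equal(v3["s1", "k1"], 0.2)
  expect_equal(v3["s1", "k2"], 0.1)
})

test_that("cluster averaging matches a brute-force loop on random matrices", {
  set.seed(11)
  for (rep in 1:5) {
    n_probe <- 40
    probes <- sprintf("p%02d", 1:n_probe)
    clock <- clock_definition(probes,
                              sprintf("k%d", c(1:8, sample.int(8, n_probe - 8, TRUE))),
                              stats::setNames(rnorm(8), sprintf("k%d", 1:8)),
                              intercept = rnorm(1))
    beta <- matrix(runif(10 * n_probe), 10,
                   dimnames = list(sprintf("s%d", 1:10), probes))
    beta[sample(length(beta), 80)] <- NA
    expect_equal(compute_cluster_values(beta, clock),
                 cluster_means_oracle(beta, clock))
  }
})

test_that("age prediction is the linear combination of cluster values", {
  # one cluster, weight 2, value 0.5, intercept 10 -> 11
  cl <- clock_definition(c("p1", "p2"), c("k", "k"), c(k = 2), intercept = 10)
  v <- matrix(0.5, 1, 1, dimnames = list("s1", "k"))
  expect_equal(unname(predict_epigenetic_age(v, cl)), 11)
  # all weights zero -> intercept for every sample
  cl0 <- clock_definition(c("p1", "p2"), c("k1", "k2"), c(k1 = 0, k2 = 0),
                          intercept = 33)
  v0 <- matrix(runif(6), 3, 2, dimnames = list(NULL, c("k1", "k2")))
  expect_equal(unname(predict_epigenetic_age(v0, cl0)), rep(33, 3))
  expect_error(predict_epigenetic_age(v0[, 1, drop = FALSE], cl0), "mismatch")
})

test_that("prediction equals an independent dot product for a 50-cluster clock", {
  set.seed(3)
  k <- 50
  cl <- clock_definition(sprintf("p%02d", 1:k), sprintf("k%02d", 1:k),
                         stats::setNames(rnorm(k), sprintf("k%02d", 1:k)),
                         intercept = rnorm(1))
  v <- matrix(runif(20 * k), 20, k, dimnames = list(NULL, sprintf("k%02d", 1:k)))
  oracle <- apply(v, 1, function(row) sum(row * cl$cluster_weights) + cl$intercept)
  expect_equal(unname(predict_epigenetic_age(v, cl)), oracle, tolerance = 1e-12)
})

test_that("prediction is linear in the cluster weights", {
  set.seed(4)
  cl <- toy_clock()
  b <- toy_beta()
  v <- compute_cluster_values(b, cl)
  p1 <- predict_epigenetic_age(v, cl)
  cl2 <- clock_definition(cl$probe_ids, unname(cl$cluster_of),
                          cl$cluster_weights * 3, intercept = cl$intercept)
  p2 <- predict_epigenetic_age(v, cl2)
  expect_equal(p2 - cl$intercept, (p1 - cl$intercept) * 3)
})

test_that("delta standardization divides by the sample SD", {
  p <- standardize_delta(c(6, 4), c(5, 5))
  expect_equal(p$s_delta, c(1, -1) / sqrt(2), tolerance = 1e-12)
  expect_error(standardize_delta(rep(9, 4), rep(4, 4)), "zero")
  set.seed(5)
  pred <- rnorm(500, 70, 8)
  p2 <- standardize_delta(pred, rnorm(500, 70, 5))
  expect_equal(sd(p2$s_delta), 1, tolerance = 1e-12)
  expect_equal(p2$delta, p2$predicted_age - p2$chronological_age)
})

test_that("accuracy metrics match their textbook formulas", {
  x <- c(60, 70, 80)
  expect_equal(accuracy_metrics(x, x), list(R2 = 1, MAE = 0, RMSE = 0))
  off <- accuracy_metrics(x + 1, x)
  expect_equal(off$MAE, 1); expect_equal(off$RMSE, 1); expect_equal(off$R2, 1)
  set.seed(6)
  a <- rnorm(20, 75, 6); b <- a + rnorm(20, 0, 3)
  m <- accuracy_metrics(b, a)
  expect_equal(m$R2, (sum((a - mean(a)) * (b - mean(b))) /
                      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2)))^2,
               tolerance = 1e-10)
  expect_equal(m$MAE, sum(abs(b - a)) / 20, tolerance = 1e-10)
  expect_equal(m$RMSE, sqrt(sum((b - a)^2) / 20), tolerance = 1e-10)
  expect_true(is.na(accuracy_metrics(rep(1, 5), 1:5)$R2))
})

test_that("platform masking hides exactly the dropped probes", {
  b <- toy_beta()
  expect_equal(apply_platform_mask(b, colnames(b)), b)
  all_gone <- apply_platform_mask(b, character(0))
  expect_true(all(is.na(all_gone)))
  expect_equal(unname(compute_cluster_values(all_gone, toy_clock())),
               matrix(0, 2, 2))
  # random 50% retention of 2000 probes -> availability fraction exactly 0.5
  set.seed(8)
  probes <- sprintf("p%04d", 1:2000)
  big <- matrix(runif(3 * 2000), 3, dimnames = list(c("a", "b", "c"), probes))
  kept <- sample(probes, 1000)
  masked <- apply_platform_mask(big, kept)
  expect_equal(mean(!is.na(masked)), 0.5)
  expect_equal(masked[, kept], big[, kept])
})

test_that("masked predictions equal full predictions when masked probes carry cluster-mean values", {
  # if every masked probe's value equals its cluster's mean over retained
  # probes, removing it cannot change the cluster average
  set.seed(9)
  cl <- toy_clock()
  b <- matrix(runif(10), 2, 5,
              dimnames = list(c("s1", "s2"), cl$probe_ids))
  b[, "cgB"] <- b[, "cgA"]                       # k1: masked cgB == retained mean
  b[, "cgE"] <- (b[, "cgC"] + b[, "cgD"]) / 2    # k2: masked cgE == retained mean
  masked <- apply_platform_mask(b, c("cgA", "cgC", "cgD"))
  vf <- compute_cluster_values(b, cl)
  vm <- compute_cluster_values(masked, cl)
  expect_equal(vm, vf, tolerance = 1e-12)
  expect_equal(predict_epigenetic_age(vm, cl), predict_epigenetic_age(vf, cl))
})

test_that("beta matrices reject out-of-range values and round-trip through TSV", {
  b <- toy_beta()
  bad <- b; bad["s1", "cgA"] <- 1.2
  expect_error(validate_beta(bad), "out of \\[0,1\\]")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_beta_matrix(b, path)
  expect_equal(read_beta_matrix(path), b)
})
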
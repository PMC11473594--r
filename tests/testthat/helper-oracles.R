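# Independent oracles used across the suite. Each is a deliberately naive
# implementation, kept separate from the package's code paths.

# Benjamini-Hochberg step-up, written straight from the definition:
# q_(i) = min over j >= i of p_(j) * m / j.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(ranked)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Exact Cox partial log-likelihood for untied data, one covariate.
partial_loglik_1cov <- function(beta, time, status, x) {
  ll <- 0
  for (i in which(status == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Dense grid maximization of the exact partial likelihood. Evaluates the
# whole beta grid at once (rows = grid points): for untied data
# ll(b) = sum_events [ b*x_i - log( sum_{t_j >= t_i} exp(b*x_j) ) ].
grid_cox_oracle <- function(time, status, x, lo = -5, hi = 5, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  E <- exp(outer(grid, x))                   # G x n
  ll <- numeric(length(grid))
  for (i in which(status == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + grid * x[i] -
      log(if (length(risk) > 1) rowSums(E[, risk, drop = FALSE]) else E[, risk])
  }
  grid[which.max(ll)]
}

# Brute-force per-cluster means under missingness (the quoted averaging rule).
cluster_means_oracle <- function(beta, clock) {
  clusters <- names(clock$cluster_weights)
  out <- matrix(0, nrow(beta), length(clusters),
                dimnames = list(rownames(beta), clusters))
  for (i in seq_len(nrow(beta))) {
    for (k in seq_along(clusters)) {
      probes <- clock$probe_ids[clock$cluster_of == clusters[k]]
      vals <- beta[i, intersect(probes, colnames(beta))]
      vals <- vals[!is.na(vals)]
      out[i, k] <- if (length(vals)) mean(vals) else 0
    }
  }
  out
}

# Grid search over the probability simplex at a given resolution.
simplex_grid_oracle <- function(A, b, resolution = 0.01) {
  k <- ncol(A)
  steps <- round(1 / resolution)
  grid_rec <- function(remaining, left) {
    if (remaining == 1) return(matrix(left, 1, 1))
    parts <- lapply(0:left, function(v) {
      sub <- grid_rec(remaining - 1, left - v)
      cbind(v, sub)
    })
    do.call(rbind, parts)
  }
  pts <- grid_rec(k, steps) * resolution
  obj <- apply(pts, 1, function(x) sum((A %*% x - b)^2))
  pts[which.min(obj), ]
}

# Tiny deterministic fixtures ------------------------------------------------

toy_clock <- function() {
  clock_definition(
    probe_ids = c("cgA", "cgB", "cgC", "cgD", "cgE"),
    cluster_of = c("k1", "k1", "k2", "k2", "k2"),
    cluster_weights = c(k1 = 2, k2 = -1),
    intercept = 10, name = "toy")
}

toy_beta <- function() {
  m <- matrix(c(0.2, 0.4, 0.1, 0.3, 0.5,
                0.6, NA,  0.2, NA,  NA),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"),
                              c("cgA", "cgB", "cgC", "cgD", "cgE")))
  m
}

# Small untied survival datasets for the partial-likelihood oracle.
random_cox_dataset <- function(n, seed) {
  set.seed(seed)
  x <- rnorm(n)
  time <- round(rexp(n, 0.2), 6)
  while (anyDuplicated(time)) time <- time + runif(n, 0, 1e-4)
  status <- rbinom(n, 1, 0.8)
  if (sum(status) == 0) status[1] <- 1
  list(time = time, status = status, x = x)
}

# Dirichlet draws for mixture fixtures.
rdirichlet_test <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  out <- g / rowSums(g)
  colnames(out) <- names(alpha)
  out
}
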
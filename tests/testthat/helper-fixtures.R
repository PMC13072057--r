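# Shared toy fixtures and independent oracles, built in code.

# scratch space shared between blocks of a test file (e.g. reusing the
# simulated cohort metrics for the particle-scaling check)
.accept_cache <- new.env(parent = emptyenv())

# three-compartment toy circulation: volumes 1/2/2 L, flows 2/1.5/3 L/min
toy_model <- function(in_field = TRUE) {
  custom_circulation_model(c("a", "b", "c"),
                           blood_volume = c(1000, 2000, 2000),
                           blood_flow = c(2000, 1500, 3000),
                           in_field = in_field)
}

# survival dropping linearly from 1 at 0 Gy to 0 at dmax
linear_dvh <- function(dmax = 10, bin = 0.01) {
  grid <- seq(0, dmax, by = bin)
  dvh(grid, 1 - grid / dmax)
}

# piecewise-linear survival through (dose, volume) anchor points
anchored_dvh <- function(anchors_d, anchors_v, bin = 0.01) {
  dvh_from_function(function(d) approx(anchors_d, anchors_v, xout = d, rule = 2)$y,
                    max_dose = max(anchors_d), bin_width = bin)
}

# brute-force Dn%: largest dose on a very fine grid whose interpolated
# volume fraction still reaches q (independent of the package's inverse)
oracle_d_at_volume <- function(x, n, step = 1e-4) {
  q <- n / 100
  fine <- seq(0, max(x$dose), by = step)
  v <- approx(x$dose, x$volume, xout = fine)$y
  fine[max(which(v >= q - 1e-12))]
}

oracle_v_at_dose <- function(x, d, step = 1e-4) {
  approx(x$dose, x$volume, xout = d, rule = 2)$y
}

# exact two-sided signed-rank p by enumerating all 2^n sign patterns
oracle_wilcoxon_exact <- function(a, b) {
  d <- (a - b)
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  m <- n * (n + 1) / 4  # center of the null distribution
  mean(abs(v_all - m) >= abs(v_obs - m) - 1e-9)
}

# Friedman statistic computed from scratch (average ranks)
oracle_friedman_stat <- function(x) {
  n <- nrow(x); k <- ncol(x)
  r <- t(apply(x, 1, rank))
  (12 / (n * k * (k + 1))) * sum((colSums(r) - n * (k + 1) / 2)^2)
}

# exhaustive within-row permutation p for the Friedman statistic,
# written as a plain loop (independent of the package's vectorized path)
oracle_friedman_perm <- function(x) {
  n <- nrow(x); k <- ncol(x)
  obs <- oracle_friedman_stat(x)
  perms <- as.matrix(expand.grid(rep(list(seq_len(k)), k)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == k), , drop = FALSE]
  combos <- expand.grid(rep(list(seq_len(nrow(perms))), n))
  cnt <- 0L
  for (i in seq_len(nrow(combos))) {
    y <- x
    for (row in seq_len(n)) y[row, ] <- x[row, perms[combos[i, row], ]]
    if (oracle_friedman_stat(y) >= obs - 1e-9) cnt <- cnt + 1L
  }
  cnt / nrow(combos)
}
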
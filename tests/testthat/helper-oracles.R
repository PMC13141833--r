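# Independent oracles and shared fixtures. The oracles deliberately use
# direct brute-force formulations (normal equations, exhaustive confusion
# counts, full enumeration of group assignments) so they share no code path
# with the implementation they check.

# Weighted least squares of y on (1, g) via explicit normal equations,
# returning the group coefficient and its two-sided t-test p-value.
wls_oracle <- function(y, g, w = rep(1, length(y))) {
  X <- cbind(1, g)
  XtWX <- t(X) %*% (w * X)
  beta <- solve(XtWX, t(X) %*% (w * y))
  resid <- y - X %*% beta
  sigma2 <- sum(w * resid^2) / (length(y) - 2L)
  se <- unname(sqrt(diag(solve(XtWX)) * sigma2)[2L])
  tval <- unname(beta[2L]) / se
  c(coefficient = unname(beta[2L]),
    p = unname(2 * stats::pt(-abs(tval), length(y) - 2L)))
}

# Exhaustive confusion-matrix oracle for a strict > threshold classifier.
confusion_oracle <- function(values, labels, threshold) {
  tp <- 0L; fp <- 0L; fn <- 0L; tn <- 0L
  for (i in seq_along(values)) {
    pred <- values[i] > threshold
    if (pred && labels[i] == 1) tp <- tp + 1L
    else if (pred && labels[i] == 0) fp <- fp + 1L
    else if (!pred && labels[i] == 1) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(n_predicted_positive = tp + fp, n_true_positive = tp,
       ppv = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
       sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_)
}

# Mann-Whitney U statistic from mid-ranks.
u_statistic <- function(x1, x0) {
  r <- rank(c(x1, x0))
  sum(r[seq_along(x1)]) - length(x1) * (length(x1) + 1) / 2
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments
# (valid with ties; feasible for n1 + n2 <= 12 or so).
mw_exact_oracle <- function(x1, x0) {
  pooled <- c(x1, x0)
  n1 <- length(x1)
  n <- length(pooled)
  mu <- n1 * (n - n1) / 2
  obs <- abs(u_statistic(x1, x0) - mu)
  combs <- utils::combn(n, n1)
  hits <- 0L
  for (j in seq_len(ncol(combs))) {
    idx <- combs[, j]
    u <- u_statistic(pooled[idx], pooled[-idx])
    if (abs(u - mu) >= obs - 1e-9) hits <- hits + 1L
  }
  hits / ncol(combs)
}

# Small deterministic count matrix fixture.
toy_counts <- function(n = 12, p = 6, seed = 99) {
  m <- mycovar:::with_seed(seed,
    matrix(stats::rnbinom(n * p, mu = 20, size = 2), n, p))
  dimnames(m) <- list(sprintf("s%02d", seq_len(n)), sprintf("f%02d",
                                                            seq_len(p)))
  count_matrix(m)
}

# Cohort used by several IPTW / differential-abundance tests.
small_cohort <- function(seed = 1, n = 300, n_planted = 0, n_features = 40L,
                         ...) {
  generate_cohort(cohort_spec(n_samples = n, n_features = n_features,
                              n_batches = 2L, n_planted = n_planted,
                              seed = seed, ...))
}
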
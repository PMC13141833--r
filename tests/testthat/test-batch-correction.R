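test_that("the combination registry obeys the pipeline constraints", {
  combos <- enumerate_combinations()
  expect_length(combos, 14L)
  labels <- vapply(combos, `[[`, "", "label")
  expect_false(any(labels %in% c("RA+PLSDA", "VOOM+PLSDA")))
  for (cb in combos) {
    if (cb$correction == "MMUPHIN") expect_equal(cb$order, "correction_first")
    else expect_equal(cb$order, "transform_first")
    if (cb$correction == "PLSDA")
      expect_true(cb$transform %in% c("CLR", "CLR_C"))
  }
  expect_error(combination_spec("RA", "PLSDA"), "CLR-family")
})

test_that("bmc centers within batches; grand mean restored by default", {
  a <- matrix(c(1, 3, 5, 7), 4, 1, dimnames = list(paste0("s", 1:4), "f1"))
  batch <- c("A", "A", "B", "B")
  pure <- bmc(a, batch, restore_grand_mean = FALSE)
  expect_equal(as.numeric(pure), c(-1, 1, -1, 1))
  restored <- bmc(a, batch)
  expect_equal(as.numeric(restored), c(-1, 1, -1, 1) + 4)
  expect_equal(mean(restored), mean(a))  # pooled feature mean preserved
  for (b in c("A", "B"))
    expect_lt(abs(mean(pure[batch == b, 1])), 1e-12)
  # idempotence
  g <- small_cohort(seed = 2, n = 60)
  x <- clr(g$counts)
  once <- bmc(x, g$meta$batch)
  expect_equal(bmc(once, g$meta$batch), once, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(bmc(x, factor(rep("A", 60), levels = c("A", "B"))),
               "zero samples")
})

test_that("combat removes a pure location shift between batches", {
  # low residual noise so the empirical-Bayes estimate of the common shift
  # is precise; the planted shift dwarfs the noise by a factor of 15
  n <- 50; p <- 20; sigma <- 0.2
  base <- mycovar:::with_seed(31, matrix(rnorm(2 * n * p, 0, sigma),
                                         2 * n, p))
  delta <- 3
  shifted <- base
  shifted[(n + 1):(2 * n), ] <- shifted[(n + 1):(2 * n), ] + delta
  dimnames(shifted) <- list(sprintf("s%03d", 1:(2 * n)), sprintf("f%02d", 1:p))
  batch <- rep(c("A", "B"), each = n)
  out <- combat_correct(shifted, batch)
  gap <- colMeans(out[batch == "B", ]) - colMeans(out[batch == "A", ])
  expect_true(all(abs(gap) < 0.05 * delta))
  expect_identical(dim(out), dim(shifted))
  expect_true(all(is.finite(out)))
  # pooled feature means approximately preserved
  expect_true(all(abs(colMeans(out) - colMeans(shifted)) < 0.2))
})

test_that("combat on identical batches leaves locations untouched", {
  block <- mycovar:::with_seed(17, matrix(rnorm(10 * 6), 10, 6))
  a <- rbind(block, block)
  dimnames(a) <- list(sprintf("s%02d", 1:20), sprintf("f%01d", 1:6))
  out <- combat_correct(a, rep(c("A", "B"), each = 10))
  # batch locations are identical, so no location adjustment happens ...
  gap <- colMeans(out[1:10, ]) - colMeans(out[11:20, ])
  expect_true(all(abs(gap) < 1e-9))
  expect_true(all(abs(colMeans(out) - colMeans(a)) < 1e-9))
  # ... and the variance moderation only rescales each feature slightly
  for (j in seq_len(ncol(a)))
    expect_gt(stats::cor(out[, j], a[, j]), 1 - 1e-9)
  expect_lt(max(abs(out - a)), 0.3 * stats::sd(a))
  expect_error(combat_correct(a, c(rep("A", 19), "B")), "size 1")
  expect_error(combat_correct(a, rep("A", 20)), "two batches")
})

test_that("mmuphin-like correction preserves zeros and removes batch fold
           changes", {
  g <- small_cohort(seed = 9, n = 100, batch_effect_sd = 0,
                    rare_feature_frac = 0)
  m <- g$counts
  # plant a 4x multiplicative batch effect on half the features
  half <- seq_len(ncol(m) / 2)
  in_b2 <- g$meta$batch == "batch2"
  planted <- m
  planted[in_b2, half] <- planted[in_b2, half] * 4L
  planted <- count_matrix(planted)
  out <- mmuphin_like(planted, g$meta$batch)
  expect_identical(out == 0L, planted == 0L)
  expect_true(is.integer(out))
  gm <- function(x) exp(mean(log(x[x > 0])))
  ratios <- vapply(half, function(j)
    gm(out[in_b2, j]) / gm(out[!in_b2, j]), numeric(1))
  expect_true(all(ratios > 0.8 & ratios < 1.25))

  ra <- relative_abundance(m)
  ra_out <- mmuphin_like(ra, g$meta$batch, type = "relative_abundance")
  expect_true(all(abs(rowSums(ra_out) - 1) < 1e-9))
  expect_equal(ra_out == 0, ra == 0, ignore_attr = TRUE)
  expect_error(mmuphin_like(ra - 1, g$meta$batch), "negative")
})

test_that("plsda removes a single-direction batch shift exactly", {
  n <- 40; p <- 10
  batch <- rep(c("A", "B"), each = n / 2)
  # noiseless data whose only structure is a batch shift along feature 3
  pure <- matrix(0, n, p)
  pure[batch == "B", 3] <- 5
  dimnames(pure) <- list(sprintf("s%02d", 1:n), sprintf("f%02d", 1:p))
  out <- plsda_correct(pure, batch, k = 1)
  gap <- colMeans(out[batch == "B", , drop = FALSE]) -
    colMeans(out[batch == "A", , drop = FALSE])
  expect_true(all(abs(gap) < 1e-6))
  expect_identical(dim(out), dim(pure))
})

test_that("plsda with permuted labels barely changes the data", {
  # removing one of p components costs about 1/p of the variance, so at the
  # study scale of 40 features a null deflation changes the data by ~2.5%
  n <- 400; p <- 40
  x <- mycovar:::with_seed(41, matrix(rnorm(n * p), n, p))
  dimnames(x) <- list(sprintf("s%04d", 1:n), sprintf("f%02d", 1:p))
  batch <- mycovar:::with_seed(42, sample(rep(c("A", "B"), each = n / 2)))
  out <- plsda_correct(x, batch, k = 1)
  expect_lt(mean((out - x)^2), 0.05 * stats::var(as.numeric(x)))
  expect_error(plsda_correct(x, batch, k = 45), "smaller than")
})

test_that("plsda components agree with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  g <- small_cohort(seed = 13, n = 60)
  x <- clr(g$counts)
  batch <- g$meta$batch
  Xc <- scale(x, scale = FALSE)
  Y <- stats::model.matrix(~ factor(batch) - 1)
  fit <- mixOmics::pls(Xc, scale(Y, scale = FALSE), ncomp = 1,
                       mode = "regression", scale = FALSE)
  t_ref <- fit$variates$X[, 1]
  # reconstruct our first component
  M <- crossprod(Xc, scale(Y, scale = FALSE))
  w <- svd(M, nu = 1, nv = 0)$u[, 1]
  t_ours <- Xc %*% w
  expect_gt(abs(stats::cor(t_ours, t_ref)), 0.999)
})

test_that("every combination runs and returns finite matrices", {
  g <- small_cohort(seed = 3, n = 50, n_features = 30)
  for (cb in enumerate_combinations()) {
    out <- apply_combination(g$counts, g$meta$batch, cb)
    expect_identical(dim(out), dim(g$counts))
    expect_true(all(is.finite(out)), info = cb$label)
  }
  # explicit composition identities
  cb <- combination_spec("CLR", "BMC")
  expect_equal(apply_combination(g$counts, g$meta$batch, cb),
               bmc(clr(g$counts), g$meta$batch), ignore_attr = TRUE)
  cb2 <- combination_spec("RA", "MMUPHIN")
  expect_equal(apply_combination(g$counts, g$meta$batch, cb2),
               relative_abundance(mmuphin_like(g$counts, g$meta$batch)),
               ignore_attr = TRUE)
})
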
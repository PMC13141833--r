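test_that("contrast eligibility enforces the minimum group size", {
  g <- small_cohort(seed = 12, n = 500)
  meta <- g$meta
  cts <- eligible_contrasts(meta, min_per_group = 20)
  expect_true("cancer1:sex" %in% names(cts))
  # race expands to pairwise contrasts; each eligible iff both races have >= 20
  race_n <- table(meta$race)
  if (all(race_n[c("European", "African")] >= 20))
    expect_true("cancer1:race_EAf" %in% names(cts))
  # a factor with a 19-sample group is excluded
  meta2 <- meta
  meta2$sex <- c(rep("male", 19), rep("female", nrow(meta2) - 19))
  cts2 <- eligible_contrasts(meta2, min_per_group = 20)
  expect_false("cancer1:sex" %in% names(cts2))
  meta3 <- meta
  meta3$sex <- c(rep("male", 20), rep("female", nrow(meta3) - 20))
  expect_true("cancer1:sex" %in% names(eligible_contrasts(meta3, 20)))
})

test_that("weighted group test matches the normal-equations oracle", {
  set.seed(7)
  for (i in 1:10) {
    n <- 60
    y <- rnorm(n)
    grp <- rbinom(n, 1, 0.5)
    if (length(unique(grp)) < 2) next
    w <- if (i %% 2 == 0) runif(n, 0.5, 4) else rep(1, n)
    got <- weighted_group_test(y, grp, w)
    want <- wls_oracle(y, grp, w)
    expect_equal(got[["coefficient"]], want[["coefficient"]],
                 tolerance = 1e-10)
    expect_equal(got[["p"]], want[["p"]], tolerance = 1e-10)
  }
})

test_that("weighted group test handles null and degenerate responses", {
  y <- c(1, 2, 3, 1, 2, 3)
  grp <- c(1L, 1L, 1L, 0L, 0L, 0L)
  out <- weighted_group_test(y, grp)
  expect_equal(out[["coefficient"]], 0, tolerance = 1e-12)
  expect_gt(out[["p"]], 0.99)
  out0 <- weighted_group_test(rep(5, 6), grp)
  expect_equal(out0, c(coefficient = 0, p = 1))
})

test_that("weighted group test recovers a unit mean shift", {
  set.seed(11)
  y <- c(rnorm(500, 0), rnorm(500, 1))
  grp <- rep(c(0L, 1L), each = 500)
  out <- weighted_group_test(y, grp)
  expect_gt(out[["coefficient"]], 0.8)
  expect_lt(out[["coefficient"]], 1.2)
})

test_that("bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_adjust(0.01, 5), 0.05)
  expect_equal(bonferroni_adjust(0.5, 5), 1)
  expect_equal(bonferroni_adjust(c(0.2, 0.8)), c(0.4, 1))
  expect_equal(bonferroni_adjust(0.3, 1), 0.3)
  expect_error(bonferroni_adjust(c(0.1, 0.2), 1), "at least")
})

test_that("consensus requires significance in every combination", {
  grid <- expand.grid(species = c("sp1", "sp2", "sp3"),
                      combination = paste0("c", 1:14),
                      stringsAsFactors = FALSE)
  grid$cancer <- "c1"
  grid$factor <- "sex"
  grid$significant <- TRUE
  grid$significant[grid$species == "sp2" & grid$combination == "c14"] <- FALSE
  grid$significant[grid$species == "sp3"] <- FALSE
  out <- consensus_call(grid, 14)
  expect_equal(out$consensus[match(c("sp1", "sp2", "sp3"), out$species)],
               c(TRUE, FALSE, FALSE))
  expect_equal(out$n_significant_combinations[out$species == "sp2"], 13L)
  # incomplete grid errors
  expect_error(consensus_call(grid[-1L, ], 14), "incomplete")
  # empty input gives empty output
  empty <- consensus_call(grid[0L, ], 14)
  expect_equal(nrow(empty), 0L)
})

test_that("raw-count confirmation matches the exact-U oracle at small n", {
  counts <- toy_counts(n = 12, p = 4, seed = 14)
  meta <- data.frame(sample_id = rownames(counts), cancer_type = "cancer1",
                     batch = "b1", sex = rep(c("male", "female"), 6),
                     age_years = 60, race = "European", bmi = NA_real_,
                     stage = 2L, histology = "h", stringsAsFactors = FALSE)
  ct <- contrast("sex", "cancer1")
  grp <- assign_groups(meta, ct)
  for (s in colnames(counts)) {
    x1 <- counts[grp == 1L, s]
    x0 <- counts[grp == 0L, s]
    if (stats::var(c(x1, x0)) < 1e-12) next
    got <- raw_count_confirm(counts, meta, ct, s)
    # identical U statistic, p within the normal-approximation accuracy
    expect_equal(
      suppressWarnings(stats::wilcox.test(x1, x0, exact = FALSE))$statistic,
      c(W = u_statistic(x1, x0)))
    expect_lt(abs(got$mw_p - mw_exact_oracle(x1, x0)), 0.08)
  }
})

test_that("raw-count confirmation separates disjoint distributions", {
  counts <- matrix(c(rep(0L, 30), rep(5:9, 6)), 60, 1,
                   dimnames = list(sprintf("s%02d", 1:60), "spX"))
  meta <- data.frame(sample_id = rownames(counts), cancer_type = "c1",
                     batch = "b1", sex = rep(c("female", "male"), each = 30),
                     age_years = 60, race = "European", bmi = NA_real_,
                     stage = 2L, histology = "h", stringsAsFactors = FALSE)
  ct <- contrast("sex", "c1")
  out <- raw_count_confirm(count_matrix(counts), meta, ct, "spX")
  expect_lt(out$mw_p, 1e-6)
  expect_equal(out$summary$pct_nonzero, c(100, 0))
  expect_equal(out$summary$n, c(30, 30))
  # percent nonzero arithmetic
  counts2 <- matrix(c(0L, 0L, 1L, 2L), 4, 1,
                    dimnames = list(paste0("s", 1:4), "spY"))
  meta2 <- meta[1:4, ]
  meta2$sample_id <- rownames(counts2)
  meta2$sex <- c("male", "male", "female", "female")
  out2 <- raw_count_confirm(count_matrix(counts2), meta2, ct, "spY")
  expect_equal(out2$summary$pct_nonzero, c(0, 100))
})

test_that("consensus set does not depend on combination evaluation order", {
  g <- small_cohort(seed = 20, n = 240, n_planted = 2,
                    planted_factor = "sex", planted_log2_effect = 2)
  cfg <- load_config()
  ct <- list("cancer1:sex" = contrast("sex", "cancer1"))
  combos <- enumerate_combinations()
  fwd <- run_consensus(g$counts, g$meta, cfg, contrasts = ct,
                       combinations = combos)
  rev <- run_consensus(g$counts, g$meta, cfg, contrasts = ct,
                       combinations = rev(combos))
  key <- function(res) sort(paste(res$consensus$species,
                                  res$consensus$consensus))
  expect_identical(key(fwd), key(rev))
})

test_that("truncation sensitivity reports an empty difference by default", {
  g <- small_cohort(seed = 22, n = 240, n_planted = 2,
                    planted_factor = "sex", planted_log2_effect = 2.5)
  cfg <- load_config()
  ct <- list("cancer1:sex" = contrast("sex", "cancer1"))
  rep99 <- truncation_sensitivity(g$counts, g$meta, cfg, percentile = 99,
                                  contrasts = ct)
  expect_true(rep99$identical)
  expect_length(rep99$only_full, 0L)
  expect_length(rep99$only_truncated, 0L)
  expect_true(all(c("n_full", "n_truncated", "percentile") %in%
                    names(rep99)))
})
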
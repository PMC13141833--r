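# Cross-cohort read-count concordance: alignment of two cohorts on shared
# samples and features, per-sample total and per-feature Pearson
# correlations, and the disjoint-pair ratio resampling statistic that is
# insensitive to per-sample sequencing-depth differences.

#' Align two cohorts on shared samples and features
#'
#' @param a,b Count matrices.
#' @return A list of class `cohort_pair` with both matrices subset and
#'   ordered identically (a's order).
#' @export
align_cohorts <- function(a, b) {
  samples <- intersect(rownames(a), rownames(b))
  features <- intersect(colnames(a), colnames(b))
  if (length(samples) < 2L || length(features) < 2L)
    stop(sprintf(
      "insufficient overlap between cohorts: %d shared samples, %d shared features",
      length(samples), length(features)), call. = FALSE)
  structure(list(a = a[samples, features, drop = FALSE],
                 b = b[samples, features, drop = FALSE]),
            class = "cohort_pair")
}

#' Correlation of per-sample total read counts
#'
#' @param pair A [align_cohorts()] pair.
#' @return Pearson r of the two per-sample total vectors, or `NA` with a
#'   warning if either vector has zero variance.
#' @export
total_reads_correlation <- function(pair) {
  stopifnot(inherits(pair, "cohort_pair"))
  ta <- rowSums(pair$a)
  tb <- rowSums(pair$b)
  if (stats::var(ta) < 1e-24 || stats::var(tb) < 1e-24) {
    warning("zero variance in per-sample totals; correlation undefined",
            call. = FALSE)
    return(NA_real_)
  }
  stats::cor(ta, tb)
}

#' Per-feature correlations across samples
#'
#' @param pair A [align_cohorts()] pair.
#' @return Named numeric vector with one Pearson r per feature; features
#'   with zero variance in either cohort are `NA`.
#' @export
per_feature_correlations <- function(pair) {
  stopifnot(inherits(pair, "cohort_pair"))
  vapply(colnames(pair$a), function(f) {
    x <- pair$a[, f]
    y <- pair$b[, f]
    if (stats::var(x) < 1e-24 || stats::var(y) < 1e-24) NA_real_
    else stats::cor(x, y)
  }, numeric(1L))
}

#' Draw a uniformly random maximal set of disjoint feature pairs
#'
#' Shuffles the feature ids and pairs consecutive items, giving
#' `floor(n/2)` pairs that cover `2*floor(n/2)` distinct features with no
#' feature in two pairs (e.g. 155 features give 77 pairs covering 154).
#'
#' @param features Character vector of feature ids (at least 2).
#' @param seed Integer seed.
#' @return A 2-column character matrix, one row per pair.
#' @export
disjoint_pair_sample <- function(features, seed = 1L) {
  if (length(features) < 2L)
    stop("need at least 2 features to form a pair", call. = FALSE)
  with_seed(seed, {
    perm <- sample(features)
    k <- floor(length(features) / 2)
    cbind(first = perm[2 * seq_len(k) - 1L], second = perm[2 * seq_len(k)])
  })
}

# One r for a given pair set: log((c1+1)/(c2+1)) ratios per (pair, sample),
# correlated between cohorts either pooled or averaged per sample.
pair_ratio_r <- function(la, lb, pairs, mode) {
  i1 <- pairs[, 1L]
  i2 <- pairs[, 2L]
  ra <- la[, i1, drop = FALSE] - la[, i2, drop = FALSE]
  rb <- lb[, i1, drop = FALSE] - lb[, i2, drop = FALSE]
  if (mode == "pooled") {
    va <- as.vector(ra)
    vb <- as.vector(rb)
    if (stats::var(va) < 1e-24 || stats::var(vb) < 1e-24) return(NA_real_)
    stats::cor(va, vb)
  } else {
    rs <- vapply(seq_len(nrow(ra)), function(i) {
      x <- ra[i, ]
      y <- rb[i, ]
      if (stats::var(x) < 1e-24 || stats::var(y) < 1e-24) NA_real_
      else stats::cor(x, y)
    }, numeric(1L))
    mean(rs, na.rm = TRUE)
  }
}

#' Disjoint-pair ratio correlation resampling
#'
#' Per resample, draws a random maximal set of disjoint feature pairs,
#' computes `log((c1 + 1) / (c2 + 1))` for every (pair, sample) in each
#' cohort, and Pearson-correlates the two ratio vectors (pooled over pairs
#' and samples by default; `mode = "per_sample"` instead averages per-sample
#' correlations). Because ratios within a sample cancel its sequencing
#' depth, the statistic is insensitive to per-sample total differences
#' between cohorts.
#'
#' @param pair A [align_cohorts()] pair.
#' @param n_resamples Number of resamples (default 2000).
#' @param seed Integer seed.
#' @param mode `"pooled"` or `"per_sample"`.
#' @return Numeric vector of length `n_resamples`; degenerate resamples are
#'   recorded as `NA`.
#' @export
ratio_correlation_resample <- function(pair, n_resamples = 2000, seed = 1L,
                                       mode = c("pooled", "per_sample")) {
  stopifnot(inherits(pair, "cohort_pair"))
  mode <- match.arg(mode)
  la <- log(pair$a + 1)
  lb <- log(pair$b + 1)
  features <- colnames(pair$a)
  with_seed(seed, {
    vapply(seq_len(n_resamples), function(i) {
      perm <- sample(features)
      k <- floor(length(features) / 2)
      pairs <- cbind(perm[2 * seq_len(k) - 1L], perm[2 * seq_len(k)])
      pair_ratio_r(la, lb, pairs, mode)
    }, numeric(1L))
  })
}

#' Compare two correlation-value distributions
#'
#' Two-sided Mann-Whitney U test between two sets of resampled correlation
#' values (missing values dropped).
#'
#' @param r_ab,r_cb Numeric vectors of correlation values.
#' @return The two-sided p-value.
#' @export
compare_r_distributions <- function(r_ab, r_cb) {
  r_ab <- r_ab[is.finite(r_ab)]
  r_cb <- r_cb[is.finite(r_cb)]
  if (length(r_ab) == 0L || length(r_cb) == 0L)
    stop("both distributions must be non-empty after dropping missing values",
         call. = FALSE)
  if (stats::var(c(r_ab, r_cb)) < 1e-24) return(1)
  suppressWarnings(stats::wilcox.test(r_ab, r_cb, exact = FALSE,
                                      correct = TRUE))$p.value
}
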
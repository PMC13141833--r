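# Per-species IPTW-weighted regression tests, Bonferroni correction within
# each (cancer, factor, combination) stratum, the strict all-combinations
# consensus rule, raw-count Mann-Whitney confirmation, and the
# weight-truncation sensitivity analysis.

#' Enumerate the eligible (cancer, factor) contrasts
#'
#' Every combination of cancer type and demographic factor whose two groups
#' each contain at least `min_per_group` samples (default 20). The race
#' factor expands to the three pairwise comparisons.
#'
#' @param meta Metadata data.frame.
#' @param min_per_group Minimum samples per group.
#' @param age_cut,bmi_cut Dichotomization cuts passed to [contrast()].
#' @return List of [contrast()] objects with attributes `n1` and `n0`.
#' @export
eligible_contrasts <- function(meta, min_per_group = 20, age_cut = 70,
                               bmi_cut = 30) {
  out <- list()
  for (cancer in sort(unique(meta$cancer_type))) {
    for (f in CONTRAST_FACTORS) {
      ct <- contrast(f, cancer, age_cut = age_cut, bmi_cut = bmi_cut)
      g <- assign_groups(meta, ct)
      n1 <- sum(g == 1L, na.rm = TRUE)
      n0 <- sum(g == 0L, na.rm = TRUE)
      if (n1 >= min_per_group && n0 >= min_per_group) {
        attr(ct, "n1") <- n1
        attr(ct, "n0") <- n0
        out[[paste(cancer, f, sep = ":")]] <- ct
      }
    }
  }
  out
}

#' Weighted two-group linear regression test
#'
#' Weighted least squares of the transformed abundance on an intercept and
#' the group indicator. The reported p-value is the two-sided t-test on the
#' group coefficient, which for this single-predictor model equals the
#' model F-test. A response with zero variance returns coefficient 0 and
#' p = 1.
#'
#' @param y Per-sample transformed abundance.
#' @param group Binary group indicator.
#' @param weights Optional positive weights (unit if `NULL`).
#' @return Named numeric vector `c(coefficient, p)`.
#' @export
weighted_group_test <- function(y, group, weights = NULL) {
  if (inherits(weights, "weight_set")) weights <- weights$weights
  w <- weights %||% rep(1, length(y))
  stopifnot(length(group) == length(y), length(w) == length(y), all(w > 0))
  if (sum(group == 1L) == 0L || sum(group == 0L) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  if (stats::var(y) < 1e-24)
    return(c(coefficient = 0, p = 1))
  fit <- stats::lm(y ~ g, data = data.frame(y = y, g = as.numeric(group)),
                   weights = w)
  cf <- summary(fit)$coefficients
  if (nrow(cf) < 2L || !is.finite(cf["g", 4L]))
    return(c(coefficient = 0, p = 1))
  c(coefficient = unname(cf["g", 1L]), p = unname(cf["g", 4L]))
}

#' Bonferroni adjustment
#'
#' @param p Vector of p-values.
#' @param m Number of tests (at least `length(p)`; defaults to it).
#' @return `pmin(1, p * m)`.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (m < length(p))
    stop("m must be at least the number of p-values", call. = FALSE)
  pmin(1, p * m)
}

# Per-species weighted tests for one (contrast, combination) stratum.
da_records <- function(abundance, species, group, weights, ct, combination,
                       alpha = 0.05, m_tests = NULL) {
  res <- t(vapply(species, function(s)
    weighted_group_test(abundance[, s], group, weights), numeric(2L)))
  m <- m_tests %||% length(species)
  p_bonf <- bonferroni_adjust(res[, "p"], m)
  data.frame(species = species, cancer = ct$cancer, factor = ct$factor,
             combination = combination, coefficient = res[, "coefficient"],
             p = res[, "p"], p_bonferroni = p_bonf,
             significant = p_bonf < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Consensus calls over the combination family
#'
#' A (species, cancer, factor) triple is a consensus call iff its test was
#' significant under every combination run.
#'
#' @param records Data.frame of per-combination records (as produced by
#'   [run_consensus()]), one row per (species, contrast, combination).
#' @param combinations_run Number of combinations in the family.
#' @return Data.frame with `n_significant_combinations` and `consensus` per
#'   (species, cancer, factor).
#' @export
consensus_call <- function(records, combinations_run) {
  if (nrow(records) == 0L)
    return(data.frame(species = character(0), cancer = character(0),
                      factor = character(0),
                      n_significant_combinations = integer(0),
                      consensus = logical(0), stringsAsFactors = FALSE))
  key <- interaction(records$species, records$cancer, records$factor,
                     drop = TRUE)
  n_comb <- tapply(records$combination, key,
                   function(x) length(unique(x)))
  if (any(n_comb != combinations_run))
    stop("incomplete combination grid: some species were not tested under ",
         "every combination", call. = FALSE)
  n_sig <- tapply(records$significant, key, sum)
  first <- records[!duplicated(key), c("species", "cancer", "factor")]
  first <- first[match(names(n_sig), key[!duplicated(key)]), ]
  data.frame(species = first$species, cancer = first$cancer,
             factor = first$factor,
             n_significant_combinations = as.integer(n_sig),
             consensus = as.integer(n_sig) == combinations_run,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Raw-count Mann-Whitney confirmation and group summaries
#'
#' Two-sided Mann-Whitney U test (normal approximation with tie and
#' continuity correction) on the raw counts of one species between the two
#' groups of a contrast, plus per-group n, mean, sd and percent of samples
#' with at least one read.
#'
#' @param m Count matrix.
#' @param meta Metadata aligned to `m`.
#' @param ct A [contrast()].
#' @param species Feature id.
#' @return List with `mw_p` and a two-row `summary` data.frame.
#' @export
raw_count_confirm <- function(m, meta, ct, species) {
  if (!species %in% colnames(m))
    stop("species not present: ", species, call. = FALSE)
  g <- assign_groups(meta, ct)
  x1 <- m[which(g == 1L), species]
  x0 <- m[which(g == 0L), species]
  if (length(x1) == 0L || length(x0) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  p <- if (stats::var(c(x1, x0)) < 1e-24) 1
       else suppressWarnings(stats::wilcox.test(x1, x0, exact = FALSE,
                                                correct = TRUE))$p.value
  summ <- data.frame(
    group = c(ct$group1_label, ct$group0_label),
    n = c(length(x1), length(x0)),
    mean = c(mean(x1), mean(x0)),
    sd = c(stats::sd(x1), stats::sd(x0)),
    pct_nonzero = 100 * c(mean(x1 > 0), mean(x0 > 0)),
    stringsAsFactors = FALSE)
  list(mw_p = p, summary = summ)
}

#' Run the full consensus differential-abundance analysis
#'
#' For every eligible contrast: fit IPTW weights once (they do not depend on
#' the normalization), run the weighted per-species regression under each of
#' the 14 transformation x batch-correction combinations applied to the full
#' cohort, Bonferroni-correct within each (cancer, factor, combination)
#' stratum, call consensus for species significant under every combination,
#' and attach the raw-count Mann-Whitney confirmation with group summaries.
#'
#' @param counts Count matrix.
#' @param meta Metadata data.frame covering every sample of `counts`.
#' @param config Configuration list from [load_config()].
#' @param contrasts Optional list of contrasts (default: all eligible).
#' @param combinations Optional combination list (default: all 14).
#' @param weight_percentile Optional percentile at which to truncate the
#'   IPTW weights before testing (`NULL` = no truncation).
#' @return List with `records` (per-combination tests), `consensus`
#'   (per-species consensus table with MW confirmation), `weights` (one
#'   `weight_set` per contrast) and `combinations_run`.
#' @export
run_consensus <- function(counts, meta, config = load_config(),
                          contrasts = NULL,
                          combinations = enumerate_combinations(),
                          weight_percentile = NULL) {
  meta <- align_metadata(counts, meta)
  contrasts <- contrasts %||% eligible_contrasts(
    meta, min_per_group = config$min_group_size,
    age_cut = config$age_cut, bmi_cut = config$bmi_cut)
  abundances <- lapply(combinations, function(spec)
    apply_combination(counts, meta$batch, spec,
                      plsda_k = config$plsda_components))
  records <- list()
  weights_out <- list()
  consensus_rows <- list()
  global_m <- length(colnames(counts)) * length(contrasts) *
    length(combinations)
  for (ct_name in names(contrasts)) {
    ct <- contrasts[[ct_name]]
    ws <- iptw_weights(meta, ct, clip = config$propensity_clip)
    if (!is.null(weight_percentile))
      ws <- truncate_weights(ws, weight_percentile)
    weights_out[[ct_name]] <- ws
    idx <- match(ws$sample_id, meta$sample_id)
    grp <- ws$group
    m_tests <- if (config$bonferroni_scope == "global") global_m else NULL
    ct_records <- lapply(names(combinations), function(cb)
      da_records(abundances[[cb]][idx, , drop = FALSE], colnames(counts),
                 grp, ws$weights, ct, cb, alpha = config$alpha,
                 m_tests = m_tests))
    ct_records <- do.call(rbind, ct_records)
    records[[ct_name]] <- ct_records
    cons <- consensus_call(ct_records, length(combinations))
    mw <- lapply(cons$species, function(s) raw_count_confirm(counts, meta,
                                                             ct, s))
    cons$mw_p_raw <- vapply(mw, `[[`, numeric(1L), "mw_p")
    for (col in c("n", "mean", "sd", "pct_nonzero")) {
      cons[[paste0(col, "_group1")]] <-
        vapply(mw, function(x) x$summary[[col]][1L], numeric(1L))
      cons[[paste0(col, "_group0")]] <-
        vapply(mw, function(x) x$summary[[col]][2L], numeric(1L))
    }
    consensus_rows[[ct_name]] <- cons
  }
  list(records = do.call(rbind, c(records, list(make.row.names = FALSE))),
       consensus = do.call(rbind, c(consensus_rows,
                                    list(make.row.names = FALSE))),
       weights = weights_out,
       combinations_run = length(combinations))
}

#' Weight-truncation sensitivity analysis
#'
#' Re-runs the consensus analysis with IPTW weights truncated at the given
#' percentile and reports the symmetric difference between the two
#' consensus sets.
#'
#' @param counts Count matrix.
#' @param meta Metadata data.frame.
#' @param config Configuration list.
#' @param percentile Truncation percentile (default 99).
#' @param ... Passed on to [run_consensus()].
#' @return List with the two consensus key sets, the calls unique to each,
#'   and `identical` (TRUE when the symmetric difference is empty).
#' @export
truncation_sensitivity <- function(counts, meta, config = load_config(),
                                   percentile = 99, ...) {
  full <- run_consensus(counts, meta, config, ...)
  trunc <- run_consensus(counts, meta, config,
                         weight_percentile = percentile, ...)
  key <- function(res) {
    cons <- res$consensus[res$consensus$consensus, , drop = FALSE]
    paste(cons$species, cons$cancer, cons$factor, sep = ":")
  }
  k_full <- key(full)
  k_trunc <- key(trunc)
  list(n_full = length(k_full), n_truncated = length(k_trunc),
       only_full = setdiff(k_full, k_trunc),
       only_truncated = setdiff(k_trunc, k_full),
       identical = setequal(k_full, k_trunc),
       percentile = percentile)
}
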
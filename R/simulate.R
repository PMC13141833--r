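# Synthetic cohort generator. Emulates the statistical structure of sparse
# tumor mycobiome count tables: zero-inflated negative-binomial counts,
# log-normal library sizes, multiplicative per-batch (sequencing center)
# effects, demographics confounded with batch through a logistic link, a few
# degenerate near-all-zero features, and planted demographic effects with a
# returned ground truth for recovery tests.

# Fixed logistic coefficient pattern (per unit confounding_strength) linking
# batch assignment to standardized age, male sex, race dummies and
# standardized stage. Deterministic so that the strength knob alone controls
# the amount of confounding.
BATCH_CONFOUNDING_PATTERN <- c(z_age = 0.5, male = 0.4, race_African = -0.4,
                               race_Asian = 0.4, z_stage = 0.3)

PLANTABLE_FACTORS <- c("sex", "age_group", "race_EA", "race_EAf", "race_AAf",
                       "bmi_group")

#' Specification of a synthetic cohort
#'
#' Bundles the generator's parameters. Defaults describe a single-cancer
#' RNA-seq cohort of 300 primary tumors with 40 fungal species sequenced in
#' 2 centers: 5% excess structural zeros on top of negative-binomial
#' sampling (most sparsity arises from low-abundance features through the
#' negative binomial itself)
#' (dispersion 0.5), log-normal library sizes (median 3000 fungal reads per
#' sample), per-batch multiplicative effects with sd 1 on the log2 scale,
#' 10% near-all-zero degenerate species, race marginals 0.70/0.15/0.15
#' (European/African/Asian) and age centered at 63 years.
#'
#' @param n_samples,n_features,n_batches Cohort dimensions.
#' @param n_planted Number of species given a planted demographic effect.
#' @param confounding_strength In \[0, 1\]; scales the logistic association
#'   between demographics and batch assignment (0 = none).
#' @param planted_factor Factor carrying the planted effects; one of
#'   sex, age_group, race_EA, race_EAf, race_AAf, bmi_group.
#' @param planted_log2_effect log2 fold change applied to group 1 of the
#'   planted factor (recycled over planted species).
#' @param zero_inflation Probability of an excess structural zero per cell.
#' @param dispersion Negative-binomial dispersion (variance
#'   \eqn{\mu + dispersion \cdot \mu^2}).
#' @param library_size_meanlog,library_size_sdlog Log-normal library-size law.
#' @param batch_effect_sd SD of per-(batch, feature) log2 effects.
#' @param rare_feature_frac Fraction of features made degenerate
#'   (relative level scaled by 1e-3, hence near-all-zero).
#' @param race_marginals Named probabilities for European/African/Asian.
#' @param bmi_missing_rate Fraction of samples with missing BMI.
#' @param cancer_type Label assigned to every sample.
#' @param seed Integer seed; the same spec (including seed) always yields
#'   bit-identical output.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 300L, n_features = 40L, n_batches = 2L,
                        n_planted = 0L, confounding_strength = 0.5,
                        planted_factor = "sex", planted_log2_effect = 2,
                        zero_inflation = 0.05, dispersion = 0.5,
                        library_size_meanlog = log(3000),
                        library_size_sdlog = 0.4,
                        batch_effect_sd = 1, rare_feature_frac = 0.1,
                        race_marginals = c(European = 0.70, African = 0.15,
                                           Asian = 0.15),
                        bmi_missing_rate = 0, cancer_type = "cancer1",
                        seed = 1L) {
  spec <- list(n_samples = as.integer(n_samples),
               n_features = as.integer(n_features),
               n_batches = as.integer(n_batches),
               n_planted = as.integer(n_planted),
               confounding_strength = confounding_strength,
               planted_factor = planted_factor,
               planted_log2_effect = planted_log2_effect,
               zero_inflation = zero_inflation, dispersion = dispersion,
               library_size_meanlog = library_size_meanlog,
               library_size_sdlog = library_size_sdlog,
               batch_effect_sd = batch_effect_sd,
               rare_feature_frac = rare_feature_frac,
               race_marginals = race_marginals,
               bmi_missing_rate = bmi_missing_rate,
               cancer_type = cancer_type, seed = as.integer(seed))
  stopifnot(spec$n_samples >= 1L, spec$n_features >= 1L, spec$n_batches >= 1L)
  if (spec$n_planted > spec$n_features)
    stop("n_planted exceeds n_features", call. = FALSE)
  assert_scalar_number(spec$confounding_strength, "confounding_strength", 0, 1)
  assert_scalar_number(spec$zero_inflation, "zero_inflation", 0, 1)
  assert_scalar_number(spec$dispersion, "dispersion", 1e-8, Inf)
  if (!planted_factor %in% PLANTABLE_FACTORS)
    stop("planted_factor must be one of: ",
         paste(PLANTABLE_FACTORS, collapse = ", "), call. = FALSE)
  if (abs(sum(race_marginals) - 1) > 1e-8 ||
      !setequal(names(race_marginals), RACE_LEVELS))
    stop("race_marginals must be named European/African/Asian and sum to 1",
         call. = FALSE)
  class(spec) <- "cohort_spec"
  spec
}

# Truncated-normal draw by rejection (bounds wide, so cheap).
rtruncnorm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

# Group-1 indicator (1/0/NA) for a planted factor, from raw metadata columns.
planted_group_indicator <- function(meta, factor_name, age_cut = 70,
                                    bmi_cut = 30) {
  switch(factor_name,
    sex = ifelse(meta$sex == "male", 1L, 0L),
    age_group = ifelse(meta$age_years > age_cut, 1L, 0L),
    race_EA = ifelse(meta$race == "European", 1L,
                     ifelse(meta$race == "Asian", 0L, NA_integer_)),
    race_EAf = ifelse(meta$race == "European", 1L,
                      ifelse(meta$race == "African", 0L, NA_integer_)),
    race_AAf = ifelse(meta$race == "Asian", 1L,
                      ifelse(meta$race == "African", 0L, NA_integer_)),
    bmi_group = ifelse(is.na(meta$bmi), NA_integer_,
                       ifelse(meta$bmi > bmi_cut, 1L, 0L)),
    stop("unknown factor: ", factor_name, call. = FALSE))
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws demographics, assigns samples to sequencing batches through a
#' logistic link to (standardized) age, sex, race and stage scaled by
#' `confounding_strength`, then draws counts per (sample, feature) as
#' zero-inflated negative binomial with mean
#' `library_size x relative_level x 2^(batch_effect + planted_effect)`.
#' Planted effects are applied to group 1 of the planted factor and only to
#' non-degenerate features, so they are recoverable in principle.
#'
#' @param spec A [cohort_spec()].
#' @return A list with elements `counts` (validated count matrix), `meta`
#'   (metadata data.frame) and `truth` (list: planted-effect table, per-batch
#'   log2 effect matrix, expected zero fraction, generator parameters).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_samples
    p <- spec$n_features
    sample_ids <- sprintf("s%04d", seq_len(n))
    feature_ids <- sprintf("sp%03d", seq_len(p))

    sex <- sample(SEX_LEVELS, n, replace = TRUE)
    age <- rtruncnorm(n, 63, 12, 20, 90)
    race <- sample(RACE_LEVELS, n, replace = TRUE,
                   prob = spec$race_marginals[RACE_LEVELS])
    bmi <- pmax(15, stats::rnorm(n, 27.5, 5))
    if (spec$bmi_missing_rate > 0)
      bmi[stats::runif(n) < spec$bmi_missing_rate] <- NA_real_
    # stage mildly correlated with age (confounding among demographics)
    stage_latent <- 0.3 * scale(age)[, 1L] + stats::rnorm(n)
    stage <- as.integer(cut(stage_latent,
                            breaks = stats::qnorm(c(0, 0.3, 0.6, 0.85, 1),
                                                  sd = sqrt(0.3^2 + 1)),
                            labels = FALSE))
    histology <- sample(c("typeA", "typeB"), n, replace = TRUE,
                        prob = c(0.6, 0.4))

    # batch assignment: softmax over per-batch linear predictors built from a
    # fixed coefficient pattern, batches spread along the confounding gradient
    X <- cbind(z_age = scale(age)[, 1L],
               male = as.numeric(sex == "male"),
               race_African = as.numeric(race == "African"),
               race_Asian = as.numeric(race == "Asian"),
               z_stage = scale(stage)[, 1L])
    B <- spec$n_batches
    mult <- if (B == 1L) 0 else seq(-1, 1, length.out = B)
    eta <- outer(drop(X %*% BATCH_CONFOUNDING_PATTERN),
                 mult * spec$confounding_strength)
    prob <- exp(eta - apply(eta, 1L, max))
    prob <- prob / rowSums(prob)
    batch_idx <- apply(prob, 1L, function(pr) sample.int(B, 1L, prob = pr))
    batch <- sprintf("batch%d", batch_idx)

    meta <- data.frame(sample_id = sample_ids,
                       cancer_type = spec$cancer_type, batch = batch,
                       sex = sex, age_years = age, race = race, bmi = bmi,
                       stage = stage, histology = histology,
                       stringsAsFactors = FALSE)

    # feature relative levels; a fraction are degenerate near-all-zero
    q <- stats::rlnorm(p, 0, 0.6)
    n_rare <- floor(spec$rare_feature_frac * p)
    rare <- if (n_rare > 0L) sample.int(p, n_rare) else integer(0)
    q[rare] <- q[rare] * 1e-3
    q <- q / sum(q)

    batch_log2 <- matrix(stats::rnorm(B * p, 0, spec$batch_effect_sd), B, p,
                         dimnames = list(sprintf("batch%d", seq_len(B)),
                                         feature_ids))
    batch_log2 <- sweep(batch_log2, 2L, colMeans(batch_log2))

    effect <- rep(0, p)
    planted <- integer(0)
    if (spec$n_planted > 0L) {
      eligible <- setdiff(seq_len(p), rare)
      if (length(eligible) < spec$n_planted)
        stop("not enough non-degenerate features to plant effects",
             call. = FALSE)
      planted <- sort(sample(eligible, spec$n_planted))
      effect[planted] <- rep_len(spec$planted_log2_effect, spec$n_planted)
    }
    g <- planted_group_indicator(meta, spec$planted_factor)
    g[is.na(g)] <- 0L

    lib <- stats::rlnorm(n, spec$library_size_meanlog, spec$library_size_sdlog)
    mu <- (lib %o% q) * 2^(batch_log2[batch_idx, , drop = FALSE] +
                             g %o% effect)
    size <- 1 / spec$dispersion
    counts <- matrix(stats::rnbinom(n * p, mu = mu, size = size), n, p)
    if (spec$zero_inflation > 0)
      counts <- counts * matrix(stats::rbinom(n * p, 1L,
                                              1 - spec$zero_inflation), n, p)
    dimnames(counts) <- list(sample_ids, feature_ids)

    expected_zero <- spec$zero_inflation +
      (1 - spec$zero_inflation) * mean((size / (size + mu))^size)

    truth <- list(
      planted = data.frame(feature = feature_ids[planted],
                           affected_factor = rep(spec$planted_factor,
                                                 length(planted)),
                           log2_effect = effect[planted],
                           stringsAsFactors = FALSE),
      batch_log2_effect = batch_log2,
      degenerate_features = feature_ids[sort(rare)],
      relative_levels = stats::setNames(q, feature_ids),
      expected_zero_fraction = expected_zero,
      zero_inflation = spec$zero_inflation,
      dispersion = spec$dispersion,
      library_size_law = c(meanlog = spec$library_size_meanlog,
                           sdlog = spec$library_size_sdlog))

    list(counts = count_matrix(counts), meta = validate_metadata(meta),
         truth = truth)
  })
}

#' Inject a degenerate artifact feature into a count matrix
#'
#' Adds one feature that is zero in all but `n_nonzero` randomly chosen
#' samples, where it takes the given constant value. This reproduces the
#' structure of near-all-zero species (e.g. one read in one sample out of
#' hundreds) whose normalized values can nevertheless acquire class signal.
#'
#' @param m Count matrix.
#' @param n_nonzero Number of samples with a nonzero entry.
#' @param value Positive integer count placed in those samples.
#' @param seed Integer seed for the sample draw.
#' @param feature_id Name of the injected feature.
#' @return The count matrix with one extra column.
#' @export
inject_artifact_feature <- function(m, n_nonzero, value = 1L, seed = 1L,
                                    feature_id = "artifact") {
  if (n_nonzero > nrow(m))
    stop("n_nonzero exceeds the number of samples", call. = FALSE)
  stopifnot(value >= 1, n_nonzero >= 0)
  col <- integer(nrow(m))
  if (n_nonzero > 0L)
    col[with_seed(seed, sample.int(nrow(m), n_nonzero))] <- as.integer(value)
  out <- cbind(m, col)
  colnames(out)[ncol(out)] <- feature_id
  count_matrix(out)
}

#' Generate a pair of cohorts with a known scale/noise relation
#'
#' Cohort A is the base matrix; cohort B is the base scaled by `scale_ratio`
#' with independent multiplicative log-normal noise of sd `noise_sd` per
#' cell, rounded back to integers. Sample and feature ids are shared, which
#' makes the pair a test bed for the cross-cohort concordance statistics.
#'
#' @param base Count matrix.
#' @param scale_ratio Positive multiplicative scale of cohort B.
#' @param noise_sd Nonnegative sd of the log-normal noise.
#' @param seed Integer seed.
#' @return List with elements `a` and `b` (count matrices).
#' @export
generate_paired_cohorts <- function(base, scale_ratio = 1, noise_sd = 0,
                                    seed = 1L) {
  assert_scalar_number(scale_ratio, "scale_ratio", 1e-12, Inf)
  assert_scalar_number(noise_sd, "noise_sd", 0, Inf)
  noisy <- with_seed(seed, {
    eps <- matrix(stats::rlnorm(length(base), 0, noise_sd), nrow(base))
    round(base * scale_ratio * eps)
  })
  dimnames(noisy) <- dimnames(base)
  list(a = count_matrix(base), b = count_matrix(noisy))
}
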
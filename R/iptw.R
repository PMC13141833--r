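# Propensity scores and inverse probability of treatment weighting for the
# demographic contrasts: confounder design matrices (excluding the tested
# factor), logistic propensity fits with clipping, ATE weights, weighted
# standardized differences as balance diagnostics, and percentile truncation
# for sensitivity analysis.

CONTRAST_FACTORS <- c("sex", "age_group", "race_EA", "race_EAf", "race_AAf",
                      "bmi_group")

#' Define a demographic contrast
#'
#' The six contrasts tested per cancer type: sex (male vs female), age group
#' (>`age_cut` vs <=`age_cut`, default cut 70 years), the three pairwise race
#' comparisons, and BMI group (>`bmi_cut` vs <=`bmi_cut`, default cut 30).
#'
#' @param factor One of sex, age_group, race_EA, race_EAf, race_AAf,
#'   bmi_group.
#' @param cancer Cancer type the contrast is restricted to.
#' @param age_cut,bmi_cut Dichotomization cuts.
#' @return A list of class `contrast` with group labels.
#' @export
contrast <- function(factor, cancer, age_cut = 70, bmi_cut = 30) {
  factor <- match.arg(factor, CONTRAST_FACTORS)
  labels <- switch(factor,
    sex = c("male", "female"),
    age_group = c(sprintf(">%g", age_cut), sprintf("<=%g", age_cut)),
    race_EA = c("European", "Asian"),
    race_EAf = c("European", "African"),
    race_AAf = c("Asian", "African"),
    bmi_group = c(sprintf(">%g", bmi_cut), sprintf("<=%g", bmi_cut)))
  structure(list(factor = factor, cancer = cancer,
                 group1_label = labels[1L], group0_label = labels[2L],
                 age_cut = age_cut, bmi_cut = bmi_cut),
            class = "contrast")
}

#' @export
print.contrast <- function(x, ...) {
  cat(sprintf("<contrast %s in %s: %s vs %s>\n", x$factor, x$cancer,
              x$group1_label, x$group0_label))
  invisible(x)
}

#' Assign samples to the two groups of a contrast
#'
#' @param meta Metadata data.frame.
#' @param ct A [contrast()].
#' @return Integer vector per metadata row: 1 (group 1), 0 (group 0) or NA
#'   (wrong cancer type, third race level, or missing factor value).
#' @export
assign_groups <- function(meta, ct) {
  g <- planted_group_indicator(meta, ct$factor, age_cut = ct$age_cut,
                               bmi_cut = ct$bmi_cut)
  g[meta$cancer_type != ct$cancer] <- NA_integer_
  g
}

one_hot <- function(x, prefix) {
  f <- as.factor(x)
  if (nlevels(f) < 2L) return(NULL)
  mm <- stats::model.matrix(~ f)[, -1L, drop = FALSE]
  colnames(mm) <- paste0(prefix, levels(f)[-1L])
  mm
}

#' Build the confounder design matrix for a contrast
#'
#' One-hot encodes the categorical confounders with a fixed reference level
#' and keeps age continuous. The contrast's own factor is excluded from the
#' design: the sex contrast has no sex column, the age contrast no age
#' column, the race contrasts no race columns. For the BMI contrast the
#' confounder set is exactly age, sex and race. Columns that are constant
#' after restriction are dropped with a warning.
#'
#' @param meta Metadata restricted to one cancer type and to the contrast's
#'   two groups, with no missing values in the used confounders.
#' @param ct A [contrast()].
#' @return Numeric design matrix (no intercept column), one row per sample.
#' @export
build_confounder_design <- function(meta, ct) {
  vars <- if (ct$factor == "bmi_group") c("age", "sex", "race")
          else c("age", "sex", "race", "stage", "histology")
  vars <- setdiff(vars, switch(ct$factor,
                               sex = "sex", age_group = "age",
                               race_EA = "race", race_EAf = "race",
                               race_AAf = "race", bmi_group = ""))
  blocks <- list()
  if ("age" %in% vars) blocks$age <- cbind(age = meta$age_years)
  if ("sex" %in% vars) blocks$sex <- cbind(sex_male =
                                             as.numeric(meta$sex == "male"))
  if ("race" %in% vars)
    blocks$race <- one_hot(factor(meta$race, levels = RACE_LEVELS), "race_")
  if ("stage" %in% vars)
    blocks$stage <- one_hot(factor(meta$stage, levels = 1:4), "stage_")
  if ("histology" %in% vars)
    blocks$histology <- one_hot(meta$histology, "histology_")
  degenerate <- setdiff(vars, c(names(Filter(Negate(is.null), blocks)),
                                if ("age" %in% vars) "age"))
  if (length(degenerate) > 0L)
    warning("dropping constant confounder(s) after restriction: ",
            paste(degenerate, collapse = ", "), call. = FALSE)
  design <- do.call(cbind, Filter(Negate(is.null), blocks))
  if (is.null(design))
    stop("no usable confounder columns for this contrast", call. = FALSE)
  const <- apply(design, 2L, function(x) stats::var(x) < 1e-12)
  if (any(const)) {
    warning("dropping constant confounder column(s): ",
            paste(colnames(design)[const], collapse = ", "), call. = FALSE)
    design <- design[, !const, drop = FALSE]
  }
  rownames(design) <- meta$sample_id
  design
}

#' Fit a logistic propensity model
#'
#' Maximum-likelihood logistic regression of group membership on the
#' confounder design; fitted probabilities are clipped to `clip` (default
#' \[0.01, 0.99\]) to bound the weights.
#'
#' @param design Confounder design matrix (no intercept column).
#' @param group Binary group indicator (1 = group 1).
#' @param clip Length-2 clipping bounds inside (0, 1).
#' @return Numeric vector of clipped propensity scores.
#' @export
fit_propensity <- function(design, group, clip = c(0.01, 0.99)) {
  if (sum(group == 1L) == 0L || sum(group == 0L) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, design)
  fit <- suppressWarnings(
    stats::glm.fit(X, group, family = stats::binomial()))
  e <- fit$fitted.values
  if (min(e[group == 1L]) > 1 - 1e-8 && max(e[group == 0L]) < 1e-8)
    stop("perfect separation in the propensity model; ",
         "this contrast should be skipped", call. = FALSE)
  pmin(pmax(e, clip[1L]), clip[2L])
}

#' Compute ATE inverse-probability weights
#'
#' Weight `1/e` for group 1 and `1/(1 - e)` for group 0, where `e` is the
#' propensity score.
#'
#' @param propensity Propensity scores in (0, 1).
#' @param group Binary group indicator.
#' @return A list of class `weight_set` with elements `weights`,
#'   `propensity`, `group`, `truncated`, `truncation_percentile`.
#' @export
compute_weights <- function(propensity, group) {
  stopifnot(all(propensity > 0 & propensity < 1))
  w <- ifelse(group == 1L, 1 / propensity, 1 / (1 - propensity))
  structure(list(weights = w, propensity = propensity, group = group,
                 truncated = FALSE, truncation_percentile = NA_real_),
            class = "weight_set")
}

#' Weighted standardized differences in percent
#'
#' For each design column, `100 * |m1 - m0| / sqrt((s1^2 + s0^2) / 2)` with
#' (weighted) group means and variances. A column with both variances zero
#' and equal means gives 0; with differing means it gives `Inf` (flagged in
#' the name attribute by the caller).
#'
#' @param design Confounder design matrix.
#' @param group Binary group indicator.
#' @param weights Optional per-sample weights (unit weights if `NULL`).
#' @return Named numeric vector of percent standardized differences.
#' @export
standardized_differences <- function(design, group, weights = NULL) {
  if (inherits(weights, "weight_set")) weights <- weights$weights
  w <- weights %||% rep(1, length(group))
  vapply(seq_len(ncol(design)), function(j) {
    x <- design[, j]
    m1 <- weighted_moments(x[group == 1L], w[group == 1L])
    m0 <- weighted_moments(x[group == 0L], w[group == 0L])
    pooled <- sqrt((m1["var"] + m0["var"]) / 2)
    diff <- abs(m1["mean"] - m0["mean"])
    if (pooled < 1e-12) {
      if (diff < 1e-12) 0 else Inf
    } else 100 * diff / pooled
  }, numeric(1L), USE.NAMES = FALSE) |>
    stats::setNames(colnames(design))
}

#' Truncate extreme weights at a percentile
#'
#' Weights above the given percentile of the weight distribution (linear
#' interpolation on the sorted weights) are set to that percentile value.
#'
#' @param ws A `weight_set` or numeric weight vector.
#' @param percentile Percentile in (50, 100].
#' @return Same type as the input, with the truncation recorded when the
#'   input is a `weight_set`.
#' @export
truncate_weights <- function(ws, percentile = 99) {
  if (percentile <= 50 || percentile > 100)
    stop("`percentile` must be in (50, 100]", call. = FALSE)
  w <- if (inherits(ws, "weight_set")) ws$weights else ws
  cap <- stats::quantile(w, percentile / 100, type = 7, names = FALSE)
  w2 <- pmin(w, cap)
  if (inherits(ws, "weight_set")) {
    ws$weights <- w2
    ws$truncated <- TRUE
    ws$truncation_percentile <- percentile
    ws
  } else w2
}

#' Fit IPTW weights and balance diagnostics for one contrast
#'
#' Restricts the metadata to the contrast's two groups and to samples with
#' complete confounder values, builds the confounder design (excluding the
#' tested factor), fits the clipped logistic propensity model, computes ATE
#' weights, and reports pre- and post-weighting standardized differences.
#' Imbalance above `balance_limit` is flagged, never fatal.
#'
#' @param meta Metadata data.frame (full cohort).
#' @param ct A [contrast()].
#' @param clip Propensity clipping bounds.
#' @param balance_limit Percent standardized-difference threshold to flag.
#' @return A `weight_set` with additional elements `sample_id`,
#'   `balance_table` (confounder, smd_unweighted, smd_weighted, flagged) and
#'   `design`.
#' @export
iptw_weights <- function(meta, ct, clip = c(0.01, 0.99), balance_limit = 10) {
  g <- assign_groups(meta, ct)
  keep <- !is.na(g)
  vars <- if (ct$factor == "bmi_group") c("age_years", "sex", "race")
          else c("age_years", "sex", "race", "stage", "histology")
  for (v in vars) keep <- keep & !is.na(meta[[v]])
  sub <- meta[keep, , drop = FALSE]
  g <- g[keep]
  design <- build_confounder_design(sub, ct)
  e <- fit_propensity(design, g, clip = clip)
  ws <- compute_weights(e, g)
  pre <- standardized_differences(design, g)
  post <- standardized_differences(design, g, ws$weights)
  ws$sample_id <- sub$sample_id
  ws$design <- design
  ws$balance_table <- data.frame(confounder = colnames(design),
                                 smd_unweighted = unname(pre),
                                 smd_weighted = unname(post),
                                 flagged = unname(!is.finite(post) |
                                                    post > balance_limit),
                                 stringsAsFactors = FALSE)
  ws
}
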
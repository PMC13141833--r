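# Normalization-artifact audit: screen features that are zero in more than a
# given fraction of samples, and quantify how well a single threshold on the
# normalized values of such a feature separates two sample classes (PPV and
# sensitivity). A near-all-zero raw feature that nevertheless classifies
# well after normalization is a manufactured signal.

#' Screen features by raw zero fraction
#'
#' Per feature, the fraction of samples with a raw count of zero; a feature
#' is flagged when the fraction is strictly greater than the threshold
#' (default 0.95, i.e. "zero in more than 95% of samples").
#'
#' @param m Count matrix.
#' @param threshold Zero-fraction flag threshold in \[0, 1\].
#' @return Data.frame with columns feature, zero_fraction, flagged,
#'   threshold.
#' @export
zero_fraction_screen <- function(m, threshold = 0.95) {
  assert_scalar_number(threshold, "threshold", 0, 1)
  zf <- colMeans(m == 0)
  data.frame(feature = colnames(m), zero_fraction = unname(zf),
             flagged = unname(zf > threshold), threshold = threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Evaluate a classification threshold on normalized values
#'
#' Predicts a sample positive iff its normalized value is strictly greater
#' than the threshold, and reports the confusion counts, PPV and
#' sensitivity in percent. With zero predicted positives the PPV is
#' undefined and reported as `NA` with `ppv_defined = FALSE`.
#'
#' @param values Per-sample normalized values.
#' @param labels Binary class labels (1 = positive).
#' @param threshold Decision threshold.
#' @return A list of class `audit_record` with fields `threshold`,
#'   `n_predicted_positive`, `n_true_positive`, `ppv_percent`,
#'   `sensitivity_percent`, `ppv_defined`.
#' @export
evaluate_threshold <- function(values, labels, threshold) {
  stopifnot(length(values) == length(labels), all(labels %in% c(0, 1)),
            all(is.finite(values)))
  pred <- values > threshold
  n_pred <- sum(pred)
  n_tp <- sum(pred & labels == 1)
  n_pos <- sum(labels == 1)
  structure(list(
    threshold = threshold,
    n_predicted_positive = n_pred,
    n_true_positive = n_tp,
    ppv_percent = if (n_pred > 0L) 100 * n_tp / n_pred else NA_real_,
    sensitivity_percent = if (n_pos > 0L) 100 * n_tp / n_pos else NA_real_,
    ppv_defined = n_pred > 0L), class = "audit_record")
}

#' @export
print.audit_record <- function(x, ...) {
  cat(sprintf(
    "<audit threshold %.4g: %d/%d predicted positive correct (PPV %s%%), sensitivity %s%%>\n",
    x$threshold, x$n_true_positive, x$n_predicted_positive,
    if (x$ppv_defined) sprintf("%.1f", x$ppv_percent) else "NA",
    sprintf("%.2f", x$sensitivity_percent)))
  invisible(x)
}

#' Select the best separating threshold
#'
#' Scans the midpoints of consecutive sorted unique values and returns the
#' threshold maximizing PPV subject to a sensitivity floor (default 25%).
#' Ties prefer higher sensitivity, then the lower threshold.
#'
#' @param values Per-sample normalized values.
#' @param labels Binary class labels (1 = positive); at least one positive.
#' @param sensitivity_floor Minimum sensitivity in percent.
#' @return The selected threshold (numeric scalar).
#' @export
best_threshold <- function(values, labels, sensitivity_floor = 25) {
  stopifnot(sum(labels == 1) >= 1L)
  u <- sort(unique(values))
  if (length(u) < 2L)
    stop("all values are equal; no threshold can split the samples",
         call. = FALSE)
  cand <- (u[-1L] + u[-length(u)]) / 2
  best <- NULL
  for (th in cand) {
    rec <- evaluate_threshold(values, labels, th)
    if (!rec$ppv_defined || rec$sensitivity_percent < sensitivity_floor)
      next
    if (is.null(best) ||
        rec$ppv_percent > best$ppv_percent + 1e-12 ||
        (abs(rec$ppv_percent - best$ppv_percent) <= 1e-12 &&
           rec$sensitivity_percent > best$sensitivity_percent + 1e-12))
      best <- rec
  }
  if (is.null(best))
    stop("no threshold reaches the sensitivity floor of ",
         sensitivity_floor, "%", call. = FALSE)
  best$threshold
}
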
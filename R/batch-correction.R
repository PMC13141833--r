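# Unsupervised batch-effect corrections and the registry of valid
# (transform, correction, order) combinations. The registry encodes the
# pipeline constraints: the count-level correction runs before the
# transformation, the PLSDA component removal applies only to CLR-family
# matrices, everything else transforms first and corrects after.

TRANSFORMS <- c("CLR", "CLR_C", "RA", "VOOM")
CORRECTIONS <- c("COMBAT", "BMC", "MMUPHIN", "PLSDA")

#' Construct one (transform, correction) combination
#'
#' @param transform One of CLR, CLR_C, RA, VOOM.
#' @param correction One of COMBAT, BMC, MMUPHIN, PLSDA.
#' @return A list of class `combination_spec` with the required `order`
#'   (`"correction_first"` for MMUPHIN, `"transform_first"` otherwise).
#' @export
combination_spec <- function(transform, correction) {
  transform <- match.arg(transform, TRANSFORMS)
  correction <- match.arg(correction, CORRECTIONS)
  if (correction == "PLSDA" && !transform %in% c("CLR", "CLR_C"))
    stop("PLSDA correction applies only after a CLR-family transform",
         call. = FALSE)
  structure(list(transform = transform, correction = correction,
                 order = if (correction == "MMUPHIN") "correction_first"
                         else "transform_first",
                 label = paste(transform, correction, sep = "+")),
            class = "combination_spec")
}

#' @export
print.combination_spec <- function(x, ...) {
  cat(sprintf("<combination %s (%s)>\n", x$label, x$order))
  invisible(x)
}

#' Enumerate the valid transformation x batch-correction combinations
#'
#' All pairs of the four transforms and four corrections that satisfy the
#' pipeline constraints: PLSDA pairs only with CLR and CLR_C, and the
#' count-level MMUPHin-style correction always runs before the transform.
#' This yields 14 combinations, in a fixed deterministic order.
#'
#' @return A list of [combination_spec()] objects (length 14).
#' @export
enumerate_combinations <- function() {
  out <- list()
  for (tr in TRANSFORMS) for (co in CORRECTIONS) {
    if (co == "PLSDA" && !tr %in% c("CLR", "CLR_C")) next
    out[[length(out) + 1L]] <- combination_spec(tr, co)
  }
  names(out) <- vapply(out, `[[`, "", "label")
  out
}

check_batch_labels <- function(values, batch) {
  if (length(batch) != nrow(values))
    stop("batch labels do not match the number of samples", call. = FALSE)
  batch <- as.factor(batch)
  if (any(table(batch) == 0L))
    stop("batch level(s) with zero samples: ",
         paste(names(which(table(batch) == 0L)), collapse = ", "),
         call. = FALSE)
  batch
}

#' Batch mean centering
#'
#' Per feature, subtracts the within-batch mean. By default the per-feature
#' grand mean (over all samples) is added back so that the pooled feature
#' location is preserved and downstream regression coefficients keep their
#' scale; `restore_grand_mean = FALSE` gives pure within-batch centering.
#'
#' @param a Abundance matrix (samples x features).
#' @param batch Per-sample batch labels.
#' @param restore_grand_mean Add back the per-feature overall mean.
#' @return Corrected abundance matrix.
#' @export
bmc <- function(a, batch, restore_grand_mean = TRUE) {
  batch <- check_batch_labels(a, batch)
  if (any(!is.finite(a))) stop("non-finite values in input", call. = FALSE)
  out <- a
  for (b in levels(batch)) {
    idx <- which(batch == b)
    out[idx, ] <- sweep(a[idx, , drop = FALSE], 2L,
                        colMeans(a[idx, , drop = FALSE]))
  }
  if (restore_grand_mean) out <- sweep(out, 2L, colMeans(a), `+`)
  attr(out, "transform") <- attr(a, "transform")
  out
}

#' ComBat parametric empirical-Bayes batch correction
#'
#' Thin validated wrapper over [sva::ComBat()] with parametric priors and no
#' covariate design: per-feature standardization, per-batch location/scale
#' estimates shrunk to priors fitted across features, adjustment, and
#' back-transformation. Features with zero pooled variance are passed
#' through unchanged (they carry no batch information and would otherwise
#' divide by zero during standardization).
#'
#' @param a Abundance matrix (samples x features).
#' @param batch Per-sample batch labels; at least 2 batches with at least 2
#'   samples each.
#' @return Corrected abundance matrix.
#' @export
combat_correct <- function(a, batch) {
  batch <- check_batch_labels(a, batch)
  sizes <- table(batch)
  if (length(sizes) < 2L)
    stop("ComBat needs at least two batches", call. = FALSE)
  if (any(sizes < 2L))
    stop("ComBat needs at least two samples per batch (batch of size 1: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), ")", call. = FALSE)
  dat <- t(a)                               # features x samples for sva
  keep <- apply(dat, 1L, stats::var) > 1e-12
  out <- dat
  if (sum(keep) >= 2L) {
    log <- utils::capture.output(
      corrected <- suppressMessages(
        sva::ComBat(dat[keep, , drop = FALSE], batch = batch, mod = NULL,
                    par.prior = TRUE, prior.plots = FALSE)))
    out[keep, ] <- corrected
  }
  res <- t(out)
  attr(res, "transform") <- attr(a, "transform")
  res
}

#' Zero-preserving log-linear batch correction for counts (MMUPHin-like)
#'
#' A simplified reimplementation of the count-level correction idea of
#' MMUPHin (not a port): per feature, batch location offsets are estimated
#' on the log scale from the nonzero entries, shrunk toward zero by an
#' empirical-Bayes factor fitted across features, and divided out on the
#' natural scale. Zeros remain exactly zero. Count input is rounded back to
#' integers; relative-abundance input is re-normalized to row sums 1.
#'
#' @param m Nonnegative count matrix or relative-abundance matrix.
#' @param batch Per-sample batch labels.
#' @param type `"counts"` (default) or `"relative_abundance"`.
#' @return Corrected matrix of the same type as the input.
#' @export
mmuphin_like <- function(m, batch, type = c("counts", "relative_abundance")) {
  type <- match.arg(type)
  batch <- check_batch_labels(m, batch)
  if (any(m < 0)) stop("negative values in input", call. = FALSE)
  B <- nlevels(batch)
  p <- ncol(m)
  gamma <- matrix(0, B, p)            # per (batch, feature) log offsets
  se2 <- matrix(NA_real_, B, p)
  for (j in seq_len(p)) {
    means <- rep(NA_real_, B)
    for (b in seq_len(B)) {
      v <- m[batch == levels(batch)[b], j]
      v <- v[v > 0]
      if (length(v) >= 1L) {
        lv <- log(v)
        means[b] <- mean(lv)
        se2[b, j] <- if (length(lv) >= 2L) stats::var(lv) / length(lv)
                     else NA_real_
      }
    }
    if (sum(!is.na(means)) >= 2L) {
      grand <- mean(means, na.rm = TRUE)
      gamma[, j] <- ifelse(is.na(means), 0, means - grand)
    }
  }
  # empirical-Bayes shrinkage toward 0: prior variance from the spread of
  # offsets across features, in excess of their sampling variance
  ok <- !is.na(se2) & gamma != 0
  shrunk <- matrix(0, B, p)
  if (any(ok)) {
    tau2 <- max(0, stats::var(gamma[ok]) - mean(se2[ok]))
    lambda <- matrix(0, B, p)
    lambda[ok] <- tau2 / (tau2 + se2[ok])
    shrunk <- gamma * lambda
  }
  out <- m
  for (b in seq_len(B)) {
    idx <- which(batch == levels(batch)[b])
    out[idx, ] <- sweep(m[idx, , drop = FALSE], 2L, exp(shrunk[b, ]), `/`)
  }
  out[m == 0] <- 0
  if (type == "counts") {
    out <- round(out)
    storage.mode(out) <- "integer"
  } else {
    out <- out / rowSums(out)
  }
  out
}

#' Remove batch-associated PLS components from a CLR-family matrix
#'
#' Fits partial-least-squares components of the (column-centered) data
#' against one-hot batch labels and subtracts the data's projection onto the
#' first `k` batch-associated components; feature means are then restored.
#'
#' @param a Abundance matrix produced by [clr()] or [clr_c()].
#' @param batch Per-sample batch labels.
#' @param k Number of components; default `min(n_batches - 1, 5)`.
#' @return Corrected abundance matrix.
#' @export
plsda_correct <- function(a, batch, k = NULL) {
  batch <- check_batch_labels(a, batch)
  k <- k %||% max(1L, min(nlevels(batch) - 1L, 5L))
  if (k < 1L) stop("k must be at least 1", call. = FALSE)
  if (k >= min(nrow(a), ncol(a)))
    stop("k must be smaller than min(n_samples, n_features)", call. = FALSE)
  mu <- colMeans(a)
  Xc <- sweep(a, 2L, mu)
  Y <- stats::model.matrix(~ batch - 1)
  Yc <- sweep(Y, 2L, colMeans(Y))
  for (comp in seq_len(k)) {
    M <- crossprod(Xc, Yc)
    if (sqrt(sum(M^2)) < 1e-12) break   # no remaining batch covariance
    w <- svd(M, nu = 1L, nv = 0L)$u[, 1L]
    t_scores <- Xc %*% w
    denom <- sum(t_scores^2)
    if (denom < 1e-12) break
    p_load <- crossprod(Xc, t_scores) / denom
    c_load <- crossprod(Yc, t_scores) / denom
    Xc <- Xc - t_scores %*% t(p_load)
    Yc <- Yc - t_scores %*% t(c_load)
  }
  out <- sweep(Xc, 2L, mu, `+`)
  dimnames(out) <- dimnames(a)
  attr(out, "transform") <- attr(a, "transform")
  out
}

#' Run one transformation x batch-correction combination
#'
#' Executes the two stages in the order required by the combination: the
#' count-level MMUPHin-like correction runs on raw counts before the
#' transformation; every other correction runs on the transformed matrix.
#'
#' @param m Count matrix.
#' @param batch Per-sample batch labels.
#' @param spec A [combination_spec()].
#' @param plsda_k Optional PLSDA component count override.
#' @return Abundance matrix.
#' @export
apply_combination <- function(m, batch, spec, plsda_k = NULL) {
  stopifnot(inherits(spec, "combination_spec"))
  if (spec$order == "correction_first") {
    corrected <- mmuphin_like(m, batch, type = "counts")
    out <- apply_transform(corrected, spec$transform)
  } else {
    transformed <- apply_transform(m, spec$transform)
    out <- switch(spec$correction,
                  COMBAT = combat_correct(transformed, batch),
                  BMC = bmc(transformed, batch),
                  PLSDA = plsda_correct(transformed, batch, k = plsda_k),
                  stop("unknown correction: ", spec$correction, call. = FALSE))
  }
  attr(out, "combination") <- spec$label
  out
}
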
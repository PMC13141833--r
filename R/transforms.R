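# The four per-sample data transformations applied before (or after, for the
# count-level batch correction) batch-effect removal: CLR with a unit offset
# for zeros, CLR_C with multiplicative zero replacement, relative abundance,
# and log-CPM followed by quantile normalization (the "voom-style" matrix;
# voom's precision weights are deliberately not computed since downstream
# inference is IPTW-weighted regression, not limma).

as_abundance <- function(values, source, transform) {
  dimnames(values) <- dimnames(source)
  attr(values, "transform") <- transform
  values
}

check_counts_input <- function(m) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("expected a numeric count matrix", call. = FALSE)
  if (ncol(m) < 1L) stop("need at least one feature", call. = FALSE)
  invisible(m)
}

#' Centered log-ratio transform with unit offset for zeros
#'
#' Per sample, zeros are offset to 1 and each value becomes
#' `ln(count) - mean(ln(count))` over features, so every transformed row
#' sums to zero.
#'
#' @param m Count matrix (samples x features).
#' @return Abundance matrix of the same shape.
#' @export
clr <- function(m) {
  check_counts_input(m)
  x <- pmax(m, 1)
  lx <- log(x)
  as_abundance(lx - rowMeans(lx), m, "CLR")
}

#' Centered log-ratio transform with multiplicative zero replacement
#'
#' Per sample, zeros are imputed by `delta = 0.5 x` (smallest nonzero count
#' in that sample) and the nonzero counts are shrunk by
#' `1 - n_zeros * delta / total` so the sample total is preserved; the CLR is
#' then taken without further offset.
#'
#' @param m Count matrix; every sample must have at least one nonzero count.
#' @return Abundance matrix of the same shape.
#' @export
clr_c <- function(m) {
  check_counts_input(m)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) {
    row <- as.numeric(m[i, ])
    nz <- row > 0
    if (!any(nz))
      stop(sprintf("sample '%s' has all-zero counts", rownames(m)[i]),
           call. = FALSE)
    if (all(nz)) adj <- row
    else {
      delta <- 0.5 * min(row[nz])
      adj <- row * (1 - sum(!nz) * delta / sum(row))
      adj[!nz] <- delta
    }
    lx <- log(adj)
    out[i, ] <- lx - mean(lx)
  }
  as_abundance(out, m, "CLR_C")
}

#' Relative abundance (total-sum scaling)
#'
#' @param m Count matrix; every sample must have a positive total.
#' @return Abundance matrix whose rows sum to 1.
#' @export
relative_abundance <- function(m) {
  check_counts_input(m)
  totals <- rowSums(m)
  if (any(totals <= 0))
    stop(sprintf("sample '%s' has all-zero counts",
                 rownames(m)[which(totals <= 0)[1L]]), call. = FALSE)
  as_abundance(m / totals, m, "RA")
}

#' Log-CPM with quantile normalization (voom-style matrix)
#'
#' Per cell, `log2((count + 0.5) / (sample_total + 1) * 1e6)`, followed by
#' quantile normalization across samples (each sample's sorted values are
#' replaced by the rank-wise mean of sorted values over samples; ties share
#' the mean over their rank span, via [limma::normalizeQuantiles()]).
#'
#' @param m Count matrix; every sample must have a positive total.
#' @param quantile_normalize Set `FALSE` to return the raw log-CPM values.
#' @return Abundance matrix of the same shape.
#' @export
voom_log_cpm <- function(m, quantile_normalize = TRUE) {
  check_counts_input(m)
  totals <- rowSums(m)
  if (any(totals <= 0))
    stop(sprintf("sample '%s' has all-zero counts",
                 rownames(m)[which(totals <= 0)[1L]]), call. = FALSE)
  lcpm <- log2((m + 0.5) / (totals + 1) * 1e6)
  if (quantile_normalize)
    lcpm <- t(limma::normalizeQuantiles(t(lcpm), ties = TRUE))
  as_abundance(lcpm, m, "VOOM")
}

TRANSFORM_FUNS <- list(CLR = clr, CLR_C = clr_c, RA = relative_abundance,
                       VOOM = voom_log_cpm)

#' Apply a named transformation
#' @param m Count matrix.
#' @param transform One of `"CLR"`, `"CLR_C"`, `"RA"`, `"VOOM"`.
#' @return Abundance matrix.
#' @export
apply_transform <- function(m, transform) {
  fun <- TRANSFORM_FUNS[[transform]]
  if (is.null(fun)) stop("unknown transform: ", transform, call. = FALSE)
  fun(m)
}
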
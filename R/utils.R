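#' @keywords internal
"_PACKAGE"

# Run expr with a fixed RNG seed without clobbering the caller's RNG stream.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Weighted mean/variance with weights normalized to sum(w); population form,
# so that unit weights at large n agree with the usual moments.
weighted_moments <- function(x, w) {
  sw <- sum(w)
  m <- sum(w * x) / sw
  v <- sum(w * (x - m)^2) / sw
  c(mean = m, var = v)
}

assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}
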
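# Internal helpers shared across modules.

#' @importFrom stats sd
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(x - mean(x))
  (x - mean(x)) / s
}

#' Column-wise z-scoring of a time-by-parcel matrix
#'
#' Zero-variance columns are demeaned rather than divided by zero.
#'
#' @param x T x R numeric matrix.
#' @return matrix of the same shape with each column standardised.
#' @export
zscore_cols <- function(x) {
  apply(x, 2, zscore)
}

# Derive a stream of child seeds (< 2^31) from one parent seed.  Used so a
# single top-level seed drives every stochastic stage reproducibly.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopifnot_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a single positive number", name), call. = FALSE)
  }
}
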
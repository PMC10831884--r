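#' Canonical double-gamma haemodynamic response function
#'
#' Evaluates the canonical two-gamma HRF used by the synthetic BOLD forward
#' model: a positive gamma lobe peaking at \code{peak_s} seconds minus an
#' undershoot lobe peaking at \code{undershoot_s} seconds, scaled by
#' \code{ratio}. Gamma lobes are parameterised so their modes fall exactly at
#' the stated delays (shape = delay * rate + 1). The returned kernel is
#' normalised to unit peak.
#'
#' @param t numeric vector of times in seconds (values < 0 return 0).
#' @param peak_s time-to-peak of the positive lobe, seconds.
#' @param undershoot_s time-to-peak of the undershoot lobe, seconds.
#' @param ratio amplitude of the undershoot relative to the peak lobe.
#' @param rate rate parameter of both gamma lobes (1/s); larger values give
#'   narrower lobes.
#' @return numeric vector, \code{h(t)}, unit peak amplitude.
#' @examples
#' tt <- seq(0, 30, by = 0.72)
#' h <- hrf_double_gamma(tt)
#' tt[which.max(h)] # close to 6 s
#' @export
hrf_double_gamma <- function(t, peak_s = 6, undershoot_s = 16,
                             ratio = 1 / 6, rate = 1) {
  stopifnot(peak_s > 0, undershoot_s > peak_s, ratio >= 0, rate > 0)
  h <- dgamma(t, shape = peak_s * rate + 1, rate = rate) -
    ratio * dgamma(t, shape = undershoot_s * rate + 1, rate = rate)
  h[t < 0] <- 0
  # unit peak on a fine grid so scaling is independent of the sample grid
  fine <- seq(0, undershoot_s * 2, by = 0.01)
  hf <- dgamma(fine, shape = peak_s * rate + 1, rate = rate) -
    ratio * dgamma(fine, shape = undershoot_s * rate + 1, rate = rate)
  h / max(hf)
}

# Discrete causal convolution of each column of `x` (timepoints x channels)
# with kernel `h`; output truncated to nrow(x).
convolve_hrf <- function(x, h) {
  x <- as.matrix(x)
  n <- nrow(x)
  out <- matrix(0, n, ncol(x))
  for (j in seq_len(ncol(x))) {
    full <- stats::convolve(x[, j], rev(h), type = "open")
    out[, j] <- full[seq_len(n)]
  }
  out
}
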
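# Canonical double-gamma haemodynamic response model used by the
# synthetic-data generator. The generator convolves this kernel with the
# 30 s regulation boxcar to produce the "true" neural HbO response.

# peak-normalisation constant, computed once at load on a fine grid
.hrf_raw <- function(t) {
  stats::dgamma(t, shape = 7, rate = 1) - stats::dgamma(t, shape = 16, rate = 1) / 6
}
.hrf_peak <- max(.hrf_raw(seq(0, 30, by = 0.001)))

#' Double-gamma haemodynamic response function
#'
#' Canonical double-gamma impulse response with its peak near 6 s and a
#' late undershoot near 16 s, normalised so the peak value is 1. This is
#' the response model behind the synthetic block-design recordings; the
#' analysis chain itself never assumes a response shape.
#'
#' @param t Time in seconds since stimulus onset. Must be non-negative.
#' @return Unitless response values, peak-normalised to 1.
#' @examples
#' hrf(c(0, 6, 16))
#' @export
hrf <- function(t) {
  if (!is.numeric(t)) stop("`t` must be numeric")
  if (any(t < 0)) stop("hrf() is defined for t >= 0 only")
  .hrf_raw(t) / .hrf_peak
}
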
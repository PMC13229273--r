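#' Canonical double-gamma haemodynamic response function
#'
#' The canonical HRF as a difference of two gamma densities, parameterised by
#' the response peak (mode of the positive lobe, default 6 s), the undershoot
#' peak (default 16 s) and the peak:undershoot amplitude ratio (default 6).
#' The returned curve is scaled to a maximum of 1.
#'
#' @param t Time in seconds (vector).
#' @param peak Time-to-peak of the response (s).
#' @param undershoot Time-to-peak of the undershoot (s).
#' @param ratio Peak to undershoot amplitude ratio.
#' @return Numeric vector of HRF values at `t`.
#' @export
hrf_double_gamma <- function(t, peak = 6, undershoot = 16, ratio = 6) {
  h <- dgamma(t, shape = peak + 1, rate = 1) -
    dgamma(t, shape = undershoot + 1, rate = 1) / ratio
  h[t < 0] <- 0
  h / max(dgamma(0:40, shape = peak + 1, rate = 1) -
            dgamma(0:40, shape = undershoot + 1, rate = 1) / ratio)
}

# Convolve a set of events (onset, duration, amplitude) with the HRF on a
# microtime grid and sample the result at the acquisition times. Durations
# enter as boxcars on the microtime grid before convolution.
convolve_events <- function(onsets, durations, sample_times,
                            amplitudes = rep(1, length(onsets)),
                            dt = 0.1, hrf = list()) {
  if (length(onsets) == 0L) return(numeric(length(sample_times)))
  t_max <- max(sample_times) + 32
  grid_n <- ceiling(t_max / dt) + 1L
  u <- numeric(grid_n)
  for (k in seq_along(onsets)) {
    from <- floor(onsets[k] / dt) + 1L
    to <- max(from, floor((onsets[k] + durations[k]) / dt))
    to <- min(to, grid_n)
    if (from <= grid_n) u[from:to] <- u[from:to] + amplitudes[k]
  }
  h <- do.call(hrf_double_gamma, c(list(t = seq(0, 32, by = dt)), hrf)) * dt
  x <- convolve(u, rev(h), type = "open")[seq_len(grid_n)]
  x[pmin(grid_n, floor(sample_times / dt) + 1L)]
}
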
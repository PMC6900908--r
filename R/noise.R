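# 1/f^chi coloured Gaussian noise, shaped in the frequency domain.
# A real white draw is filtered by the symmetric gain |f|^(-chi/2); frequencies
# below f_floor share the floor gain so the variance stays finite near DC.
# Output is normalized to unit standard deviation. Uses the caller's RNG
# stream (callers are responsible for seeding).
colored_noise <- function(n, fs, chi = 1, f_floor = 0.5) {
  stopifnot(n > 8, chi >= 0, f_floor > 0)
  w <- stats::rnorm(n)
  if (chi == 0) return(w / stats::sd(w))
  X <- stats::fft(w)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)            # two-sided |f|
  gain <- pmax(f, f_floor)^(-chi / 2)
  gain[1] <- 0                    # remove DC
  x <- Re(stats::fft(X * gain, inverse = TRUE) / n)
  x / stats::sd(x)
}

#' Spectral slope of a signal in dB per decade
#'
#' Least-squares fit of `log10(PSD)` on `log10(frequency)` over `f_range`,
#' using the Welch estimate; a 1/f^chi process has slope `-10 * chi`.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param f_range `c(low, high)` fitting range in Hz.
#' @param window_sec Welch window length, seconds.
#' @return Slope in dB/decade.
#' @export
psd_slope_db_per_decade <- function(x, fs, f_range, window_sec = 1) {
  p <- welch_psd(x, fs, window_sec = window_sec)
  keep <- p$freq >= f_range[1] & p$freq <= f_range[2] & p$psd > 0
  fit <- stats::lm(log10(p$psd[keep]) ~ log10(p$freq[keep]))
  10 * unname(stats::coef(fit)[2])
}
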
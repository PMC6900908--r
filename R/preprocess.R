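# FIR design and zero-phase application.
#
# Filters are windowed-sinc (Hamming) designs from signal::fir1. A symmetric
# (linear-phase) FIR applied once and compensated for its group delay is
# exactly zero phase, so application is a single FFT convolution with edge
# reflection rather than a forward-backward pass; this halves the cost on
# long multichannel records and keeps the designed magnitude response.

fir_taps_for_transition <- function(fs, transition_hz) {
  n <- ceiling(3.3 * fs / transition_hz)  # Hamming window transition width
  if (n %% 2 == 0) n <- n + 1             # odd length -> integer group delay
  as.integer(n)
}

# zero-phase application of a symmetric odd-length FIR to a channels-by-
# samples matrix: edge-reflected, FFT overlap-free convolution at a padded
# length with small prime factors, all channels in one mvfft call
fir_zerophase_matrix <- function(x, b) {
  nb <- length(b)
  stopifnot(nb %% 2 == 1)
  half <- (nb - 1L) %/% 2L
  n <- ncol(x)
  if (n <= half + 1L)
    stop("signal too short for this filter (", nb, " taps)")
  # reflect edges to suppress startup transients
  xp <- cbind(x[, (half + 1L):2, drop = FALSE], x,
              x[, (n - 1L):(n - half), drop = FALSE])
  np <- ncol(xp)
  L <- stats::nextn(np + nb - 1L, c(2, 3, 5))
  X <- rbind(t(xp), matrix(0, L - np, nrow(x)))
  B <- stats::fft(c(b, rep(0, L - nb)))
  Y <- Re(stats::mvfft(stats::mvfft(X) * B, inverse = TRUE)) / L
  t(Y[(2L * half + 1L):(2L * half + n), , drop = FALSE])
}

fir_zerophase <- function(x, b) {
  drop(fir_zerophase_matrix(matrix(x, nrow = 1), b))
}

apply_fir <- function(rec, b) {
  out <- rec
  out$data <- fir_zerophase_matrix(rec$data, b)
  dimnames(out$data) <- dimnames(rec$data)
  out
}

#' Downsample a recording by an integer factor
#'
#' Applies an anti-alias low-pass (Hamming-window FIR, cutoff at 0.4 times the
#' target rate) before decimation. Epoch bounds are in seconds and carry over
#' unchanged.
#'
#' @param rec An [eeg_recording()].
#' @param target_fs Target sampling rate; must divide `rec$fs` exactly.
#' @return The decimated [eeg_recording()].
#' @export
downsample <- function(rec, target_fs = 250) {
  stopifnot(inherits(rec, "eeg_recording"))
  ratio <- rec$fs / target_fs
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("target_fs must divide the original sampling rate")
  ratio <- as.integer(round(ratio))
  if (ratio == 1L) return(rec)
  cutoff <- 0.4 * target_fs
  taps <- fir_taps_for_transition(rec$fs, 0.1 * target_fs)
  b <- signal::fir1(taps - 1L, cutoff / (rec$fs / 2), type = "low")
  out <- apply_fir(rec, b)
  out$data <- out$data[, seq(1, ncol(out$data), by = ratio), drop = FALSE]
  out$fs <- target_fs
  out
}

#' Zero-phase FIR band-pass filter
#'
#' Windowed-sinc (Hamming) band-pass with a 0.5 Hz transition at the low edge,
#' applied with exact zero phase. The default 0.5--50 Hz band is the standard
#' broadband EEG passband used before band-power analysis.
#'
#' @param rec An [eeg_recording()].
#' @param band `c(low, high)` in Hz; requires `0 < low < high < fs/2`.
#' @return Filtered [eeg_recording()].
#' @export
bandpass <- function(rec, band = c(0.5, 50)) {
  stopifnot(inherits(rec, "eeg_recording"), length(band) == 2)
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < rec$fs / 2))
    stop("band must satisfy 0 < low < high < Nyquist")
  taps <- fir_taps_for_transition(rec$fs, 0.5)
  b <- signal::fir1(taps - 1L, band / (rec$fs / 2), type = "pass")
  apply_fir(rec, b)
}

#' Zero-phase FIR notch (band-stop) filter
#'
#' Realized as a narrow band-stop FIR (default 58--62 Hz) removing power-line
#' interference at 60 Hz.
#'
#' @param rec An [eeg_recording()].
#' @param center Notch centre frequency in Hz (< Nyquist).
#' @param width Full stop-band width in Hz (default 4).
#' @return Filtered [eeg_recording()].
#' @export
notch <- function(rec, center = 60, width = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (center >= rec$fs / 2) stop("notch centre must be below Nyquist")
  edges <- c(center - width / 2, center + width / 2)
  taps <- fir_taps_for_transition(rec$fs, 1)
  b <- signal::fir1(taps - 1L, edges / (rec$fs / 2), type = "stop")
  apply_fir(rec, b)
}

#' Standard preprocessing chain
#'
#' Downsample to 250 Hz, band-pass 0.5--50 Hz, notch at 60 Hz -- the chain
#' applied to every recording before spectral analysis.
#'
#' @param rec An [eeg_recording()].
#' @param target_fs Decimation target (default 250 Hz).
#' @param band Band-pass edges (default `c(0.5, 50)`).
#' @param notch_center Notch frequency (default 60 Hz); `NA` skips the notch.
#' @return Preprocessed [eeg_recording()].
#' @export
preprocess_recording <- function(rec, target_fs = 250, band = c(0.5, 50),
                                 notch_center = 60) {
  out <- downsample(rec, target_fs)
  out <- bandpass(out, band)
  if (!is.na(notch_center)) out <- notch(out, notch_center)
  out
}
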
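#' Canonical EEG frequency bands
#'
#' Half-open intervals `[low, high)` so the shared edges at 4, 8, 13 and
#' 30 Hz are never double counted: delta 0.5--4, theta 4--8, alpha 8--13,
#' beta 13--30, gamma 30--50 Hz.
#'
#' @return Named list of `c(low, high)` pairs.
#' @export
band_defs <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
       beta = c(13, 30), gamma = c(30, 50))
}

#' Welch power spectral density
#'
#' Averaged modified periodograms: Hann windows of `window_sec` seconds with
#' `overlap` fractional overlap, segment means removed, one-sided density
#' scaling (integrating the PSD over frequency recovers the signal variance).
#' The 4 s default gives 0.25 Hz resolution -- fine enough to resolve the
#' 6 Hz bin and the 0.5 Hz band edge.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param window_sec Segment length in seconds (default 4).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return List with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, window_sec = 4, overlap = 0.5) {
  nper <- round(window_sec * fs)
  if (length(x) < 2 * nper)
    stop("signal too short: need at least two Welch windows (",
         2 * window_sec, " s)")
  w <- 0.5 * (1 - cos(2 * pi * (0:(nper - 1)) / nper))  # periodic Hann
  step <- max(1L, floor(nper * (1 - overlap)))
  starts <- seq.int(1L, length(x) - nper + 1L, by = step)
  segs <- vapply(starts, function(s) {
    seg <- x[s:(s + nper - 1L)]
    (seg - mean(seg)) * w
  }, numeric(nper))
  P <- rowMeans(Mod(stats::mvfft(segs))^2)
  nfreq <- nper %/% 2 + 1L
  psd <- P[seq_len(nfreq)] / (fs * sum(w^2))
  # one-sided: double everything except DC (and Nyquist when nper is even)
  dbl <- seq_len(nfreq) > 1L
  if (nper %% 2 == 0) dbl[nfreq] <- FALSE
  psd[dbl] <- 2 * psd[dbl]
  list(freq = (seq_len(nfreq) - 1L) * fs / nper, psd = psd)
}

#' Band power of a single channel
#'
#' Integrates the Welch PSD over the half-open interval `[low, high)`.
#'
#' @param x Numeric signal (one channel).
#' @param fs Sampling rate, Hz.
#' @param band `c(low, high)` in Hz, or the name of a canonical band.
#' @param ... Passed to [welch_psd()].
#' @return Non-negative power (signal units squared).
#' @export
band_power <- function(x, fs, band, ...) {
  if (is.character(band)) band <- band_defs()[[match.arg(band, names(band_defs()))]]
  p <- welch_psd(x, fs, ...)
  df <- p$freq[2] - p$freq[1]
  sum(p$psd[p$freq >= band[1] & p$freq < band[2]]) * df
}

#' Per-channel, per-band power table for one epoch
#'
#' @param rec An [eeg_recording()].
#' @param epoch Epoch label (`"baseline"`, `"stimulation"`, `"post"`).
#' @param bands Named list of band edges (default [band_defs()]).
#' @param log10 Report `log10` power instead of linear power.
#' @param ... Passed to [welch_psd()].
#' @return A tibble (class `band_power_table`) with columns `epoch`,
#'   `channel`, `band`, `power`, and the montage attached as an attribute.
#' @export
band_power_table <- function(rec, epoch, bands = band_defs(), log10 = FALSE,
                             ...) {
  stopifnot(inherits(rec, "eeg_recording"))
  idx <- epoch_samples(rec, epoch)
  rows <- lapply(rownames(rec$data), function(ch) {
    p <- welch_psd(rec$data[ch, idx], rec$fs, ...)
    df <- p$freq[2] - p$freq[1]
    pw <- vapply(bands, function(b)
      sum(p$psd[p$freq >= b[1] & p$freq < b[2]]) * df, numeric(1))
    tibble::tibble(epoch = epoch, channel = ch, band = names(bands),
                   power = if (log10) base::log10(pw) else unname(pw))
  })
  out <- do.call(rbind, rows)
  attr(out, "montage") <- rec$montage
  class(out) <- c("band_power_table", class(out))
  out
}

#' Aggregate channel powers to a region
#'
#' Regional power is the arithmetic mean of the member channels' powers.
#'
#' @param table A [band_power_table()].
#' @param region Region name from the attached montage.
#' @param band Band name (default all bands present).
#' @return Tibble with `region`, `band`, `power`.
#' @export
region_power <- function(table, region, band = NULL) {
  montage <- attr(table, "montage")
  if (is.null(montage)) stop("table has no montage attribute")
  if (!region %in% names(montage$regions)) stop("unknown region: ", region)
  chans <- montage$regions[[region]]
  tab <- table[table$channel %in% chans, ]
  if (!is.null(band)) tab <- tab[tab$band %in% band, ]
  agg <- stats::aggregate(power ~ band, data = tab, FUN = mean)
  tibble::tibble(region = region, band = agg$band, power = agg$power)
}

#' Region-by-band aggregate of a power table
#'
#' @param table A [band_power_table()].
#' @return Tibble with `region`, `band`, `power` for every montage region.
#' @export
region_power_table <- function(table) {
  montage <- attr(table, "montage")
  out <- do.call(rbind, lapply(names(montage$regions),
                               function(r) region_power(table, r)))
  out
}

#' Stimulation-minus-baseline power change
#'
#' Elementwise difference of two power tables over the same montage and bands.
#'
#' @param stim,baseline [band_power_table()] objects with identical channel
#'   and band layout.
#' @return Tibble like the inputs with `power = stim - baseline` and an
#'   `epoch` label of `"change"`.
#' @export
power_change <- function(stim, baseline) {
  if (!identical(stim$channel, baseline$channel) ||
      !identical(stim$band, baseline$band))
    stop("power tables do not share a channel/band layout")
  out <- stim
  out$power <- stim$power - baseline$power
  out$epoch <- "change"
  attr(out, "montage") <- attr(stim, "montage")
  out
}

#' Midline peak at the target frequency
#'
#' Mean Welch PSD at the bin nearest the target frequency across the given
#' channels, reported as the stimulation / baseline ratio (the normalization
#' makes the peak unitless; a value of 1 means no entrainment).
#'
#' @param rec An [eeg_recording()].
#' @param target Target frequency, Hz (default 6).
#' @param channels Channels to average (default the montage midline region).
#' @param stim,baseline Epoch labels.
#' @param ... Passed to [welch_psd()].
#' @return Scalar peak ratio.
#' @export
peak_at_target <- function(rec, target = 6, channels = NULL,
                           stim = "stimulation", baseline = "baseline", ...) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(channels)) channels <- rec$montage$regions$midline
  idx_s <- epoch_samples(rec, stim)
  idx_b <- epoch_samples(rec, baseline)
  vals <- vapply(channels, function(ch) {
    ps <- welch_psd(rec$data[ch, idx_s], rec$fs, ...)
    pb <- welch_psd(rec$data[ch, idx_b], rec$fs, ...)
    if (ps$freq[2] - ps$freq[1] > 1)
      warning("PSD frequency grid coarser than 1 Hz")
    k <- which.min(abs(ps$freq - target))
    c(ps$psd[k], pb$psd[k])
  }, numeric(2))
  mean(vals[1, ]) / mean(vals[2, ])
}

#' Laterality index
#'
#' `LI = (L - R) / (L + R)` for non-negative hemisphere powers; bounded in
#' `[-1, 1]`, positive for left-hemisphere dominance.
#'
#' @param L,R Left and right hemisphere powers (>= 0, not both zero).
#' @return The laterality index.
#' @export
laterality_index <- function(L, R) {
  stopifnot(L >= 0, R >= 0)
  if (L + R == 0) stop("laterality index undefined: L + R = 0")
  (L - R) / (L + R)
}

#' Frontal alpha laterality of one epoch
#'
#' Alpha-band power averaged over the lateral prefrontal+frontal channels of
#' each hemisphere (left Fp1, F7, F3; right Fp2, F8, F4), combined into the
#' laterality index.
#'
#' @param rec An [eeg_recording()].
#' @param epoch Epoch label.
#' @param ... Passed to [welch_psd()].
#' @return List with `L`, `R`, `LI`.
#' @export
alpha_laterality <- function(rec, epoch, ...) {
  hemis <- laterality_channels()
  idx <- epoch_samples(rec, epoch)
  pow <- function(chans) mean(vapply(chans, function(ch)
    band_power(rec$data[ch, idx], rec$fs, "alpha", ...), numeric(1)))
  L <- pow(hemis$left); R <- pow(hemis$right)
  list(L = L, R = R, LI = laterality_index(L, R))
}
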
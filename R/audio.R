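#' Specification of a pure tone
#'
#' A `tone_spec` describes one sinusoid of the dichotic pair: the carrier
#' delivered to the left ear and the offset tone delivered to the right ear.
#' The perceived binaural beat equals the frequency difference between the two.
#'
#' @param frequency Tone frequency in Hz. Must be positive and below the
#'   Nyquist frequency `sample_rate / 2`.
#' @param duration Duration in seconds (> 0).
#' @param sample_rate Sampling rate in Hz. Default 44100.
#' @param phase Initial phase in radians.
#' @return An object of class `tone_spec`.
#' @examples
#' carrier <- tone_spec(250, duration = 1)
#' offset  <- tone_spec(256, duration = 1)
#' @export
tone_spec <- function(frequency, duration, sample_rate = 44100, phase = 0) {
  stopifnot(is.numeric(frequency), length(frequency) == 1L, is.finite(frequency))
  if (frequency <= 0) stop("tone frequency must be positive")
  if (frequency >= sample_rate / 2) {
    stop("tone frequency must be below the Nyquist frequency (sample_rate/2)")
  }
  if (!is.numeric(duration) || duration <= 0) stop("duration must be > 0")
  structure(
    list(frequency = frequency, duration = duration,
         sample_rate = sample_rate, phase = phase),
    class = "tone_spec"
  )
}

#' Two-channel audio container
#'
#' @param left,right Numeric sample vectors of equal length.
#' @param sample_rate Sampling rate in Hz.
#' @return A `stereo_audio` object (list with `left`, `right`, `sample_rate`).
#' @export
stereo_audio <- function(left, right, sample_rate) {
  if (length(left) != length(right)) stop("channel lengths differ")
  stopifnot(sample_rate > 0)
  structure(list(left = as.numeric(left), right = as.numeric(right),
                 sample_rate = sample_rate),
            class = "stereo_audio")
}

#' @export
print.stereo_audio <- function(x, ...) {
  cat(sprintf("<stereo_audio> %d samples/channel @ %g Hz (%.2f s), RMS %.4g\n",
              length(x$left), x$sample_rate, length(x$left) / x$sample_rate,
              audio_rms(x)))
  invisible(x)
}

#' Root-mean-square level of stereo audio
#'
#' Level is measured as the RMS over the whole file, averaged across the two
#' channels (arithmetic mean of the per-channel RMS values).
#'
#' @param audio A [stereo_audio()] object.
#' @return Scalar RMS.
#' @export
audio_rms <- function(audio) {
  stopifnot(inherits(audio, "stereo_audio"))
  mean(c(sqrt(mean(audio$left^2)), sqrt(mean(audio$right^2))))
}

#' Convert a decibel difference to an amplitude gain
#'
#' @param delta_db Level difference in dB.
#' @return Linear amplitude gain `10^(delta_db/20)`.
#' @examples
#' db_to_amplitude(0)    # 1
#' db_to_amplitude(-30)  # 0.03162
#' @export
db_to_amplitude <- function(delta_db) {
  if (!all(is.finite(delta_db))) stop("delta_db must be finite")
  10^(delta_db / 20)
}

#' Synthesize a binaural-beat stimulus from two tone specifications
#'
#' Renders the carrier sinusoid on the left channel and the offset sinusoid on
#' the right channel. When the two channels are summed (as in the acoustic
#' superposition the auditory system performs centrally), the envelope of the
#' sum is modulated at the beat frequency `|offset - carrier|`; with the
#' default 250/256 Hz pair the beat is 6 Hz, the centre of the theta band.
#'
#' @param carrier,offset [tone_spec()] objects sharing `duration` and
#'   `sample_rate`.
#' @param amplitude Peak amplitude of each tone (default 1).
#' @return A [stereo_audio()] object.
#' @export
synthesize_binaural <- function(carrier, offset, amplitude = 1) {
  stopifnot(inherits(carrier, "tone_spec"), inherits(offset, "tone_spec"))
  if (carrier$sample_rate != offset$sample_rate)
    stop("carrier and offset tones must share a sample rate")
  if (carrier$duration != offset$duration)
    stop("carrier and offset tones must share a duration")
  fs <- carrier$sample_rate
  n <- round(carrier$duration * fs)
  t <- (seq_len(n) - 1) / fs
  stereo_audio(
    left  = amplitude * sin(2 * pi * carrier$frequency * t + carrier$phase),
    right = amplitude * sin(2 * pi * offset$frequency * t + offset$phase),
    sample_rate = fs
  )
}

#' Calibrate stereo audio to a target relative level
#'
#' Rescales both channels jointly so the channel-averaged RMS equals
#' `reference_rms * 10^(target_db/20)`. Printed sound-pressure levels cannot
#' be realized in a digital file, so levels here are relative: `reference_rms`
#' anchors 0 dB on the package's digital scale and all printed *differences*
#' (e.g. the 30:60 mix ratio) are preserved exactly.
#'
#' @param audio A [stereo_audio()] object; must not be silent.
#' @param target_db Target level in dB relative to the anchor.
#' @param reference_rms RMS that defines 0 dB. Default `2e-4`, which places a
#'   60 dB signal at RMS 0.2 -- comfortably inside full scale.
#' @return Calibrated [stereo_audio()].
#' @export
calibrate_rms_level <- function(audio, target_db, reference_rms = 2e-4) {
  stopifnot(inherits(audio, "stereo_audio"), reference_rms > 0)
  cur <- audio_rms(audio)
  if (cur == 0) stop("cannot calibrate silent audio: level is undefined")
  g <- reference_rms * db_to_amplitude(target_db) / cur
  stereo_audio(audio$left * g, audio$right * g, audio$sample_rate)
}

# filter/AM parameters distinguishing the five surrogate natural sounds;
# chi is the 1/f^chi spectral exponent (slope = -10*chi dB/decade in power)
.asmr_kinds <- list(
  rain      = list(chi = 1.0, am_rate = 8.0, am_depth = 0.10),
  waves     = list(chi = 1.2, am_rate = 0.1, am_depth = 0.70),
  waterfall = list(chi = 0.8, am_rate = 0.0, am_depth = 0.00),
  forest    = list(chi = 1.3, am_rate = 0.3, am_depth = 0.30),
  river     = list(chi = 1.1, am_rate = 0.5, am_depth = 0.20)
)

#' Surrogate ASMR-style natural sound
#'
#' Seeded broadband noise standing in for the five natural-sound triggers
#' (rain, sea waves, waterfall, forest, river). Each kind is 1/f-shaped noise
#' with a documented spectral tilt and amplitude-modulation setting; the five
#' kinds differ only in those parameters. Output is reproducible from
#' `(kind, seed)` and peak-normalized to 0.9.
#'
#' @param kind One of `"rain"`, `"waves"`, `"waterfall"`, `"forest"`,
#'   `"river"`.
#' @param duration Duration in seconds (> 0).
#' @param sample_rate Sampling rate in Hz.
#' @param seed Integer seed.
#' @return A [stereo_audio()] object.
#' @export
generate_surrogate_asmr <- function(kind, duration, sample_rate = 44100,
                                    seed = 1L) {
  if (!is.character(kind) || length(kind) != 1L || !kind %in% names(.asmr_kinds))
    stop("unknown surrogate sound kind: ", paste(kind, collapse = ", "),
         " (expected one of ", paste(names(.asmr_kinds), collapse = ", "), ")")
  if (duration <= 0) stop("duration must be > 0")
  p <- .asmr_kinds[[kind]]
  n <- round(duration * sample_rate)
  # decorrelate kinds sharing a seed, and the two channels
  base <- (as.integer(seed) + 7L * match(kind, names(.asmr_kinds))) %% .Machine$integer.max
  ch <- lapply(0:1, function(k) {
    set.seed(base + k)
    x <- colored_noise(n, sample_rate, chi = p$chi, f_floor = 20)
    if (p$am_depth > 0 && p$am_rate > 0) {
      t <- (seq_len(n) - 1) / sample_rate
      ph <- stats::runif(1, 0, 2 * pi)
      x <- x * (1 + p$am_depth * sin(2 * pi * p$am_rate * t + ph))
    }
    x
  })
  peak <- max(abs(c(ch[[1]], ch[[2]])))
  stereo_audio(0.9 * ch[[1]] / peak, 0.9 * ch[[2]] / peak, sample_rate)
}

#' Mixing specification for a combined stimulus condition
#'
#' Encodes the fixed decibel ratios of the combined-stimulus (CS) conditions:
#' CS1 mixes the binaural beat at 45 dB against the natural sound at 60 dB,
#' CS2 at 30:60, CS3 at 20:60. `BB_only` and `AT_only` play a single component
#' at 60 dB; `SHAM` is silence.
#'
#' @param condition_label One of `"CS1"`, `"CS2"`, `"CS3"`, `"BB_only"`,
#'   `"AT_only"`, `"SHAM"`.
#' @return A `mix_spec` with fields `bb_level_db`, `asmr_level_db`,
#'   `condition_label` (`NA` level means the component is absent).
#' @export
mix_spec <- function(condition_label) {
  levels <- switch(condition_label,
    CS1     = c(bb = 45, asmr = 60),
    CS2     = c(bb = 30, asmr = 60),
    CS3     = c(bb = 20, asmr = 60),
    BB_only = c(bb = 60, asmr = NA_real_),
    AT_only = c(bb = NA_real_, asmr = 60),
    SHAM    = c(bb = NA_real_, asmr = NA_real_),
    stop("unknown condition label: ", condition_label)
  )
  structure(list(bb_level_db = unname(levels["bb"]),
                 asmr_level_db = unname(levels["asmr"]),
                 condition_label = condition_label),
            class = "mix_spec")
}

#' Mix a binaural beat with surrogate natural sound at a fixed dB ratio
#'
#' Both components are calibrated to their condition levels on the shared
#' relative scale and summed channelwise; the ASMR track is trimmed or looped
#' to the beat's duration first. If the sum would clip, both components are
#' scaled jointly (preserving the ratio) to leave headroom, and the applied
#' gain is recorded in the `headroom_gain` attribute.
#'
#' @param bb Binaural-beat [stereo_audio()] (ignored for `AT_only`/`SHAM`).
#' @param asmr Natural-sound [stereo_audio()] (ignored for `BB_only`/`SHAM`).
#' @param spec A [mix_spec()].
#' @param reference_rms Anchor for 0 dB, see [calibrate_rms_level()].
#' @param headroom Maximum allowed absolute sample value (default 0.99).
#' @return Mixed [stereo_audio()] with attribute `headroom_gain`.
#' @export
mix_combined <- function(bb, asmr, spec, reference_rms = 2e-4,
                         headroom = 0.99) {
  stopifnot(inherits(spec, "mix_spec"))
  use_bb <- !is.na(spec$bb_level_db)
  use_asmr <- !is.na(spec$asmr_level_db)
  if (use_bb && use_asmr && bb$sample_rate != asmr$sample_rate)
    stop("sample-rate mismatch between components")
  ref <- if (use_bb) bb else if (use_asmr) asmr else NULL
  if (is.null(ref)) { # SHAM: silence of nominal 1 s unless a template exists
    n <- if (!missing(bb) && inherits(bb, "stereo_audio")) length(bb$left) else 44100L
    fs <- if (!missing(bb) && inherits(bb, "stereo_audio")) bb$sample_rate else 44100
    out <- stereo_audio(numeric(n), numeric(n), fs)
    attr(out, "headroom_gain") <- 1
    return(out)
  }
  n <- length(ref$left)
  fs <- ref$sample_rate
  acc_l <- numeric(n); acc_r <- numeric(n)
  if (use_bb) {
    cb <- calibrate_rms_level(bb, spec$bb_level_db, reference_rms)
    acc_l <- acc_l + cb$left; acc_r <- acc_r + cb$right
  }
  if (use_asmr) {
    al <- loop_to_length(asmr$left, n); ar <- loop_to_length(asmr$right, n)
    ca <- calibrate_rms_level(stereo_audio(al, ar, asmr$sample_rate),
                              spec$asmr_level_db, reference_rms)
    acc_l <- acc_l + ca$left; acc_r <- acc_r + ca$right
  }
  g <- 1
  peak <- max(abs(c(acc_l, acc_r)))
  if (peak > headroom) {
    g <- headroom / peak
    acc_l <- acc_l * g; acc_r <- acc_r * g
  }
  out <- stereo_audio(acc_l, acc_r, fs)
  attr(out, "headroom_gain") <- g
  out
}

loop_to_length <- function(x, n) {
  if (length(x) == n) return(x)
  if (length(x) > n) return(x[seq_len(n)])
  rep_len(x, n)
}

#' Amplitude envelope via the analytic signal
#'
#' Computes `|x + i*H(x)|` where `H` is the Hilbert transform, obtained by
#' zeroing the negative-frequency half of the spectrum.
#'
#' @param x Numeric signal.
#' @return Envelope vector of the same length.
#' @export
hilbert_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

#' Dominant modulation frequency of a stimulus envelope
#'
#' Sums the two channels to mono, extracts the amplitude envelope via the
#' analytic signal, and returns the frequency of the periodogram maximum above
#' `f_min`. For a dichotic tone pair this recovers the beat frequency.
#'
#' @param audio A [stereo_audio()] object.
#' @param f_min Lowest frequency considered (Hz); excludes the DC pedestal of
#'   the envelope. Default 0.5.
#' @return List with `frequency` (Hz at the peak bin), `resolution`
#'   (bin width, Hz).
#' @export
envelope_peak_frequency <- function(audio, f_min = 0.5) {
  stopifnot(inherits(audio, "stereo_audio"))
  mono <- audio$left + audio$right
  env <- hilbert_envelope(mono)
  env <- env - mean(env)
  n <- length(env)
  spec <- Mod(stats::fft(env))^2
  freq <- (seq_len(n) - 1) * audio$sample_rate / n
  keep <- freq >= f_min & freq <= audio$sample_rate / 2
  list(frequency = freq[keep][which.max(spec[keep])],
       resolution = audio$sample_rate / n)
}
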
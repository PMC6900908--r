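#' Epoch layout of one recording session
#'
#' Consecutive disjoint intervals, in seconds from record start:
#' baseline rest, stimulation, and (optionally) post-stimulus rest.
#'
#' @param baseline,stimulation,post Durations in seconds; `post = 0` omits the
#'   post epoch. The study layout is 120 s baseline, 180 s (screening session)
#'   or 600 s (comparison session) stimulation, and 120 s post rest.
#' @return Named list of `c(start, end)` intervals, class `epoch_spec`.
#' @export
epoch_spec <- function(baseline = 120, stimulation = 180, post = 0) {
  stopifnot(baseline > 0, stimulation > 0, post >= 0)
  ep <- list(baseline = c(0, baseline),
             stimulation = c(baseline, baseline + stimulation))
  if (post > 0) ep$post <- c(baseline + stimulation, baseline + stimulation + post)
  structure(ep, class = "epoch_spec")
}

epoch_total <- function(epochs) max(vapply(epochs, `[`, numeric(1), 2))

#' A stimulus-locked entrainment effect for the EEG simulator
#'
#' Describes the oscillatory response injected during stimulation: a sinusoid
#' at `target_frequency` added to every channel of the `regions` set, with a
#' per-subject amplitude drawn once per subject from a log-normal with the
#' given mean and between-subject SD (both in microvolts). `post_carryover`
#' scales the amplitude persisting into the post-stimulus rest epoch;
#' `alpha_suppression` fractionally reduces the background alpha oscillation
#' while the stimulus plays.
#'
#' @param target_frequency Hz; default 6 (theta-band beat frequency).
#' @param regions Character vector of montage regions receiving the effect.
#' @param amplitude_mean Mean injected amplitude, microvolts (>= 0).
#' @param amplitude_sd Between-subject SD of the amplitude, microvolts.
#' @param alpha_suppression Fractional alpha reduction during stimulation,
#'   in `[0, 1]`.
#' @param post_carryover Fraction of the amplitude persisting in the post
#'   epoch, in `[0, 1]`. Default 1 (entrainment outlasts the brief post rest).
#' @return An `entrainment_effect` object.
#' @export
entrainment_effect <- function(target_frequency = 6, regions = "midline",
                               amplitude_mean = 2, amplitude_sd = 0.5,
                               alpha_suppression = 0, post_carryover = 1) {
  stopifnot(amplitude_mean >= 0, amplitude_sd >= 0,
            alpha_suppression >= 0, alpha_suppression <= 1,
            post_carryover >= 0, post_carryover <= 1)
  structure(list(target_frequency = target_frequency, regions = regions,
                 amplitude_mean = amplitude_mean, amplitude_sd = amplitude_sd,
                 alpha_suppression = alpha_suppression,
                 post_carryover = post_carryover),
            class = "entrainment_effect")
}

#' Null (no-stimulation) effect
#' @return An [entrainment_effect()] with zero amplitude.
#' @export
null_effect <- function() entrainment_effect(amplitude_mean = 0, amplitude_sd = 0)

#' Calibrate an effect to a target standardized paired effect size
#'
#' The theta-power change a subject shows is proportional to the square of the
#' injected amplitude, so with a log-normal amplitude of log-scale SD
#' \eqn{\sigma} the noise-free standardized effect of the change is
#' \eqn{d = 1/\sqrt{e^{4\sigma^2} - 1}}. Inverting gives
#' \eqn{\sigma = \sqrt{\log(1 + 1/d^2)}/2}; the returned effect carries the
#' matching microvolt-scale `amplitude_sd`. Spectral-estimation noise
#' attenuates the measured effect slightly below `d_target`, so choose
#' `amplitude_mean` large enough that estimation noise is subdominant.
#'
#' @param d_target Desired standardized paired effect (> 0) of the
#'   regional theta-power change.
#' @param amplitude_mean Mean injected amplitude, microvolts.
#' @param ... Further arguments passed to [entrainment_effect()].
#' @return An [entrainment_effect()].
#' @export
calibrate_effect <- function(d_target, amplitude_mean = 7, ...) {
  stopifnot(d_target > 0)
  sigma <- sqrt(log(1 + 1 / d_target^2)) / 2
  sd_uv <- amplitude_mean * sqrt(exp(sigma^2) - 1)
  entrainment_effect(amplitude_mean = amplitude_mean, amplitude_sd = sd_uv, ...)
}

# log-normal parameterized by arithmetic mean m and SD s
rlnorm_ms <- function(n, m, s) {
  if (m == 0) return(numeric(n))
  if (s == 0) return(rep(m, n))
  sigma2 <- log(1 + (s / m)^2)
  stats::rlnorm(n, meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
}

#' Multi-channel EEG recording container
#'
#' @param data Channels-by-samples numeric matrix, microvolts, with rownames
#'   equal to the montage channel labels.
#' @param fs Sampling rate, Hz.
#' @param epochs An [epoch_spec()] (intervals must lie within the record).
#' @param montage A `montage` object.
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(data, fs, epochs, montage = default_montage()) {
  stopifnot(is.matrix(data), fs > 0)
  validate_montage(montage)
  if (nrow(data) != length(montage$channels) ||
      !identical(rownames(data), montage$channels))
    stop("data rows must match the montage channels")
  if (epoch_total(epochs) * fs > ncol(data) + 1e-6)
    stop("epoch spec exceeds the record duration")
  structure(list(data = data, fs = fs, epochs = epochs, montage = montage),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples @ %g Hz; epochs: %s\n",
              nrow(x$data), ncol(x$data), x$fs,
              paste(names(x$epochs), collapse = ", ")))
  invisible(x)
}

epoch_samples <- function(rec, epoch) {
  iv <- rec$epochs[[epoch]]
  if (is.null(iv)) stop("no epoch named '", epoch, "' in recording")
  idx <- seq.int(floor(iv[1] * rec$fs) + 1L, floor(iv[2] * rec$fs))
  idx[idx >= 1 & idx <= ncol(rec$data)]
}

#' Simulate one subject's EEG recording
#'
#' Background activity is 1/f^`chi` noise plus an alpha-band oscillation with
#' subject-specific frequency (uniform on `alpha_freq`) and random per-channel
#' phase. During the stimulation epoch a sinusoid at the effect's target
#' frequency, with an amplitude drawn once for the subject, is added to every
#' channel of the affected regions; `post_carryover` of it persists in the
#' post epoch. Everything is reproducible from `seed`.
#'
#' @param effect An [entrainment_effect()].
#' @param timing An [epoch_spec()].
#' @param seed Integer seed.
#' @param fs Sampling rate, Hz (default 500, the acquisition rate).
#' @param montage A `montage`.
#' @param noise_sd Broadband background SD per channel, microvolts (default 10).
#' @param chi Spectral exponent of the background (default 1; PSD slope
#'   -10*chi dB/decade).
#' @param alpha_amp Alpha oscillation amplitude, microvolts (default 6).
#' @param alpha_freq Range of the subject alpha frequency, Hz.
#' @return An [eeg_recording()].
#' @export
simulate_subject <- function(effect = null_effect(), timing = epoch_spec(),
                             seed = 1L, fs = 500,
                             montage = default_montage(),
                             noise_sd = 10, chi = 1, alpha_amp = 6,
                             alpha_freq = c(9, 11)) {
  stopifnot(inherits(effect, "entrainment_effect"))
  validate_montage(montage)
  bad <- setdiff(effect$regions, names(montage$regions))
  if (length(bad)) stop("effect regions not in montage: ", paste(bad, collapse = ", "))
  set.seed(as.integer(seed))
  n <- round(epoch_total(timing) * fs)
  t <- (seq_len(n) - 1) / fs
  nch <- length(montage$channels)
  # subject-level draws
  amp <- rlnorm_ms(1, effect$amplitude_mean, effect$amplitude_sd)
  f_alpha <- stats::runif(1, alpha_freq[1], alpha_freq[2])
  stim_idx <- t >= timing$stimulation[1] & t < timing$stimulation[2]
  post_idx <- if (!is.null(timing$post)) t >= timing$post[1] & t < timing$post[2] else rep(FALSE, n)
  alpha_gain <- rep(1, n)
  alpha_gain[stim_idx] <- 1 - effect$alpha_suppression
  affected <- unique(unlist(montage$regions[effect$regions], use.names = FALSE))
  data <- matrix(0, nrow = nch, ncol = n,
                 dimnames = list(montage$channels, NULL))
  for (i in seq_len(nch)) {
    ch_gain <- stats::runif(1, 0.8, 1.2)
    ph <- stats::runif(1, 0, 2 * pi)
    x <- noise_sd * colored_noise(n, fs, chi = chi, f_floor = 0.5) +
      alpha_amp * ch_gain * alpha_gain * sin(2 * pi * f_alpha * t + ph)
    if (amp > 0 && montage$channels[i] %in% affected) {
      ph_e <- stats::runif(1, 0, 2 * pi)
      drive <- numeric(n)
      drive[stim_idx] <- amp
      drive[post_idx] <- amp * effect$post_carryover
      x <- x + drive * sin(2 * pi * effect$target_frequency * t + ph_e)
    }
    data[i, ] <- x
  }
  eeg_recording(data, fs, timing, montage)
}

#' Simulate a cohort of subjects under one or more conditions
#'
#' Per-subject, per-condition seeds are derived deterministically from the
#' master seed; condition presentation order is randomized per subject to
#' mirror counterbalancing (recorded, not used by the generator itself since
#' conditions are simulated independently).
#'
#' @param n Number of subjects (>= 2; the study cohort size is 15).
#' @param conditions Named list of [entrainment_effect()] objects, one per
#'   condition label.
#' @param timing An [epoch_spec()] shared by all conditions.
#' @param seed Master integer seed.
#' @param ... Passed on to [simulate_subject()] (fs, montage, noise model).
#' @return A `cohort` object: list with `subjects` (list of per-condition
#'   [eeg_recording()] lists), `n`, `conditions`, `order`, `seed`.
#' @export
simulate_cohort <- function(n = 15, conditions, timing = epoch_spec(),
                            seed = 1L, ...) {
  stopifnot(n >= 2, length(conditions) >= 1, !is.null(names(conditions)))
  set.seed(as.integer(seed))
  labs <- names(conditions)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L, n * length(labs)),
                  nrow = n, dimnames = list(NULL, labs))
  order <- replicate(n, sample(labs), simplify = FALSE)
  subjects <- lapply(seq_len(n), function(i) {
    recs <- lapply(labs, function(lab)
      simulate_subject(conditions[[lab]], timing = timing,
                       seed = seeds[i, lab], ...))
    names(recs) <- labs
    recs
  })
  structure(list(subjects = subjects, n = n, conditions = labs,
                 order = order, seed = seed),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects x %d conditions (%s)\n",
              x$n, length(x$conditions), paste(x$conditions, collapse = ", ")))
  invisible(x)
}

#' Write / read a recording as a delimited matrix with a sidecar header
#'
#' Plain-text exchange format: a tab-separated channels-by-samples matrix with
#' channel labels as row names, plus a YAML sidecar (`<path>.yaml`) holding
#' the sampling rate, epoch bounds and region map.
#'
#' @param rec An [eeg_recording()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  utils::write.table(rec$data, path, sep = "\t", col.names = FALSE,
                     row.names = TRUE, quote = FALSE)
  meta <- list(sample_rate = rec$fs,
               epochs = lapply(rec$epochs, as.numeric),
               regions = rec$montage$regions)
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  raw <- utils::read.table(path, sep = "\t", row.names = 1)
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  montage <- structure(list(channels = rownames(raw),
                            regions = lapply(meta$regions, as.character)),
                       class = "montage")
  epochs <- structure(lapply(meta$epochs, as.numeric), class = "epoch_spec")
  data <- as.matrix(raw)
  dimnames(data) <- list(rownames(raw), NULL)
  eeg_recording(data, meta$sample_rate, epochs, montage)
}
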
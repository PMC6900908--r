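# shared fixtures: everything is generated in code at test time

# a recording whose channels all carry the same given signal
flat_recording <- function(x, fs, epochs = NULL,
                           montage = default_montage()) {
  n <- length(x)
  if (is.null(epochs)) {
    third <- n / fs / 3
    epochs <- epoch_spec(third, third, third)
  }
  data <- matrix(rep(x, length(montage$channels)),
                 nrow = length(montage$channels), byrow = TRUE,
                 dimnames = list(montage$channels, NULL))
  eeg_recording(data, fs, epochs, montage)
}

# a band_power_table built directly from a named channel -> power map,
# single band, bypassing any spectral estimation
manual_power_table <- function(powers, band = "theta", epoch = "baseline",
                               montage = default_montage()) {
  out <- tibble::tibble(epoch = epoch, channel = names(powers),
                        band = band, power = unname(powers))
  attr(out, "montage") <- montage
  class(out) <- c("band_power_table", class(out))
  out
}

midline_only <- montage_subset(default_montage(), "midline")

# mean midline theta-power change (stimulation - baseline) of one recording
midline_theta_change <- function(rec) {
  chans <- rec$montage$regions$midline
  idx_b <- seq.int(floor(rec$epochs$baseline[1] * rec$fs) + 1,
                   floor(rec$epochs$baseline[2] * rec$fs))
  idx_s <- seq.int(floor(rec$epochs$stimulation[1] * rec$fs) + 1,
                   floor(rec$epochs$stimulation[2] * rec$fs))
  mean(vapply(chans, function(ch)
    band_power(rec$data[ch, idx_s], rec$fs, "theta") -
      band_power(rec$data[ch, idx_b], rec$fs, "theta"), numeric(1)))
}
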
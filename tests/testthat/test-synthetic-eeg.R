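timing_short <- epoch_spec(12, 12)

test_that("simulation is deterministic given the seed", {
  e <- entrainment_effect(amplitude_mean = 2, amplitude_sd = 0.5)
  a <- simulate_subject(e, timing_short, seed = 10, fs = 250)
  b <- simulate_subject(e, timing_short, seed = 10, fs = 250)
  expect_identical(a$data, b$data)
  c <- simulate_subject(e, timing_short, seed = 11, fs = 250)
  expect_false(identical(a$data, c$data))
})

test_that("recordings carry the montage and reject bad epoch specs", {
  rec <- simulate_subject(null_effect(), timing_short, seed = 1, fs = 250)
  expect_equal(nrow(rec$data), 19)
  expect_identical(rownames(rec$data), default_montage()$channels)
  expect_error(
    eeg_recording(rec$data, 250, epoch_spec(12, 30), rec$montage),
    "exceeds")
  expect_error(
    simulate_subject(entrainment_effect(regions = "thalamus"), timing_short,
                     seed = 1),
    "regions not in montage")
})

test_that("background spectrum has the configured 1/f slope", {
  for (chi in c(0.5, 1, 1.5)) {
    rec <- simulate_subject(null_effect(), epoch_spec(20, 20), seed = 60,
                            fs = 250, montage = midline_only, chi = chi,
                            alpha_amp = 0)
    slope <- psd_slope_db_per_decade(rec$data[1, ], 250, c(1, 40),
                                     window_sec = 4)
    expect_lt(abs(slope / (-10) - chi), 0.3)
  }
})

test_that("injected theta amplitude maps monotonically to recovered power", {
  # same seed across amplitudes: identical noise, monotone amplitude draws
  grid <- c(0.5, 1, 2, 4)
  changes <- vapply(grid, function(a) {
    mean(vapply(1:30, function(s) {
      rec <- simulate_subject(
        entrainment_effect(amplitude_mean = a, amplitude_sd = 0.3 * a),
        timing_short, seed = 7000 + s, fs = 250, montage = midline_only)
      midline_theta_change(rec)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(changes) > 0))
})

test_that("a zero-amplitude effect leaves theta power unchanged on average", {
  ch <- vapply(1:100, function(s) {
    rec <- simulate_subject(null_effect(), timing_short, seed = 5000 + s,
                            fs = 250, montage = midline_only)
    midline_theta_change(rec)
  }, numeric(1))
  expect_gt(paired_t(ch)$p, 0.01)
})

test_that("the effect is region specific", {
  occ <- montage_subset(default_montage(), c("midline", "occipital"))
  deltas <- vapply(1:40, function(s) {
    rec <- simulate_subject(
      entrainment_effect(amplitude_mean = 6, amplitude_sd = 1,
                         regions = "midline"),
      timing_short, seed = 8000 + s, fs = 250, montage = occ)
    idx_b <- seq.int(1, 12 * 250)
    idx_s <- seq.int(12 * 250 + 1, 24 * 250)
    o <- mean(vapply(occ$regions$occipital, function(chn)
      band_power(rec$data[chn, idx_s], 250, "theta") -
        band_power(rec$data[chn, idx_b], 250, "theta"), numeric(1)))
    m <- midline_theta_change(rec)
    c(m, o)
  }, numeric(2))
  expect_gt(mean(deltas[1, ]), 10)              # injected region responds
  expect_gt(paired_t(deltas[2, ])$p, 0.01)      # unaffected region is null
})

test_that("alpha suppression reduces stimulation-epoch alpha power", {
  rec <- simulate_subject(
    entrainment_effect(amplitude_mean = 0, amplitude_sd = 0,
                       alpha_suppression = 0.6),
    epoch_spec(16, 16), seed = 42, fs = 250, montage = midline_only,
    alpha_amp = 8)
  idx_b <- seq.int(1, 16 * 250); idx_s <- seq.int(16 * 250 + 1, 32 * 250)
  ab <- band_power(rec$data[1, idx_b], 250, "alpha")
  as_ <- band_power(rec$data[1, idx_s], 250, "alpha")
  expect_lt(as_ / ab, 0.7)
})

test_that("cohorts derive per-subject seeds and hold every condition", {
  conds <- list(SHAM = null_effect(), CS = entrainment_effect())
  co <- simulate_cohort(n = 3, conds, timing_short, seed = 5, fs = 250,
                        montage = midline_only)
  expect_equal(co$n, 3)
  expect_length(co$subjects, 3)
  expect_true(all(vapply(co$subjects, function(s)
    identical(names(s), c("SHAM", "CS")), logical(1))))
  co2 <- simulate_cohort(n = 3, conds, timing_short, seed = 5, fs = 250,
                         montage = midline_only)
  expect_identical(co$subjects[[2]]$CS$data, co2$subjects[[2]]$CS$data)
  expect_false(identical(co$subjects[[1]]$CS$data, co$subjects[[2]]$CS$data))
  expect_true(all(vapply(co$order, setequal, logical(1), y = c("SHAM", "CS"))))
  expect_error(simulate_cohort(1, conds, timing_short), "n >= 2")
})

test_that("recordings round-trip through the delimited format", {
  rec <- simulate_subject(null_effect(), epoch_spec(2, 2), seed = 3, fs = 100,
                          montage = midline_only)
  f <- tempfile(fileext = ".tsv")
  write_recording(rec, f)
  back <- read_recording(f)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$data, rec$data, tolerance = 1e-6)
  expect_equal(back$epochs$stimulation, rec$epochs$stimulation)
  expect_equal(back$montage$regions$midline, rec$montage$regions$midline)
  unlink(c(f, paste0(f, ".yaml")))
})

test_that("effect calibration hits the requested noise-free effect size", {
  e <- calibrate_effect(0.9, amplitude_mean = 7)
  # draw many subject amplitudes; the standardized effect of a^2/2
  set.seed(1)
  a <- thetabeat:::rlnorm_ms(2e5, e$amplitude_mean, e$amplitude_sd)
  x <- a^2 / 2
  expect_equal(mean(x) / sd(x), 0.9, tolerance = 0.02)
})
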
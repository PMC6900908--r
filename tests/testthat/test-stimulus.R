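test_that("dB-to-amplitude conversion matches the closed form", {
  expect_equal(db_to_amplitude(0), 1)
  expect_equal(db_to_amplitude(-30), 0.031623, tolerance = 1e-4)
  expect_equal(db_to_amplitude(-6.0206), 0.5, tolerance = 1e-4)
  expect_equal(db_to_amplitude(20), 10)
  expect_error(db_to_amplitude(NA), "finite")
})

test_that("tone specifications reject unphysical parameters", {
  expect_error(tone_spec(0, 1), "positive")
  expect_error(tone_spec(30000, 1, sample_rate = 44100), "Nyquist")
  expect_error(tone_spec(250, 0), "duration")
})

test_that("dichotic tone pairs produce the expected beat frequency", {
  fs <- 8000
  # beat = |offset - carrier| for a spread of offsets
  for (delta in c(2, 3, 6, 11, 19)) {
    bb <- synthesize_binaural(tone_spec(250, 10, fs),
                              tone_spec(250 + delta, 10, fs))
    pk <- envelope_peak_frequency(bb)
    expect_lt(abs(pk$frequency - delta), pk$resolution + 1e-9)
  }
  # identical tones: constant envelope (no modulation)
  same <- synthesize_binaural(tone_spec(250, 5, fs), tone_spec(250, 5, fs))
  env <- hilbert_envelope(same$left + same$right)
  core <- env[1000:(length(env) - 1000)]
  expect_lt(stats::sd(core) / mean(core), 1e-3)
})

test_that("binaural synthesis rejects mismatched tone pairs", {
  expect_error(synthesize_binaural(tone_spec(250, 1, 44100),
                                   tone_spec(256, 1, 22050)),
               "sample rate")
  expect_error(synthesize_binaural(tone_spec(250, 1), tone_spec(256, 2)),
               "duration")
})

test_that("RMS calibration reaches its target and is idempotent", {
  fs <- 8000
  t <- (0:(fs - 1)) / fs
  x <- stereo_audio(0.1 * sqrt(2) * sin(2 * pi * 100 * t),
                    0.1 * sqrt(2) * sin(2 * pi * 100 * t), fs)
  out <- calibrate_rms_level(x, 0, reference_rms = 0.05)
  expect_equal(audio_rms(out), 0.05, tolerance = 1e-6)
  out2 <- calibrate_rms_level(out, 0, reference_rms = 0.05)
  expect_equal(out2$left, out$left, tolerance = 1e-12)
  # 30 vs 60 dB on the same anchor differ by 10^(30/20)
  lo <- calibrate_rms_level(x, 30)
  hi <- calibrate_rms_level(x, 60)
  expect_equal(audio_rms(hi) / audio_rms(lo), 10^(30 / 20), tolerance = 1e-9)
  silent <- stereo_audio(numeric(100), numeric(100), fs)
  expect_error(calibrate_rms_level(silent, 0), "silent")
})

test_that("surrogate natural sound is reproducible and correctly shaped", {
  a <- generate_surrogate_asmr("rain", 2, sample_rate = 8000, seed = 7)
  b <- generate_surrogate_asmr("rain", 2, sample_rate = 8000, seed = 7)
  expect_identical(a$left, b$left)
  expect_identical(a$right, b$right)
  c <- generate_surrogate_asmr("rain", 2, sample_rate = 8000, seed = 8)
  expect_false(identical(a$left, c$left))
  expect_error(generate_surrogate_asmr("thunder", 1), "unknown")
  expect_length(generate_surrogate_asmr("river", 10, 44100, 1)$left, 441000)
})

test_that("rain surrogate has a pink (about -10 dB/decade) spectrum", {
  a <- generate_surrogate_asmr("rain", 5, sample_rate = 44100, seed = 11)
  slope <- psd_slope_db_per_decade(a$left, 44100, c(50, 2000),
                                   window_sec = 0.5)
  expect_lt(abs(slope - (-10)), 2)
})

test_that("combined mixes realize the printed dB ratios", {
  fs <- 44100
  bb <- synthesize_binaural(tone_spec(250, 3, fs), tone_spec(256, 3, fs))
  asmr <- generate_surrogate_asmr("waves", 3, fs, seed = 2)
  ratios <- c(CS1 = 10^(15 / 20), CS2 = 10^(30 / 20), CS3 = 10^(40 / 20))
  for (cond in names(ratios)) {
    spec <- mix_spec(cond)
    cb <- calibrate_rms_level(bb, spec$bb_level_db)
    ca <- calibrate_rms_level(asmr, spec$asmr_level_db)
    expect_equal(audio_rms(ca) / audio_rms(cb), unname(ratios[cond]),
                 tolerance = 0.01)
    mx <- mix_combined(bb, asmr, spec)
    # uncorrelated components: mix power is close to the component sum
    expect_equal(audio_rms(mx)^2,
                 (audio_rms(cb)^2 + audio_rms(ca)^2) *
                   attr(mx, "headroom_gain")^2,
                 tolerance = 0.05)
    expect_lte(max(abs(c(mx$left, mx$right))), 0.99 + 1e-9)
  }
})

test_that("mix handles equal levels, headroom and degenerate conditions", {
  fs <- 8000
  bb <- synthesize_binaural(tone_spec(250, 2, fs), tone_spec(256, 2, fs))
  asmr <- generate_surrogate_asmr("river", 2, fs, seed = 5)
  spec <- mix_spec("CS2")
  spec$bb_level_db <- 60  # equal 60:60 levels
  cb <- calibrate_rms_level(bb, 60)
  ca <- calibrate_rms_level(asmr, 60)
  expect_equal(audio_rms(ca) / audio_rms(cb), 1, tolerance = 1e-9)
  # force clipping: huge anchor -> joint rescale recorded, ratio preserved
  loud <- mix_combined(bb, asmr, mix_spec("CS2"), reference_rms = 0.05)
  expect_lt(attr(loud, "headroom_gain"), 1)
  expect_lte(max(abs(c(loud$left, loud$right))), 0.99 + 1e-9)
  sham <- mix_combined(bb, asmr, mix_spec("SHAM"))
  expect_true(all(sham$left == 0))
  wrong <- generate_surrogate_asmr("river", 2, 4000, seed = 5)
  expect_error(mix_combined(bb, wrong, mix_spec("CS1")), "mismatch")
})

test_that("WAV files round-trip through write and read", {
  fs <- 8000
  bb <- synthesize_binaural(tone_spec(250, 0.5, fs), tone_spec(256, 0.5, fs),
                            amplitude = 0.5)
  f <- tempfile(fileext = ".wav")
  write_wav(bb, f)
  back <- read_wav(f)
  expect_equal(back$sample_rate, fs)
  expect_equal(back$left, bb$left, tolerance = 1e-7)   # float32 quantization
  expect_equal(back$right, bb$right, tolerance = 1e-7)
  write_wav(bb, f, bit_depth = "pcm16")
  back16 <- read_wav(f)
  expect_equal(back16$left, bb$left, tolerance = 1e-4)
  unlink(f)
})
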
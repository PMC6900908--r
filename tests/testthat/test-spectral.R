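test_that("band power integrates a pure tone to its total power", {
  fs <- 250
  t <- (0:(60 * fs - 1)) / fs
  x <- sin(2 * pi * 6 * t)
  expect_equal(band_power(x, fs, "theta"), 0.5, tolerance = 0.01)
  for (b in c("delta", "alpha", "beta", "gamma"))
    expect_lt(band_power(x, fs, b), 0.005)
  expect_true(all(vapply(names(band_defs()), function(b)
    band_power(numeric(4000), fs, b), numeric(1)) == 0))
  expect_error(band_power(numeric(100), fs, "theta"), "too short")
})

test_that("white-noise band power is proportional to bandwidth", {
  set.seed(21)
  fs <- 250
  x <- rnorm(120 * fs)
  g <- band_power(x, fs, "gamma")
  th <- band_power(x, fs, "theta")
  expect_equal(g / th, 20 / 4, tolerance = 0.10)
  # half-open bands partition 0.5-50 Hz: band powers sum to the total
  total <- band_power(x, fs, c(0.5, 50))
  parts <- sum(vapply(band_defs(), function(b) band_power(x, fs, b),
                      numeric(1)))
  expect_equal(parts, total, tolerance = 0.01)
})

test_that("Welch PSD agrees with the raw periodogram on average", {
  set.seed(4)
  fs <- 200
  x <- rnorm(60 * fs)
  p <- welch_psd(x, fs)
  # independent oracle: variance recovery (Parseval) and spec.pgram level
  expect_equal(sum(p$psd) * (p$freq[2] - p$freq[1]), stats::var(x),
               tolerance = 0.05)
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0,
                          plot = FALSE)
  # spec.pgram reports two-sided density; ours is one-sided
  expect_equal(mean(p$psd[p$freq > 5 & p$freq < 95]),
               2 * mean(sp$spec[sp$freq > 5 & sp$freq < 95]),
               tolerance = 0.05)
})

test_that("regional aggregation is the member-channel mean", {
  m <- default_montage()
  powers <- stats::setNames(seq_along(m$channels), m$channels)
  tab <- manual_power_table(powers)
  expect_equal(region_power(tab, "midline")$power,
               mean(powers[c("Fz", "Cz", "Pz")]))
  expect_equal(region_power(tab, "prefrontal")$power,
               mean(powers[c("Fp1", "Fp2", "F7", "F8")]))
  expect_length(m$regions$prefrontal, 4)
  # permutation invariance over member channels
  shuf <- manual_power_table(powers[sample(names(powers))])
  for (r in names(m$regions))
    expect_equal(region_power(shuf, r)$power, region_power(tab, r)$power)
  # equal channel powers collapse to that power
  eq <- manual_power_table(stats::setNames(rep(3.5, 19), m$channels))
  expect_true(all(region_power_table(eq)$power == 3.5))
  expect_error(region_power(tab, "cerebellar"), "unknown region")
})

test_that("power change is an elementwise antisymmetric difference", {
  m <- default_montage()
  a <- manual_power_table(stats::setNames(runif(19), m$channels))
  b <- manual_power_table(stats::setNames(runif(19), m$channels))
  expect_true(all(power_change(a, a)$power == 0))
  expect_equal(power_change(a, b)$power, -power_change(b, a)$power)
  bad <- b[-1, ]
  attr(bad, "montage") <- m
  expect_error(power_change(a, bad), "layout")
})

test_that("the midline target-frequency peak tracks an injected 6 Hz tone", {
  fs <- 250
  timing <- epoch_spec(16, 16)
  peaks <- vapply(c(0, 1, 2, 4), function(a) {
    rec <- simulate_subject(
      entrainment_effect(amplitude_mean = a, amplitude_sd = 0),
      timing, seed = 400, fs = fs, montage = midline_only)
    peak_at_target(rec)
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))          # monotone in amplitude
  expect_lt(abs(peaks[1] - 1), 0.75)         # no injection: ratio near 1
  # off-target control: a 3 Hz injection leaves the 6 Hz peak alone
  rec3 <- simulate_subject(
    entrainment_effect(target_frequency = 3, amplitude_mean = 4,
                       amplitude_sd = 0),
    timing, seed = 401, fs = fs, montage = midline_only)
  expect_lt(abs(peak_at_target(rec3, target = 6) - 1), 0.75)
  expect_gt(peak_at_target(rec3, target = 3), 2)
})

test_that("laterality index follows its closed form and bounds", {
  expect_equal(laterality_index(2, 2), 0)
  expect_equal(laterality_index(1, 3), -0.5)
  expect_equal(laterality_index(5, 0), 1)   # pure left dominance
  expect_error(laterality_index(0, 0), "undefined")
  set.seed(31)
  for (i in 1:50) {
    L <- runif(1, 0, 10); R <- runif(1, 0, 10)
    li <- laterality_index(L, R)
    expect_true(li >= -1 && li <= 1)
    expect_equal(li, -laterality_index(R, L))
  }
})

test_that("alpha laterality is near zero for hemispherically symmetric data", {
  rec <- simulate_subject(null_effect(), epoch_spec(20, 20), seed = 77,
                          fs = 250)
  li <- alpha_laterality(rec, "baseline")
  expect_lt(abs(li$LI), 0.3)
  expect_gt(li$L, 0)
  expect_gt(li$R, 0)
})
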
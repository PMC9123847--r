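# scipy.signal.windows.dpss(64, 3, 5, norm=2) and dpss(1000, 3, 5, norm=2),
# computed once and frozen (reference values for both the dense and the
# bisection/inverse-iteration code paths)
scipy_dpss64_t1 <- c(0.0003564442, 0.0007911888, 0.0014682758,
                     0.0024592785, 0.0038434459, 0.0057058625)
scipy_dpss64_t2 <- c(0.0025072425, 0.0048624186, 0.0081702152,
                     0.0125845927, 0.0182408214, 0.0252450215)
scipy_dpss64_t5 <- c(0.1160563702, 0.1425246746, 0.1663497402,
                     0.1860036502, 0.2001113280, 0.2075484681)
scipy_dpss1000_t1 <- c(5.1686909395e-05, 5.5825737538e-05,
                       6.0124669822e-05, 6.4587304437e-05)
scipy_dpss1000_t3 <- c(-0.0389739769, -0.0389806749, -0.0389806749,
                       -0.0389739769)

test_that("DPSS tapers match the reference implementation on both paths", {
  H <- dpss_tapers(64, 3, 5)
  expect_equal(H[1:6, 1], scipy_dpss64_t1, tolerance = 1e-7)
  expect_equal(H[1:6, 2], scipy_dpss64_t2, tolerance = 1e-7)
  expect_equal(H[1:6, 5], scipy_dpss64_t5, tolerance = 1e-7)
  expect_lt(max(abs(crossprod(H) - diag(5))), 1e-10)
  H2 <- dpss_tapers(1000, 3, 5)  # long-window bisection path
  expect_equal(H2[1:4, 1], scipy_dpss1000_t1, tolerance = 1e-7)
  expect_equal(H2[499:502, 3], scipy_dpss1000_t3, tolerance = 1e-7)
  expect_lt(max(abs(crossprod(H2) - diag(5))), 1e-8)
})

test_that("DPSS tapers concentrate their energy in the design band", {
  n <- 128; nw <- 3
  H <- dpss_tapers(n, nw, 5)
  # in-band energy via the sinc kernel of the band [-W, W]
  W <- nw / n
  i <- seq_len(n)
  K <- outer(i, i, function(a, b) {
    d <- a - b
    ifelse(d == 0, 2 * W, sin(2 * pi * W * d) / (pi * d))
  })
  conc <- diag(crossprod(H, K %*% H))
  expect_true(all(diff(conc) < 1e-6))    # ordered by concentration
  expect_gt(conc[1], 0.9999)
  expect_gt(conc[5], 0.9)
})

test_that("windowed spectra behave like periodograms should", {
  # pure tone on a bin center concentrates in that bin, in every window
  rec <- tone_recording(3, fs = 128, duration_s = 20)
  sp <- windowed_power_spectrum(rec, spectral_config())
  expect_equal(dim(sp$power)[2], 20)
  expect_equal(diff(sp$freq[1:2]), 1)
  frac3 <- apply(sp$power[, , 1], 2, function(p) sum(p[3:5]) / sum(p))
  expect_true(all(frac3 > 0.999))

  # partial trailing window is discarded
  rec2 <- time_series_recording(rnorm(round(10.7 * 128)), 128)
  expect_equal(dim(windowed_power_spectrum(rec2)$power)[2], 10)
  expect_error(windowed_power_spectrum(
    time_series_recording(rnorm(64), 128)), "insufficient")

  # Parseval: integrated PSD of a demeaned window ~ its variance
  set.seed(1)
  x <- rnorm(256)
  spp <- windowed_power_spectrum(time_series_recording(x, 256))
  expect_equal(sum(spp$power[, 1, 1]) * 1,
               mean((x - mean(x))^2), tolerance = 0.15)

  # white noise: flat expected spectrum at the analytic level 2*sigma^2/fs
  set.seed(2)
  fs <- 128
  recw <- time_series_recording(rnorm(fs * 1500, sd = 2), fs)
  mp <- rowMeans(windowed_power_spectrum(recw)$power[, , 1])
  level <- 2 * 4 / fs
  interior <- 3:63   # away from the demeaning-depressed DC edge
  expect_lt(max(abs(mp[interior] - level)) / level, 0.05)

  # wake mask restricts analysis to complete wake windows
  recm <- time_series_recording(rnorm(128 * 30), 128,
                                wake_mask = rbind(c(0, 5.5), c(10, 14)))
  expect_equal(dim(windowed_power_spectrum(recm)$power)[2], 9)
})

test_that("relative delta power follows its band conventions", {
  expect_gt(relative_delta_power(tone_recording(3))$value, 0.99)
  est <- relative_delta_power(tone_recording(c(3, 10), c(1, 1)))
  expect_equal(est$value, 0.5, tolerance = 0.01)
  # 7 Hz is outside delta but inside total
  expect_lt(relative_delta_power(tone_recording(7))$value, 0.01)
  # amplitude-scaling invariance of the ratio
  set.seed(3)
  rec <- make_synthetic_eeg(0.4, duration_s = 10, seed = 10)
  r1 <- relative_delta_power(rec)$per_interval
  rec$samples <- rec$samples * 37
  r2 <- relative_delta_power(rec)$per_interval
  expect_equal(r1, r2, tolerance = 1e-12)
  # zero-power intervals are dropped and counted
  x <- sin(2 * pi * 3 * seq_len(5 * 128) / 128)
  x[129:256] <- 0
  est2 <- relative_delta_power(time_series_recording(x, 128))
  expect_equal(est2$n_dropped, 1L)
  expect_equal(est2$n_intervals, 4L)
  expect_error(relative_delta_power(
    time_series_recording(rep(0, 128 * 2), 128)), "zero total power")
  # both channel-combination conventions agree for identical channels
  recc <- tone_recording(c(3, 10), n_channels = 3)
  expect_equal(
    relative_delta_power(recc, channel_combine = "average_of_ratios")$value,
    relative_delta_power(recc)$value, tolerance = 1e-10)
})

test_that("absolute delta peak finds the in-band multitaper maximum", {
  fs <- 500
  rec <- tone_recording(3, fs = fs, duration_s = 60, n_channels = 2,
                        noise_sd = 0.05, units = "mV", seed = 4)
  pk <- absolute_delta_peak(rec)
  expect_equal(pk$peak_freq, 3, tolerance = 0.21)  # 0.2 Hz grid
  expect_equal(pk$units, "mV^2/Hz")

  # a tone outside 1-5 Hz is ignored: the peak drops to the noise floor
  rec8 <- tone_recording(8, fs = fs, duration_s = 60, n_channels = 2,
                         noise_sd = 0.05, units = "mV", seed = 5)
  pk8 <- absolute_delta_peak(rec8)
  expect_lt(pk8$value, pk$value / 100)

  # hemisphere averaging is linear: mean of single-hemisphere spectra
  tt <- seq_len(fs * 60) / fs
  xa <- sqrt(2) * sin(2 * pi * 3 * tt); xb <- sin(2 * pi * 3 * tt)
  both <- absolute_delta_peak(
    time_series_recording(cbind(xa, xb), fs, c("L", "R"), units = "mV"))
  sa <- suppressWarnings(absolute_delta_peak(
    time_series_recording(xa, fs, "L", units = "mV")))
  expect_warning(sb <- absolute_delta_peak(
    time_series_recording(xb, fs, "R", units = "mV")), "single-hemisphere")
  expect_equal(both$value, (sa$value + sb$value) / 2, tolerance = 1e-10)

  # analysis restricted to the last N minutes
  y <- c(10 * sin(2 * pi * 3 * tt[1:(30 * fs)]),
         0.1 * sin(2 * pi * 3 * tt[1:(30 * fs)]))
  full <- absolute_delta_peak(
    time_series_recording(cbind(y, y), fs, c("L", "R"), units = "mV"),
    last_minutes = 1)
  tail_only <- absolute_delta_peak(
    time_series_recording(cbind(y, y), fs, c("L", "R"), units = "mV"),
    last_minutes = 0.5)
  expect_lt(tail_only$value, full$value / 100)
})
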
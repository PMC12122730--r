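test_that("the two Welch parameterizations are element-wise identical", {
  set.seed(11)
  seg <- analog_segment(matrix(rnorm(3 * 2000), nrow = 3), 500)
  a <- welch_psd_by_resolution(seg, qty(2, "Hz"), 0.5, "hann")
  b <- welch_psd_by_samples(seg, 500, 250L, 125L, "hann")
  expect_identical(a$frequencies, b$frequencies)
  expect_identical(a$power, b$power)
})

test_that("white-noise Welch estimates satisfy Parseval within 10%", {
  set.seed(3)
  seg <- analog_segment(rnorm(50000), 500)
  p <- welch_psd_by_resolution(seg, qty(2, "Hz"), 0.5, "hann")
  total <- sum(p$power) * diff(p$frequencies[1:2])
  expect_lt(abs(total - 1), 0.1)
})

test_that("a sinusoid at a bin center peaks at its frequency", {
  tt <- (0:1999) / 500
  seg <- analog_segment(sin(2 * pi * 20 * tt), 500)
  p <- welch_psd_by_resolution(seg, qty(2, "Hz"), 0.5, "hann")
  expect_equal(p$frequencies[which.max(p$power)], 20)
  # total power of a unit sinusoid is 1/2
  expect_lt(abs(sum(p$power) * diff(p$frequencies[1:2]) - 0.5), 0.05)
})

test_that("degenerate Welch cases behave: zero input, single window, errors", {
  seg0 <- analog_segment(rep(0, 1000), 500)
  p0 <- welch_psd_by_samples(seg0, 500, 250L, 125L, "hann")
  expect_true(all(p0$power == 0))
  # full-segment window with no overlap is a plain periodogram
  seg <- analog_segment(rnorm(512), 256)
  p1 <- welch_psd_by_samples(seg, 256, 512L, 0L, "boxcar")
  expect_length(p1$frequencies, 257)
  expect_error(welch_psd_by_samples(seg, 256, 128L, 128L), "overlap")
  short <- analog_segment(rnorm(100), 500)
  expect_error(welch_psd_by_resolution(short, qty(2, "Hz")),
               "insufficient data")
})

test_that("zero-phase Butterworth has unit DC gain and -6 dB at cutoff", {
  x <- analog_segment(rep(1, 1000), 1000)
  y <- butterworth_lowpass(x, 4L, qty(250, "Hz"))
  expect_lt(max(abs(y$samples - 1)), 1e-6)

  tt <- (0:3999) / 1000
  at_cut <- butterworth_lowpass(analog_segment(sin(2 * pi * 250 * tt), 1000),
                                4L, qty(250, "Hz"))
  amp <- max(abs(at_cut$samples[1, 1500:2500]))   # steady-state mid-segment
  expect_lt(abs(amp - 0.5), 0.02)                 # two passes: -3 dB twice

  low <- butterworth_lowpass(analog_segment(sin(2 * pi * 5 * tt), 1000),
                             4L, qty(250, "Hz"))
  expect_lt(abs(max(abs(low$samples[1, 1500:2500])) - 1), 0.01)
})

test_that("cutoffs at or above Nyquist are rejected", {
  x <- analog_segment(rnorm(100), 1000)
  expect_error(butterworth_lowpass(x, 4L, 500), "Nyquist")
})

test_that("downsampling keeps every k-th sample and validates the factor", {
  x <- analog_segment(matrix(seq_len(1000), nrow = 1), 1000)
  y <- downsample(x, 500)
  expect_equal(ncol(y$samples), 500)
  expect_equal(y$samples[1, 1:3], c(1, 3, 5))
  expect_equal(y$sampling_rate, 500)
  expect_identical(downsample(x, 1000)$samples, x$samples)  # factor 1
  expect_error(downsample(x, 300), "integer")
})

test_that("multitaper estimates are a distinct, correctly normalized estimator", {
  set.seed(5)
  seg <- analog_segment(rnorm(2000), 500)
  m <- multitaper_psd(seg, 4L, 4)
  total <- sum(m$power) * diff(m$frequencies[1:2])
  expect_lt(abs(total - 1), 0.1)                            # Parseval
  w <- welch_psd_by_resolution(seg, qty(2, "Hz"), 0.5, "hann")
  expect_false(isTRUE(all.equal(length(m$frequencies), length(w$frequencies))))
  expect_error(multitaper_psd(seg, 10L, 4), "num_tapers")
})

test_that("a single taper reduces to a hand-computed tapered periodogram", {
  set.seed(6)
  x <- rnorm(1024)
  seg <- analog_segment(x, 256)
  m <- multitaper_psd(seg, 1L, 1)
  # independent single-taper periodogram: taper, FFT, one-sided density
  tap <- neaokg:::dpss_tapers(1024, 1, 1)[, 1]
  ft <- stats::fft(x * tap)
  nfreq <- 513
  dbl <- c(1, rep(2, nfreq - 2), 1)
  per <- Mod(ft[seq_len(nfreq)])^2 * dbl / 256
  expect_equal(as.vector(m$power), per, tolerance = 1e-10)
  # and it still tracks the plain periodogram on the same data
  box <- welch_psd_by_samples(seg, 256, 1024L, 0L, "boxcar")
  keep <- 2:512
  expect_gt(stats::cor(log(m$power[keep]), log(box$power[keep])), 0.5)
})

test_that("DPSS tapers are orthonormal and cached", {
  t1 <- neaokg:::dpss_tapers(512, 4, 4)
  expect_equal(crossprod(t1), diag(4), tolerance = 1e-8)
  t2 <- neaokg:::dpss_tapers(512, 4, 4)
  expect_identical(t1, t2)
})
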
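test_that("initial-volume discard keeps the remaining frames intact", {
  b <- random_bold(c(3, 3, 2), 240, seed = 1)
  out <- discard_initial(b, 10)
  expect_equal(out$n_volumes, 230)
  expect_identical(out$data[, , , 1], b$data[, , , 11])
  expect_identical(discard_initial(b, 0), b)
  expect_error(discard_initial(b, 240), "discard")
})

test_that("motion QC applies strict per-axis limits", {
  tr <- matrix(0, 10, 3); ro <- matrix(0, 10, 3)
  expect_true(motion_qc(motion_trace(tr, ro))$pass)
  tr[5, 2] <- 2.5
  expect_false(motion_qc(motion_trace(tr, ro))$pass)
  tr[5, 2] <- 2.0   # exactly at the limit passes (rule is strictly greater)
  expect_true(motion_qc(motion_trace(tr, ro))$pass)
  ro[3, 1] <- -2.4
  expect_false(motion_qc(motion_trace(tr, ro))$pass)
  qc <- motion_qc(motion_trace(tr, ro))
  expect_equal(qc$worst_rotation_deg, 2.4)
})

test_that("motion files round-trip through the 6-column text format", {
  tr <- matrix(rnorm(30), 10, 3); ro <- matrix(rnorm(30), 10, 3)
  f <- withr::local_tempfile(fileext = ".txt")
  write.table(cbind(tr, ro), f, row.names = FALSE, col.names = FALSE)
  mt <- read_motion_trace(f)
  expect_equal(mt$translations, tr, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(mt$rotations, ro, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("linear detrending removes ramps exactly and recovers sinusoids", {
  g <- tiny_grid(c(1, 1, 1))
  n <- 100
  ramp <- bold_series(array(5 + 0.3 * (1:n), dim = c(1, 1, 1, n)), g, 2)
  expect_lt(max(abs(detrend_linear(ramp)$data)), 1e-10)
  const <- bold_series(array(7, dim = c(1, 1, 1, n)), g, 2)
  expect_lt(max(abs(detrend_linear(const)$data)), 1e-10)
  sine <- sin(2 * pi * (1:n) / 10)
  sine <- sine - mean(sine)
  tt <- (1:n) - (n + 1) / 2
  sine <- sine - tt * sum(sine * tt) / sum(tt^2)  # project out line analytically
  mix <- bold_series(array(2 + 0.5 * (1:n) + sine, dim = c(1, 1, 1, n)), g, 2)
  out <- detrend_linear(mix)$data[1, 1, 1, ]
  expect_lt(sqrt(mean((out - sine)^2)), 1e-10)
  expect_lt(abs(mean(out)), 1e-10)
})

test_that("the ideal band-pass keeps passband and kills stopband sinusoids", {
  g <- tiny_grid(c(1, 1, 1))
  tt <- (0:229) * 2
  amp_ratio <- function(f_hz) {
    x <- sin(2 * pi * f_hz * tt)
    b <- bold_series(array(x, dim = c(1, 1, 1, 230)), g, 2)
    out <- bandpass(b, 0.01, 0.08)$data[1, 1, 1, ]
    sqrt(mean(out^2)) / sqrt(mean(x^2))
  }
  expect_gte(amp_ratio(0.05), 0.9)
  expect_lte(amp_ratio(0.20), 0.1)
  expect_lte(amp_ratio(2 / 460), 0.1)   # bin-aligned slow drift below the band
  z <- bold_series(array(0, dim = c(1, 1, 1, 230)), g, 2)
  expect_lt(max(abs(bandpass(z, 0.01, 0.08)$data)), 1e-12)
  expect_error(bandpass(random_bold(c(1, 1, 1), 50, 1), 0.01, 0.4), "band")
})

test_that("detrend + band-pass concentrates white-noise power in the band", {
  b <- random_bold(c(2, 2, 2), 230, seed = 3)
  out <- bandpass(detrend_linear(b), 0.01, 0.08)
  x <- out$data[1, 1, 1, ]
  sp <- Mod(fft(x))^2
  freqs <- (seq_along(x) - 1) / (length(x) * 2)
  freqs <- pmin(freqs, 0.5 - freqs)   # fold to [0, Nyquist] for TR = 2
  inband <- freqs >= 0.01 & freqs <= 0.08
  expect_gte(sum(sp[inband]) / sum(sp), 0.8)
})

test_that("Gaussian smoothing has the requested FWHM and preserves interior intensity", {
  g <- volume_grid(c(21, 21, 21))
  a <- array(0, dim = c(21, 21, 21)); a[11, 11, 11] <- 1
  sm <- smooth_gaussian(scalar_map(a, g, "tstat"), 6)
  prof <- sm$data[, 11, 11]
  xs <- ((1:21) - 11) * 3
  fitted_fwhm <- 2 * sqrt(2 * log(2)) * sqrt(sum(prof * xs^2) / sum(prof))
  expect_lt(abs(fitted_fwhm - 6) / 6, 0.05)
  # identity at fwhm 0
  m <- scalar_map(array(rnorm(27), dim = c(3, 3, 3)), tiny_grid(c(3, 3, 3)), "tstat")
  expect_identical(smooth_gaussian(m, 0), m)
  # constant volume stays constant away from the zero-padded boundary
  const <- scalar_map(array(5, dim = c(21, 21, 21)), g, "tstat")
  out <- smooth_gaussian(const, 6)
  expect_lt(max(abs(out$data[8:14, 8:14, 8:14] - 5)), 1e-6)
  expect_error(smooth_gaussian(const, -1), "non-negative")
})

test_that("gray-matter masking is strictly greater than the threshold", {
  g <- tiny_grid(c(2, 2, 2))
  p <- array(c(0.5, 0.2, 0.19, 0.21, 0.9, 0, 1, 0.200001), dim = c(2, 2, 2))
  m <- gm_mask_from_prob(scalar_map(p, g, "gm_prob"), 0.2)
  expect_equal(m$n_true, 5)  # hand count: 0.5, 0.21, 0.9, 1, 0.200001; 0.2 excluded
  expect_identical(c(m$data), c(p) > 0.2)
  full <- gm_mask_from_prob(scalar_map(array(0.5, dim = c(2, 2, 2)), g, "gm_prob"), 0.2)
  expect_equal(full$n_true, 8)
  bad <- scalar_map(array(seq(0, 1.4, length.out = 8), dim = c(2, 2, 2)), g, "gm_prob")
  expect_error(gm_mask_from_prob(bad, 0.2), "outside")
})
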
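# The spectral engine: autocorrelation, the two power-spectrum routes,
# mode selection, the Cartesian route and peak extraction.

CM1 <- 219474.6313705

test_that("biased autocorrelation matches the hand/brute-force oracle", {
  s <- md_signal(c(1, 1, 1, 1), timestep = 1)
  ac <- autocorrelate(s)
  expect_equal(ac$values, c(1, 0.75, 0.5, 0.25), tolerance = 1e-14)
  expect_identical(ac$normalization, "biased")
  expect_equal(ac$lags, 0:3)

  z <- md_signal(numeric(16), timestep = 2)
  expect_true(all(autocorrelate(z)$values == 0))

  # cosine of period 8 samples oscillates with the same period, and the
  # whole estimator agrees with the explicit double loop
  x <- cos(2 * pi * (0:63) / 8)
  ac2 <- autocorrelate(md_signal(x, 1))
  expect_equal(ac2$values, brute_autocorr(x), tolerance = 1e-12)
  expect_gt(stats::cor(ac2$values[1:32], brute_autocorr(x)[1:32]), 0.999)
  expect_equal(which.max(ac2$values[2:12]) + 1L, 9L)  # first revival at lag 8

  # lag-0 value is the time mean of the squared signal
  set.seed(1)
  r <- rnorm(100)
  expect_equal(autocorrelate(md_signal(r, 1))$values[1], mean(r^2),
               tolerance = 1e-12)

  expect_error(autocorrelate(s, max_lag_fraction = 0), "max_lag_fraction")
  expect_error(autocorrelate(s, max_lag_fraction = 1.5), "max_lag_fraction")
})

test_that("a pure oscillator peaks at its frequency within one padded bin", {
  dt <- 10
  for (nu in c(700, 1500, 3333)) {
    t <- (0:2499) * dt
    sig <- md_signal(cos(nu / CM1 * t), dt)
    ps <- power_spectrum(sig, freq_window = c(0, 4000))
    bin <- ps$frequencies[2] - ps$frequencies[1]
    expect_lt(abs(dominant_peak(ps)["frequency"] - nu), bin)
  }
})

test_that("zero and constant signals give zero spectra", {
  z <- md_signal(numeric(64), 10)
  expect_true(all(power_spectrum(z, freq_window = c(0, 4000))$intensities == 0))
  cst <- md_signal(rep(2.5, 64), 10)
  expect_true(all(power_spectrum(cst, freq_window = c(0, 4000),
                                 remove_mean = TRUE)$intensities == 0))
})

test_that("FFT route equals the autocorrelation-FT route and the oracle", {
  set.seed(4)
  s <- md_signal(rnorm(64), 10)
  nyq <- pi / 10 * CM1
  a <- power_spectrum(s, freq_window = c(0, nyq), pad_factor = 4,
                      remove_mean = FALSE)
  b <- power_spectrum_direct(s, freq_window = c(0, nyq), pad_factor = 4,
                             remove_mean = FALSE)
  expect_equal(a$frequencies, b$frequencies, tolerance = 1e-12)
  expect_lt(max(abs(a$intensities - b$intensities)) / max(a$intensities),
            1e-10)
  # and both match the fully independent double-loop Wiener-Khinchin oracle
  oracle <- brute_wk_spectrum(s$values, 10, a$frequencies)
  expect_lt(max(abs(a$intensities[, 1] - oracle)) / max(oracle), 1e-10)
})

test_that("Parseval: the spectral integral equals half the mean square", {
  set.seed(8)
  nyq <- pi / 10 * CM1
  for (rep in 1:5) {
    s <- md_signal(rnorm(sample(50:400, 1)), 10)
    ps <- power_spectrum(s, freq_window = c(0, nyq), pad_factor = 4,
                         remove_mean = FALSE)
    expect_true(all(ps$intensities >= 0))
    expect_equal(spectrum_integral(ps), mean(s$values^2) / 2,
                 tolerance = 1e-8)
  }
})

test_that("frequency-window preconditions are enforced with Nyquist named", {
  s <- md_signal(rnorm(32), 10)
  err <- tryCatch(power_spectrum(s, freq_window = c(0, 1e6)),
                  error = function(e) conditionMessage(e))
  expect_match(err, "Nyquist")
  expect_match(err, "68950", fixed = FALSE)  # pi/(10 a.u.) in cm^-1
  expect_error(power_spectrum(s, freq_window = c(100, 100)), "lower")
})

test_that("mode selection: columns, sum linearity and range checks", {
  sys <- generate_harmonic_trajectory(c(1200, 2800), dt = 10, n_steps = 1500,
                                      seed = 6)
  all_sp <- power_spectrum(sys$nm, modes = "all")
  expect_identical(colnames(all_sp$intensities), c("mode_1", "mode_2"))
  bin <- all_sp$frequencies[2] - all_sp$frequencies[1]
  # each uncoupled mode peaks only at its own frequency
  expect_lt(abs(dominant_peak(all_sp, 1)["frequency"] - 1200), bin)
  expect_lt(abs(dominant_peak(all_sp, 2)["frequency"] - 2800), bin)
  p1 <- find_peaks(all_sp, 1, 0.01)
  expect_false(any(abs(p1$frequency - 2800) < 5 * bin))

  sum_sp <- power_spectrum(sys$nm, modes = "sum")
  expect_equal(sum_sp$intensities[, 1], rowSums(all_sp$intensities),
               tolerance = 0, ignore_attr = TRUE)
  pk <- find_peaks(sum_sp, 1, 0.1)
  expect_true(any(abs(pk$frequency - 1200) < bin))
  expect_true(any(abs(pk$frequency - 2800) < bin))

  picked <- power_spectrum(sys$nm, modes = c(2L, 1L))
  expect_identical(colnames(picked$intensities), c("mode_2", "mode_1"))

  expect_error(power_spectrum(sys$nm, modes = 3L), regexp = "1\\.\\.2")
})

test_that("mass-weighted Cartesian spectrum equals the normal-mode sum", {
  sys <- generate_harmonic_trajectory(c(900, 1700, 3100), dt = 10,
                                      n_steps = 800, seed = 10)
  pc <- power_spectrum(sys$trajectory, freq_window = c(0, 4000))
  pm <- power_spectrum(sys$nm, modes = "sum", freq_window = c(0, 4000))
  expect_lt(max(abs(pc$intensities - pm$intensities)) / max(pm$intensities),
            1e-8)
})

test_that("peak extraction finds constructed peaks and handles edge cases", {
  dt <- 10; t <- (0:2499) * dt
  two <- md_signal(cos(1100 / CM1 * t) + cos(2600 / CM1 * t + 0.7), dt)
  ps <- power_spectrum(two)
  bin <- ps$frequencies[2] - ps$frequencies[1]
  pk <- find_peaks(ps, 1, 0.5)
  expect_equal(nrow(pk), 2L)
  expect_lt(abs(pk$frequency[1] - 1100), bin)
  expect_lt(abs(pk$frequency[2] - 2600), bin)

  one <- power_spectrum(md_signal(cos(1500 / CM1 * t), dt))
  expect_equal(nrow(find_peaks(one, 1, 0.1)), 1L)

  flat <- vibspec:::new_power_spectrum(1:5, matrix(1, 5, 1), 10,
                                       list(padded_length = 10, timestep = 1))
  expect_equal(nrow(find_peaks(flat)), 0L)

  # exact tie: both bins reported, dominant = lower frequency
  tie <- vibspec:::new_power_spectrum(
    c(1, 2, 3, 4, 5), matrix(c(0, 3, 0, 3, 0), 5, 1), 10,
    list(padded_length = 10, timestep = 1))
  pk2 <- find_peaks(tie, 1, 0.5)
  expect_equal(pk2$frequency, c(2, 4))
  expect_equal(unname(dominant_peak(tie)["frequency"]), 2)

  expect_error(find_peaks(ps, 1, 0), "min_relative_height")
})

test_that("the Hann taper preserves peak location", {
  dt <- 10; t <- (0:2499) * dt
  sig <- md_signal(cos(2000 / CM1 * t), dt)
  ps <- power_spectrum(sig, taper = "hann")
  bin <- ps$frequencies[2] - ps$frequencies[1]
  expect_lt(abs(dominant_peak(ps)["frequency"] - 2000), bin)
})

test_that("spectra are nonnegative on randomized inputs", {
  set.seed(99)
  for (rep in 1:10) {
    s <- md_signal(rnorm(128) * runif(1, 0.1, 10), 10)
    ps <- power_spectrum(s, freq_window = c(0, 4000),
                         pad_factor = sample(c(1, 2, 8), 1),
                         taper = sample(c("rect", "hann"), 1),
                         remove_mean = sample(c(TRUE, FALSE), 1))
    expect_true(all(ps$intensities >= 0))
  }
})
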
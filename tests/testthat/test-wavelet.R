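sine_series <- function(n = 105, length_km = 2850, wavelengths = 150,
                        amps = 2, noise_sd = 1, seed = 1) {
  set.seed(seed)
  x <- sort(seq(length_km / n / 2, length_km - length_km / n / 2,
                length.out = n) + runif(n, -10, 10))
  v <- rnorm(n, 0, noise_sd)
  for (i in seq_along(wavelengths)) {
    v <- v + amps[i] * sin(2 * pi * x / wavelengths[i] + runif(1, 0, 2 * pi))
  }
  abundance_series("u", "o", x, v)
}

test_that("regularize_series interpolates linearly without extrapolation", {
  ser <- abundance_series("u", "o", seq(0, 175, by = 25), c(0, 1, 0, 1, 0, 1, 0, 1))
  g <- regularize_series(ser, dx_km = 25)
  expect_equal(g$values, ser$values)  # sites already on the grid
  # midpoint between two sites gets the mean of their values
  ser2 <- abundance_series("u", "o", c(0, 50, 100, 150, 200, 250, 300, 350),
                           c(0, 1, 0, 1, 0, 1, 0, 1))
  g2 <- regularize_series(ser2, dx_km = 25)
  expect_equal(g2$values[2], 0.5)
  expect_equal(range(g2$grid_positions_km), c(0, 350))
  expect_error(regularize_series(
    abundance_series("u", "o", 1:5, rnorm(5))), "at least 8")
})

test_that("a constant signal has (numerically) zero power", {
  ser <- abundance_series("u", "o", seq(0, 2800, by = 25), rep(3, 113))
  g <- regularize_series(ser)
  wp <- suppressWarnings(morlet_power(g))
  expect_true(max(wp$power) < 1e-20)
})

test_that("pure sinusoids peak at their own wavelength", {
  ser <- sine_series(wavelengths = 150, amps = 1, noise_sd = 0, seed = 3)
  g <- regularize_series(ser)
  wp <- suppressWarnings(morlet_power(g))
  gp <- global_power_spectrum(wp)
  peak <- gp$scale_km[which.max(gp$global_power)]
  # within one scale step (8 voices: factor 2^(1/8)) of 150 km
  expect_true(abs(log2(peak / 150)) <= 1 / 8 + 1e-9)
  # two planted sinusoids produce two local maxima, each near its wavelength
  ser2 <- sine_series(wavelengths = c(100, 600), amps = c(1, 1),
                      noise_sd = 0, seed = 4)
  gp2 <- global_power_spectrum(suppressWarnings(morlet_power(regularize_series(ser2))))
  v <- gp2$global_power
  locmax <- which(diff(sign(diff(c(-Inf, v, -Inf)))) < 0)
  peaks <- gp2$scale_km[locmax]
  expect_true(any(abs(log2(peaks / 100)) <= 1 / 8 + 1e-9))
  expect_true(any(abs(log2(peaks / 600)) <= 1 / 8 + 1e-9))
})

test_that("scale rectification keeps sinusoid peaks comparable across wavelengths", {
  h <- sapply(c(100, 200, 400, 800), function(lam) {
    ser <- sine_series(wavelengths = lam, amps = 1, noise_sd = 0, seed = 5)
    g <- regularize_series(ser)
    wp <- suppressWarnings(morlet_power(g))
    # read the peak away from edge effects: positions outside the COI
    gp <- global_power_spectrum(wp, mask = wp$coi_km >= lam)
    max(gp$global_power)
  })
  # peak heights at equal amplitude agree within ~20% across a 3-octave span
  expect_true(max(h) / min(h) < 1.5)
})

test_that("global power averages the power matrix over masked positions", {
  ser <- sine_series(seed = 6)
  wp <- suppressWarnings(morlet_power(regularize_series(ser)))
  gp <- global_power_spectrum(wp)
  expect_equal(gp$global_power, rowMeans(wp$power), tolerance = 1e-12)
  mask <- rep(c(TRUE, FALSE), length.out = ncol(wp$power))
  gpm <- global_power_spectrum(wp, mask)
  expect_equal(gpm$global_power, rowMeans(wp$power[, mask]), tolerance = 1e-12)
  expect_error(global_power_spectrum(wp, mask = rep(FALSE, ncol(wp$power))),
               "every position")
})

test_that("surrogate thresholds are positive, reproducible, and scale-equivariant", {
  ser <- sine_series(seed = 7)
  g <- regularize_series(ser)
  nt1 <- null_thresholds(g, n_sim = 30, seed = 5)
  nt2 <- null_thresholds(g, n_sim = 30, seed = 5)
  expect_identical(nt1$null_q95, nt2$null_q95)
  expect_true(all(nt1$null_q95 > 0))
  # doubling all values: standardization makes the whole analysis invariant
  ser2 <- abundance_series("u", "o", ser$positions_km, 2 * ser$values)
  w1 <- wavelet_analysis(ser, n_sim = 30, seed = 9)
  w2 <- wavelet_analysis(ser2, n_sim = 30, seed = 9)
  expect_equal(w1$spectrum$global_power, w2$spectrum$global_power,
               tolerance = 1e-12)
  expect_equal(w1$dominant_scale_km, w2$dominant_scale_km)
  # shifting by a constant leaves power unchanged (mean removed)
  ser3 <- abundance_series("u", "o", ser$positions_km, ser$values + 11)
  w3 <- wavelet_analysis(ser3, n_sim = 30, seed = 9)
  expect_equal(w1$spectrum$global_power, w3$spectrum$global_power,
               tolerance = 1e-12)
})

test_that("dominant_scales applies the local-max, threshold and octave rules", {
  scales <- wavelet_scales(50, 1600, 4)
  gp <- rep(0.1, length(scales))
  thr <- rep(0.2, length(scales))
  # no scale exceeds the threshold -> empty result
  out <- dominant_scales(gp, thr, scales)
  expect_true(is.na(out$dominant_scale_km))
  expect_length(out$secondary_scales_km, 0)
  # a single super-threshold local max
  i150 <- which.min(abs(scales - 150))
  gp[i150] <- 0.5
  out1 <- dominant_scales(gp, thr, scales)
  expect_equal(out1$dominant_scale_km, scales[i150])
  expect_length(out1$secondary_scales_km, 0)
  # a second peak two octaves away becomes a secondary; a sub-octave bump does not
  i600 <- which.min(abs(scales - 600))
  gp[i600] <- 0.4
  i200 <- which.min(abs(scales - 200))
  gp[i200] <- 0.45  # significant local max but < 1 octave from 150
  out2 <- dominant_scales(gp, thr, scales)
  expect_equal(out2$dominant_scale_km, scales[i150])
  expect_equal(out2$secondary_scales_km, scales[i600])
})

test_that("the full analysis recovers a planted scale and is deterministic", {
  ser <- sine_series(wavelengths = 150, amps = 2, noise_sd = 1, seed = 8)
  w1 <- wavelet_analysis(ser, n_sim = 50, seed = 13)
  w2 <- wavelet_analysis(ser, n_sim = 50, seed = 13)
  expect_identical(w1$spectrum, w2$spectrum)
  expect_true(abs(w1$dominant_scale_km - 150) <= 0.25 * 150)
})
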
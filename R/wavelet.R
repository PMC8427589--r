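# Morlet continuous-wavelet detection of repeating spatial structure in
# along-shore abundance series.
#
# The implementation follows the standard FFT formulation of the CWT with
# an analytic Morlet mother wavelet (omega0 = 6). Raw squared-modulus
# power under the classic normalisation is biased toward large scales (a
# sinusoid's peak power grows linearly with its scale), so power is
# rectified by dividing by scale (the Liu/Liang/Weisberg correction):
# reported power is |W|^2 * dx / s, under which sinusoids of equal
# amplitude produce peaks of equal height at any wavelength and spectra
# are comparable across scales. Scales are parameterised by their Fourier
# wavelength lambda = 4*pi*s / (omega0 + sqrt(2 + omega0^2)) ~ 1.033 s, so
# results are read directly in km. Significance of the position-averaged
# (global) power is assessed against surrogate series obtained by
# permuting the observed site values over the site positions, which
# preserves the marginal value distribution while destroying all spatial
# ordering.

MORLET_OMEGA0 <- 6
FOURIER_FACTOR <- 4 * pi / (MORLET_OMEGA0 + sqrt(2 + MORLET_OMEGA0^2))

#' Log2-spaced Fourier wavelengths for the wavelet scan
#'
#' @param min_km,max_km Wavelength bounds (defaults 50 and 1,600 km).
#' @param voices Scales per octave (default 8).
#' @return Strictly increasing wavelengths covering \[min_km, max_km\].
#' @export
wavelet_scales <- function(min_km = 50, max_km = 1600, voices = 8) {
  stop_if_not(min_km > 0 && max_km > min_km, "need 0 < min_km < max_km")
  n_oct <- log2(max_km / min_km)
  min_km * 2^(seq(0, n_oct, by = 1 / voices))
}

#' Interpolate an irregular site series onto a regular grid
#'
#' Linear interpolation onto a grid of spacing `dx_km` spanning the
#' sampled extent (first to last site); no extrapolation beyond the
#' extreme sites. The original site positions and values are retained in
#' the result so surrogate series can be re-gridded the same way.
#'
#' @param series An [abundance_series()] with at least 8 sites (fewer is
#'   an error: too few for spectral analysis).
#' @param dx_km Grid spacing (default 25 km, below half the smallest
#'   default scale and comparable to typical inter-site spacing).
#' @return Object of class `gridded_series`: list `grid_positions_km`,
#'   `values`, `dx_km`, `coverage_mask`, `site_positions_km`,
#'   `site_values`, `species`, `observer`.
#' @export
regularize_series <- function(series, dx_km = 25) {
  stop_if_not(inherits(series, "abundance_series"),
              "series must be an abundance_series")
  n <- length(series$values)
  stop_if_not(n >= 8, "need at least 8 sites for spectral analysis")
  stop_if_not(dx_km > 0, "dx_km must be positive")
  p <- series$positions_km
  grid <- seq(p[1], p[n], by = dx_km)
  vals <- stats::approx(p, series$values, xout = grid, method = "linear")$y
  structure(
    list(grid_positions_km = grid,
         values = vals,
         dx_km = dx_km,
         coverage_mask = rep(TRUE, length(grid)),
         site_positions_km = p,
         site_values = series$values,
         species = series$species,
         observer = series$observer),
    class = "gridded_series"
  )
}

# Core CWT on an already standardized regular signal. Returns the
# n_scales x n_pos power matrix for the requested Fourier wavelengths.
morlet_cwt_power <- function(values, dx, wavelengths) {
  n <- length(values)
  # pad to at least twice the series length so large-scale coefficients
  # never wrap around the transect ends
  n_pad <- 2^(ceiling(log2(n)) + 1)
  z <- c(values, rep(0, n_pad - n))
  fz <- stats::fft(z)
  k <- seq_len(n_pad) - 1
  omega <- 2 * pi * k / (n_pad * dx)
  omega[k > n_pad / 2] <- -omega[k > n_pad / 2]
  scales <- wavelengths / FOURIER_FACTOR
  power <- matrix(0, nrow = length(scales), ncol = n)
  for (si in seq_along(scales)) {
    s <- scales[si]
    psi_hat <- ifelse(
      omega > 0,
      pi^(-1/4) * sqrt(2 * pi * s / dx) * exp(-(s * omega - MORLET_OMEGA0)^2 / 2),
      0)
    w <- stats::fft(fz * psi_hat, inverse = TRUE) / n_pad
    # scale rectification: |W|^2 dx / s
    power[si, ] <- Mod(w[seq_len(n)])^2 * dx / s
  }
  power
}

#' Morlet wavelet power of a gridded series
#'
#' The series is standardized (mean removed, unit variance) before the
#' transform, so a constant shift leaves the power unchanged and the
#' reported power is relative to the series' own variance. Power is
#' scale-rectified (divided by scale), so peak heights are comparable
#' across wavelengths. Requested
#' wavelengths at or below the Nyquist wavelength (2 dx) or at or above
#' the gridded extent are excluded with a warning.
#'
#' @param gridded A [regularize_series()] result.
#' @param scales_km Fourier wavelengths to evaluate (default
#'   [wavelet_scales()]).
#' @return Object of class `wavelet_power`: list `scales_km`, `power`
#'   (scales x positions matrix), `coi_km` (per-position cone-of-influence
#'   wavelength: scales above it are edge-affected there), `positions_km`,
#'   `dx_km`.
#' @export
morlet_power <- function(gridded, scales_km = wavelet_scales()) {
  stop_if_not(inherits(gridded, "gridded_series"),
              "gridded must come from regularize_series()")
  dx <- gridded$dx_km
  extent <- diff(range(gridded$grid_positions_km))
  ok <- scales_km > 2 * dx & scales_km < extent
  if (!all(ok)) {
    warning(sprintf(
      "%d scale(s) outside (2 dx, extent) = (%.0f, %.0f) km excluded",
      sum(!ok), 2 * dx, extent))
  }
  scales_km <- scales_km[ok]
  stop_if_not(length(scales_km) >= 2, "fewer than 2 usable scales")
  v <- gridded$values
  sdv <- stats::sd(v)
  v <- if (sdv > 0) (v - mean(v)) / sdv else v - mean(v)
  power <- morlet_cwt_power(v, dx, scales_km)
  x <- gridded$grid_positions_km
  edge_dist <- pmin(x - x[1], x[length(x)] - x)
  coi <- FOURIER_FACTOR * edge_dist / sqrt(2)
  structure(list(scales_km = scales_km, power = power, coi_km = coi,
                 positions_km = x, dx_km = dx),
            class = "wavelet_power")
}

#' Global (position-averaged) wavelet power spectrum
#'
#' @param wp A [morlet_power()] result.
#' @param mask Logical per-position mask; defaults to all positions.
#' @return data.frame `scale_km`, `global_power`, `frac_edge_affected`
#'   (fraction of masked positions whose cone-of-influence wavelength is
#'   below the scale, i.e. where that scale is edge-affected).
#' @export
global_power_spectrum <- function(wp, mask = NULL) {
  stop_if_not(inherits(wp, "wavelet_power"), "wp must come from morlet_power()")
  if (is.null(mask)) mask <- rep(TRUE, ncol(wp$power))
  stop_if_not(length(mask) == ncol(wp$power), "mask length mismatch")
  stop_if_not(any(mask), "mask excludes every position")
  data.frame(
    scale_km = wp$scales_km,
    global_power = rowMeans(wp$power[, mask, drop = FALSE]),
    frac_edge_affected = vapply(wp$scales_km,
                                function(s) mean(wp$coi_km[mask] < s), 0)
  )
}

#' Surrogate-based significance thresholds for the global spectrum
#'
#' Each of `n_sim` surrogates permutes the observed site values over the
#' site positions, re-grids and standardizes them exactly as the observed
#' series, and recomputes the global power. The per-scale threshold is
#' the empirical 95th percentile over surrogates. Permutation preserves
#' the (typically skewed) marginal distribution of the data while
#' removing all spatial structure.
#'
#' @param gridded A [regularize_series()] result (it carries the original
#'   site values used for permutation).
#' @param scales_km Fourier wavelengths, as in [morlet_power()].
#' @param n_sim Number of surrogates (default 100; minimum 20).
#' @param seed Seed for the surrogate stream.
#' @param probs Quantile for the threshold (default 0.95).
#' @return List `null_q95` (per-scale threshold), `scales_km`,
#'   `null_power` (n_sim x n_scales matrix).
#' @export
null_thresholds <- function(gridded, scales_km = wavelet_scales(),
                            n_sim = 100, seed = 1L, probs = 0.95) {
  stop_if_not(inherits(gridded, "gridded_series"),
              "gridded must come from regularize_series()")
  stop_if_not(n_sim >= 20, "need n_sim >= 20")
  dx <- gridded$dx_km
  extent <- diff(range(gridded$grid_positions_km))
  scales_km <- scales_km[scales_km > 2 * dx & scales_km < extent]
  p <- gridded$site_positions_km
  v <- gridded$site_values
  grid <- gridded$grid_positions_km
  sims <- with_seed(seed, {
    t(vapply(seq_len(n_sim), function(b) {
      vb <- v[sample.int(length(v))]
      g <- stats::approx(p, vb, xout = grid, method = "linear")$y
      sdg <- stats::sd(g)
      g <- if (sdg > 0) (g - mean(g)) / sdg else g - mean(g)
      rowMeans(morlet_cwt_power(g, dx, scales_km))
    }, numeric(length(scales_km))))
  })
  list(null_q95 = apply(sims, 2, stats::quantile, probs = probs, names = FALSE),
       scales_km = scales_km,
       null_power = sims)
}

#' Dominant and secondary spatial scales from a global spectrum
#'
#' Candidate scales are local maxima of the global power that exceed the
#' surrogate threshold. The dominant scale is the candidate with maximal
#' power; secondary scales are the remaining candidates at least one
#' octave away from the dominant, ordered by decreasing power. An empty
#' candidate set means no significant repeating pattern.
#'
#' @param global_power Per-scale global power.
#' @param null_q95 Per-scale thresholds, aligned with `global_power`.
#' @param scales_km Scales, aligned.
#' @return List `dominant_scale_km` (`NA` if none), `secondary_scales_km`
#'   (possibly empty), `candidates` data.frame (`scale_km`, `power`,
#'   `threshold`).
#' @export
dominant_scales <- function(global_power, null_q95, scales_km) {
  m <- length(scales_km)
  stop_if_not(length(global_power) == m && length(null_q95) == m,
              "global_power, null_q95 and scales_km must be aligned")
  is_max <- logical(m)
  for (i in seq_len(m)) {
    left_ok <- i == 1 || global_power[i] > global_power[i - 1]
    right_ok <- i == m || global_power[i] >= global_power[i + 1]
    is_max[i] <- left_ok && right_ok
  }
  cand <- which(is_max & global_power > null_q95)
  candidates <- data.frame(scale_km = scales_km[cand],
                           power = global_power[cand],
                           threshold = null_q95[cand])
  if (length(cand) == 0) {
    return(list(dominant_scale_km = NA_real_,
                secondary_scales_km = numeric(0),
                candidates = candidates))
  }
  dom_i <- cand[which.max(global_power[cand])]
  dom <- scales_km[dom_i]
  sec_i <- cand[abs(log2(scales_km[cand] / dom)) >= 1]
  sec_i <- sec_i[order(global_power[sec_i], decreasing = TRUE)]
  list(dominant_scale_km = dom,
       secondary_scales_km = scales_km[sec_i],
       candidates = candidates)
}

#' Full wavelet analysis of one abundance series
#'
#' Convenience wrapper: grid the series, compute Morlet power, the global
#' spectrum, surrogate thresholds, and dominant/secondary scales.
#'
#' @param series An [abundance_series()].
#' @param dx_km Grid spacing (default 25 km).
#' @param scales_km Fourier wavelengths (default [wavelet_scales()]).
#' @param n_sim Surrogate count (default 100).
#' @param seed Seed for the surrogate stream.
#' @return Object of class `wavelet_result`: list `gridded`, `power`
#'   (`wavelet_power`), `spectrum` (global spectrum data.frame with a
#'   `null_q95` column), `dominant_scale_km`, `secondary_scales_km`,
#'   `candidates`, `n_sim`, `seed`.
#' @export
wavelet_analysis <- function(series, dx_km = 25, scales_km = wavelet_scales(),
                             n_sim = 100, seed = 1L) {
  gridded <- regularize_series(series, dx_km)
  wp <- suppressWarnings(morlet_power(gridded, scales_km))
  spec <- global_power_spectrum(wp)
  nt <- null_thresholds(gridded, scales_km, n_sim = n_sim, seed = seed)
  stop_if_not(identical(nt$scales_km, wp$scales_km),
              "internal scale mismatch between observed and surrogate spectra")
  spec$null_q95 <- nt$null_q95
  ds <- dominant_scales(spec$global_power, spec$null_q95, spec$scale_km)
  structure(list(gridded = gridded, power = wp, spectrum = spec,
                 dominant_scale_km = ds$dominant_scale_km,
                 secondary_scales_km = ds$secondary_scales_km,
                 candidates = ds$candidates,
                 n_sim = n_sim, seed = seed),
            class = "wavelet_result")
}

#' @export
print.wavelet_result <- function(x, ...) {
  cat(sprintf("Morlet wavelet analysis (%s / %s): %d scales in [%.0f, %.0f] km, %d surrogates\n",
              x$gridded$species %||% "?", x$gridded$observer %||% "?",
              length(x$power$scales_km), min(x$power$scales_km),
              max(x$power$scales_km), x$n_sim))
  if (is.na(x$dominant_scale_km)) {
    cat("  no significant repeating pattern\n")
  } else {
    cat(sprintf("  dominant scale: %.0f km", x$dominant_scale_km))
    if (length(x$secondary_scales_km)) {
      cat(sprintf("; secondary: %s km",
                  paste(sprintf("%.0f", x$secondary_scales_km), collapse = ", ")))
    }
    cat("\n")
  }
  invisible(x)
}
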
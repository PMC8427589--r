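# Global spatial autocorrelation along a 1-D coastline: Moran's I with a
# permutation null, and empirical variograms. Abundance values are
# log10(x + 1)-transformed before these analyses because CPUE is strongly
# right-skewed.

#' log10(x + 1) transform for right-skewed abundance
#'
#' @param x Nonnegative numeric.
#' @return `log10(x + 1)`.
#' @export
log10p1 <- function(x) {
  stop_if_not(all(x >= 0), "x must be nonnegative")
  log10(x + 1)
}

#' An along-shore abundance series for one species and observer
#'
#' @param species,observer Labels.
#' @param positions_km Strictly increasing along-shore positions.
#' @param values Transformed abundance, same length, finite.
#' @return Object of class `abundance_series`.
#' @export
abundance_series <- function(species, observer, positions_km, values) {
  stop_if_not(length(positions_km) == length(values),
              "positions and values must have the same length")
  stop_if_not(all(is.finite(positions_km)) && all(is.finite(values)),
              "positions and values must be finite")
  o <- order(positions_km)
  positions_km <- positions_km[o]; values <- values[o]
  stop_if_not(all(diff(positions_km) > 0),
              "positions must be strictly increasing (aggregate duplicate sites first)")
  structure(list(species = species, observer = observer,
                 positions_km = positions_km, values = values),
            class = "abundance_series")
}

#' Build the log-CPUE series of one observer from a site table
#'
#' @param site_table A `site_abundance` table.
#' @param species,observer Which rows to take.
#' @param transform Value transform, default [log10p1()].
#' @return An [abundance_series()].
#' @export
observer_series <- function(site_table, species, observer, transform = log10p1) {
  tab <- site_table[site_table$species == species &
                      site_table$observer_id == observer, ]
  stop_if_not(nrow(tab) >= 1,
              sprintf("no rows for species '%s', observer '%s'", species, observer))
  abundance_series(species, observer, tab$alongshore_km, transform(tab$cpue))
}

#' Spatial weight matrix for 1-D positions
#'
#' @param positions_km Strictly increasing positions.
#' @param scheme `"inverse_distance"` (w_ij = 1/d_ij, the common ecology
#'   default), `"distance_band"` (w_ij = 1 for 0 < d_ij <= `band_km`), or
#'   `"knn"` (w_ij = 1 when j is among the `k` nearest neighbours of i;
#'   not symmetrised).
#' @param band_km Band cutoff for `"distance_band"`.
#' @param k Neighbour count for `"knn"`.
#' @param normalize `"none"` (default) keeps raw weights; `"row"`
#'   standardises each row to sum to 1 (the W-style convention, as used by
#'   e.g. `ape::Moran.I`).
#' @return n x n weight matrix with zero diagonal.
#' @export
spatial_weights <- function(positions_km,
                            scheme = c("inverse_distance", "distance_band", "knn"),
                            band_km = NULL, k = 4,
                            normalize = c("none", "row")) {
  scheme <- match.arg(scheme)
  normalize <- match.arg(normalize)
  n <- length(positions_km)
  d <- abs(outer(positions_km, positions_km, "-"))
  w <- switch(scheme,
    inverse_distance = {
      m <- 1 / d
      diag(m) <- 0
      m
    },
    distance_band = {
      stop_if_not(!is.null(band_km) && band_km > 0,
                  "distance_band scheme needs band_km > 0")
      m <- (d > 0 & d <= band_km) * 1
      m
    },
    knn = {
      stop_if_not(k >= 1 && k < n, "need 1 <= k < n")
      m <- matrix(0, n, n)
      for (i in seq_len(n)) {
        nb <- order(d[i, ])[-1][seq_len(k)]  # nearest excluding self
        m[i, nb] <- 1
      }
      m
    })
  stop_if_not(sum(w) > 0, "weight matrix is all zero; widen the scheme")
  if (normalize == "row") {
    rs <- rowSums(w)
    w[rs > 0, ] <- w[rs > 0, , drop = FALSE] / rs[rs > 0]
  }
  w
}

#' Global Moran's I with permutation-based significance
#'
#' \deqn{I = \frac{n}{W} \frac{\sum_{ij} w_{ij} (v_i - \bar v)(v_j - \bar v)}
#'   {\sum_i (v_i - \bar v)^2}, \quad W = \sum_{ij} w_{ij}, \; w_{ii} = 0.}
#' Positive I indicates spatial clustering, negative dispersion; the null
#' expectation is \eqn{-1/(n-1)}. Significance comes from a permutation
#' null (values shuffled over positions, `n_perm` draws, seeded): the
#' z-score is `(I - mean(perm)) / sd(perm)` and the p-value is the
#' two-sided permutation tail with the observed arrangement counted, so p
#' is always in (0, 1\].
#'
#' @param series An [abundance_series()] with n >= 3 and non-constant
#'   values.
#' @param weight_scheme,band_km,k,normalize Passed to [spatial_weights()].
#' @param n_perm Number of permutations (default 999).
#' @param seed Seed for the permutation stream.
#' @return Object of class `moran_result`: list `I`, `expected_I`,
#'   `z_score`, `p_value`, `n`, `n_perm`, `weight_scheme`.
#' @export
morans_i <- function(series, weight_scheme = "inverse_distance",
                     n_perm = 999, seed = 1L, band_km = NULL, k = 4,
                     normalize = "none") {
  stop_if_not(inherits(series, "abundance_series"),
              "series must be an abundance_series")
  v <- series$values
  n <- length(v)
  stop_if_not(n >= 3, "need at least 3 sites")
  stop_if_not(stats::sd(v) > 0,
              "values are constant; Moran's I is undefined (degenerate input)")
  w <- spatial_weights(series$positions_km, weight_scheme,
                       band_km = band_km, k = k, normalize = normalize)
  W <- sum(w)
  i_stat <- function(z) {
    zc <- z - mean(z)
    (n / W) * as.numeric(zc %*% w %*% zc) / sum(zc^2)
  }
  i_obs <- i_stat(v)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) i_stat(v[sample.int(n)]), 0)
  })
  mu <- mean(perm); sdv <- stats::sd(perm)
  z <- if (sdv > 0) (i_obs - mu) / sdv else NA_real_
  p <- (1 + sum(abs(perm - mu) >= abs(i_obs - mu) - 1e-12)) / (n_perm + 1)
  structure(list(I = i_obs, expected_I = -1 / (n - 1), z_score = z,
                 p_value = min(p, 1), n = n, n_perm = n_perm,
                 weight_scheme = weight_scheme),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf(
    "Moran's I = %.4f (E[I] = %.4f), z = %.2f, perm. p = %.4g (n = %d, %d perms, %s weights)\n",
    x$I, x$expected_I, x$z_score, x$p_value, x$n, x$n_perm, x$weight_scheme))
  invisible(x)
}

#' Empirical variogram of an along-shore series
#'
#' Semivariance \eqn{\gamma(h)} is the mean of \eqn{(v_i - v_j)^2 / 2}
#' over site pairs whose separation falls in each lag bin. Because
#' variograms decompose at large lags, only pairs within 80% of the
#' maximum pairwise distance are used; that cutoff is divided into
#' `n_bins` equal-width bins with centres at bin midpoints. Empty bins
#' are kept (with `NA` semivariance) and flagged.
#'
#' @param series An [abundance_series()] with n >= 3.
#' @param n_bins Number of lag bins (default 20).
#' @param max_lag_fraction Fraction of the maximum pairwise distance used
#'   as the largest lag (default 0.8).
#' @return Object of class `variogram`: data.frame `lag_center_km`,
#'   `semivariance`, `n_pairs`, `empty`, with attributes `max_lag_km` and
#'   `n_pairs_total`.
#' @export
empirical_variogram <- function(series, n_bins = 20, max_lag_fraction = 0.8) {
  stop_if_not(inherits(series, "abundance_series"),
              "series must be an abundance_series")
  p <- series$positions_km; v <- series$values
  n <- length(v)
  stop_if_not(n >= 3, "need at least 3 sites")
  stop_if_not(n_bins >= 1, "n_bins must be >= 1")
  ij <- utils::combn(n, 2)
  d <- abs(p[ij[1, ]] - p[ij[2, ]])
  g <- 0.5 * (v[ij[1, ]] - v[ij[2, ]])^2
  max_lag <- max_lag_fraction * max(d)
  use <- d <= max_lag
  breaks <- seq(0, max_lag, length.out = n_bins + 1)
  bin <- findInterval(d[use], breaks, rightmost.closed = TRUE,
                      left.open = TRUE)
  bin[bin == 0] <- 1L  # zero-distance guard; pairs at d = 0 cannot occur
  gamma <- rep(NA_real_, n_bins)
  counts <- integer(n_bins)
  for (b in unique(bin)) {
    gamma[b] <- mean(g[use][bin == b])
    counts[b] <- sum(bin == b)
  }
  out <- data.frame(lag_center_km = (breaks[-1] + breaks[-length(breaks)]) / 2,
                    semivariance = gamma,
                    n_pairs = counts,
                    empty = counts == 0L)
  attr(out, "max_lag_km") <- max_lag
  attr(out, "n_pairs_total") <- sum(use)
  class(out) <- c("variogram", "data.frame")
  out
}
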
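# Independent brute-force oracles used to validate the package's
# statistical primitives. These deliberately use naive algorithms
# (counting ranks, double loops, all-k scans) so they share no code path
# with the implementations they check.

# mid-ranks by counting: rank of x_i = (# strictly smaller) + (# equal + 1)/2
oracle_midranks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }
  r
}

# Spearman rho as the explicit Pearson formula on counted mid-ranks
oracle_spearman <- function(x, y) {
  rx <- oracle_midranks(x)
  ry <- oracle_midranks(y)
  mx <- mean(rx); my <- mean(ry)
  num <- sum((rx - mx) * (ry - my))
  den <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  num / den
}

# BH by definition: adjusted p via min over j >= rank(i); rejection set by
# scanning every k
oracle_bh <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (pos in seq_len(m)) {
    i <- o[pos]
    vals <- sapply(pos:m, function(j) m * p[o[j]] / j)
    adj[i] <- min(1, min(vals))
  }
  k_star <- 0
  for (k in seq_len(m)) {
    if (p[o[k]] <= k * alpha / m) k_star <- k
  }
  reject <- logical(m)
  if (k_star > 0) reject[o[seq_len(k_star)]] <- TRUE
  list(p_adjusted = adj, reject = reject)
}

# Moran's I as a literal double loop over the weight matrix
oracle_moran <- function(values, w) {
  n <- length(values)
  vbar <- mean(values)
  num <- 0; W <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- num + w[i, j] * (values[i] - vbar) * (values[j] - vbar)
      W <- W + w[i, j]
    }
  }
  (n / W) * num / sum((values - vbar)^2)
}

# binned semivariance as a literal pair loop
oracle_variogram <- function(positions, values, n_bins, max_lag_fraction = 0.8) {
  n <- length(values)
  dmax <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dmax <- max(dmax, abs(positions[i] - positions[j]))
  }
  max_lag <- max_lag_fraction * dmax
  breaks <- seq(0, max_lag, length.out = n_bins + 1)
  sums <- numeric(n_bins); counts <- integer(n_bins)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- abs(positions[i] - positions[j])
    if (d > max_lag) next
    b <- NA
    for (k in seq_len(n_bins)) {
      if (d > breaks[k] && d <= breaks[k + 1]) { b <- k; break }
    }
    if (is.na(b)) b <- 1  # d == 0 guard (cannot occur for strict positions)
    sums[b] <- sums[b] + 0.5 * (values[i] - values[j])^2
    counts[b] <- counts[b] + 1L
  }
  list(semivariance = ifelse(counts > 0, sums / pmax(counts, 1), NA_real_),
       n_pairs = counts, max_lag = max_lag)
}

# habitat amount by walking cells one at a time
oracle_habitat <- function(map, site_km, direction, window_km) {
  cell <- floor(site_km) + 1
  sgn <- map$upstream_sign[cell]
  if (direction == "downstream") sgn <- -sgn
  total <- 0
  for (step in seq_len(window_km)) {
    idx <- cell + sgn * step
    if (idx >= 1 && idx <= map$length_km) total <- total + map$rocky[idx]
  }
  total
}

# small survey world reused by several test files
make_test_world <- function(seed = 1, n_sites = 40, length_km = 1000,
                            coupling = 0, overdisp = 1, baseline = 0.5) {
  map <- generate_habitat_map(length_km, 0.5, 20, seed = seed)
  cfg <- list(species_field_config("urchin", c(0, length_km), baseline,
                                   habitat_coupling = coupling,
                                   dispersal_window_km = 100,
                                   overdispersion = overdisp))
  fields <- generate_species_fields(map, cfg)
  visits <- generate_survey(map, fields, list(observer_config("obs1", 1)),
                            n_sites = n_sites, seed = seed + 1)
  list(map = map, fields = fields, visits = visits)
}

# longest run of consecutive significant positive windows, as a span in km
sig_run_span_km <- function(scan, dir, step_km = 5) {
  sc <- scan[scan$direction == dir, ]
  sc <- sc[order(sc$window_km), ]
  sig <- sc$significant & !is.na(sc$rho) & sc$rho > 0
  r <- rle(sig)
  if (!any(r$values)) return(0)
  (max(r$lengths[r$values]) - 1) * step_km
}
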
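# Synthetic coastal-survey generator.
#
# The generator emulates the sampling design the downstream analyses
# assume: a ~2,850 km linear coast discretised into 1-km habitat cells,
# ~105 rocky-shore sites surveyed by up to six observers with differing
# detection efficiency, timed searches whose duration and tidal metadata
# occasionally violate the quality filters, and per-species expected
# abundance surfaces carrying periodic along-shore structure and optional
# coupling to the amount of upstream rocky habitat.

#' Generate a binary rocky-habitat map for a linear coast
#'
#' The coast is discretised into 1-km cells (cell `i` in the returned
#' vectors covers the along-shore interval `[i-1, i)` km, with km 0 at the
#' map's north-western end). Rockiness is produced by thresholding a
#' moving-average of white noise: the moving-average window sets the patch
#' scale, and the threshold is the empirical quantile that yields the
#' requested rocky fraction, so the realised fraction matches
#' `rocky_fraction` to within one cell.
#'
#' Each cell also carries an upstream sign: the direction (+1 = increasing
#' along-shore coordinate, -1 = decreasing) pointing toward the source of
#' the prevailing current. By default the whole coast is +1; setting
#' `flip_below_boundary = TRUE` flips cells before `boundary_km`, which
#' models a coast split between two opposing current systems.
#'
#' @param length_km Number of 1-km cells (positive integer).
#' @param rocky_fraction Target fraction of rocky cells, in \[0, 1\].
#' @param patch_scale_km Moving-average window width; sets the typical
#'   rocky patch length (km).
#' @param boundary_km Along-shore position of the current divide.
#' @param flip_below_boundary If `TRUE`, cells with position < `boundary_km`
#'   get upstream sign -1.
#' @param seed Integer seed; the same seed and arguments regenerate the map
#'   bit-identically.
#' @return An object of class `coast_map`: a list with `length_km`,
#'   integer vector `rocky` (0/1), `upstream_sign` (+1/-1), and `meta`.
#' @examples
#' m <- generate_habitat_map(500, rocky_fraction = 0.4, seed = 1)
#' mean(m$rocky)
#' @export
generate_habitat_map <- function(length_km, rocky_fraction,
                                 patch_scale_km = 20,
                                 boundary_km = 0,
                                 flip_below_boundary = FALSE,
                                 seed = 1L) {
  stop_if_not(length_km >= 1 && length_km == round(length_km),
              "length_km must be a positive integer")
  stop_if_not(rocky_fraction >= 0 && rocky_fraction <= 1,
              "rocky_fraction must be in [0, 1]")
  stop_if_not(patch_scale_km >= 1, "patch_scale_km must be >= 1")
  stop_if_not(boundary_km >= 0 && boundary_km <= length_km,
              "boundary_km must be within [0, length_km]")
  length_km <- as.integer(length_km)
  rocky <- with_seed(seed, {
    z <- stats::rnorm(length_km)
    w <- as.integer(round(patch_scale_km))
    # running mean with shrinking windows at the edges (no NA padding)
    cs <- c(0, cumsum(z))
    half <- w %/% 2
    lo <- pmax(seq_len(length_km) - half, 1L)
    hi <- pmin(seq_len(length_km) + half, length_km)
    sm <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
    n_rocky <- round(rocky_fraction * length_km)
    if (n_rocky == 0) {
      integer(length_km)
    } else if (n_rocky == length_km) {
      rep(1L, length_km)
    } else {
      # top-n_rocky cells of the smoothed field; quantile thresholding with
      # deterministic tie-breaking so the realised fraction is exact
      as.integer(rank(-sm, ties.method = "first") <= n_rocky)
    }
  })
  upstream_sign <- rep(1L, length_km)
  if (flip_below_boundary && boundary_km > 0) {
    upstream_sign[seq_len(min(length_km, floor(boundary_km)))] <- -1L
  }
  structure(
    list(length_km = length_km,
         rocky = rocky,
         upstream_sign = upstream_sign,
         meta = list(rocky_fraction = rocky_fraction,
                     patch_scale_km = patch_scale_km,
                     boundary_km = boundary_km,
                     flip_below_boundary = flip_below_boundary,
                     seed = seed)),
    class = "coast_map"
  )
}

#' @export
print.coast_map <- function(x, ...) {
  cat(sprintf("coast_map: %d km, rocky fraction %.3f, current divide at %s km\n",
              x$length_km, mean(x$rocky),
              if (x$meta$flip_below_boundary) format(x$meta$boundary_km) else "none"))
  invisible(x)
}

#' Configuration of one species' true abundance surface
#'
#' The expected catch-per-unit-effort (individuals per observer-minute) of
#' a species at along-shore position x is zero outside `range_km` and,
#' inside it,
#' \deqn{\mu(x) = B \exp\left(\sum_i a_i \sin(2\pi x/\lambda_i + \phi_i)\right)
#'   (1 + c\, h(x))}
#' where B is `baseline_cpue`, the sum runs over `periodic_components`
#' (wavelength \eqn{\lambda_i} km, amplitude \eqn{a_i}, phase \eqn{\phi_i}),
#' c is `habitat_coupling`, and h(x) is the amount of rocky habitat within
#' `dispersal_window_km` upstream of x divided by the window length (so
#' h in \[0, 1\]). The multiplicative periodic term keeps the surface
#' positive and produces the right-skewed abundance typical of count data.
#'
#' @param species Species label (used as the visits-table count column
#'   suffix, so keep it syntactic).
#' @param range_km Length-2 numeric `c(lo, hi)`, the along-shore
#'   distributional range.
#' @param baseline_cpue Expected individuals per observer-minute at a
#'   structureless point of the range.
#' @param periodic_components List of length-3 numeric vectors
#'   `c(wavelength_km, amplitude, phase)`.
#' @param habitat_coupling Strength c >= 0 of the upstream-habitat term.
#' @param dispersal_window_km Upstream kernel width (km) for the coupling.
#' @param overdispersion Negative-binomial size parameter k for the count
#'   noise (smaller = more overdispersed; k -> Inf is the Poisson limit).
#' @return A `species_field_config` list.
#' @export
species_field_config <- function(species, range_km, baseline_cpue,
                                 periodic_components = list(),
                                 habitat_coupling = 0,
                                 dispersal_window_km = 100,
                                 overdispersion = 1) {
  stop_if_not(length(range_km) == 2 && range_km[1] < range_km[2],
              "range_km must be c(lo, hi) with lo < hi")
  stop_if_not(baseline_cpue >= 0, "baseline_cpue must be >= 0")
  stop_if_not(habitat_coupling >= 0, "habitat_coupling must be >= 0")
  stop_if_not(dispersal_window_km > 0, "dispersal_window_km must be > 0")
  stop_if_not(overdispersion > 0, "overdispersion must be > 0")
  for (pc in periodic_components) {
    stop_if_not(length(pc) == 3 && pc[1] > 0 && pc[2] >= 0,
                "periodic components must be c(wavelength > 0, amplitude >= 0, phase)")
  }
  structure(
    list(species = as.character(species),
         range_km = as.numeric(range_km),
         baseline_cpue = baseline_cpue,
         periodic_components = periodic_components,
         habitat_coupling = habitat_coupling,
         dispersal_window_km = dispersal_window_km,
         overdispersion = overdispersion),
    class = "species_field_config"
  )
}

#' Configuration of one observer
#'
#' @param observer Observer id.
#' @param detection_efficiency Positive multiplier on expected counts;
#'   captures inter-observer detection differences.
#' @param shore_focus One of "mid", "low", "full" — which vertical shore
#'   band the observer concentrates on (metadata label; the quantitative
#'   consequence is expressed through `detection_efficiency`).
#' @param sites_covered Optional character vector of site ids the observer
#'   can visit; `NULL` means any site.
#' @param activity Positive sampling weight: how often this observer joins
#'   a survey team relative to the others. Real multi-observer surveys are
#'   very unequal (25 to 100+ sites per observer over ~105 sites).
#' @return An `observer_config` list.
#' @export
observer_config <- function(observer, detection_efficiency = 1,
                            shore_focus = c("full", "mid", "low"),
                            sites_covered = NULL, activity = 1) {
  shore_focus <- match.arg(shore_focus)
  stop_if_not(detection_efficiency > 0, "detection_efficiency must be > 0")
  stop_if_not(activity > 0, "activity must be > 0")
  structure(
    list(observer = as.character(observer),
         detection_efficiency = detection_efficiency,
         shore_focus = shore_focus,
         sites_covered = sites_covered,
         activity = activity),
    class = "observer_config"
  )
}

#' Evaluate species' expected-CPUE surfaces on the habitat map
#'
#' Deterministic given the map and configurations: evaluates each species'
#' expected CPUE (see [species_field_config()]) at every habitat-cell
#' centre (x = cell + 0.5 km, 0-based cells).
#'
#' @param map A `coast_map`.
#' @param species_configs Nonempty list of `species_field_config`s whose
#'   ranges lie within the map.
#' @return A `species_fields` object: list with `positions_km` (cell
#'   centres), `mu` (cells x species matrix of expected CPUE), and
#'   `configs`.
#' @export
generate_species_fields <- function(map, species_configs) {
  stop_if_not(inherits(map, "coast_map"), "map must be a coast_map")
  stop_if_not(length(species_configs) >= 1, "species_configs must be nonempty")
  positions <- seq_len(map$length_km) - 0.5
  mu <- matrix(0, nrow = map$length_km, ncol = length(species_configs))
  colnames(mu) <- vapply(species_configs, `[[`, "", "species")
  for (j in seq_along(species_configs)) {
    cfg <- species_configs[[j]]
    stop_if_not(cfg$range_km[1] >= 0 && cfg$range_km[2] <= map$length_km,
                sprintf("range of '%s' falls outside the map", cfg$species))
    inside <- positions >= cfg$range_km[1] & positions <= cfg$range_km[2]
    if (!any(inside)) next
    x <- positions[inside]
    logper <- 0
    for (pc in cfg$periodic_components) {
      logper <- logper + pc[2] * sin(2 * pi * x / pc[1] + pc[3])
    }
    f <- cfg$baseline_cpue * exp(logper)
    if (cfg$habitat_coupling > 0) {
      h <- habitat_amount(map, x, direction = "upstream",
                          window_km = cfg$dispersal_window_km)
      f <- f * (1 + cfg$habitat_coupling * h / cfg$dispersal_window_km)
    }
    mu[inside, j] <- f
  }
  structure(list(positions_km = positions, mu = mu, configs = species_configs),
            class = "species_fields")
}

#' Default synthetic world: four urchin-like species on a 2,850-km coast
#'
#' One wide-ranging abundant species spanning the whole coast and three
#' narrow-ranging species confined to its eastern end, with nested ranges
#' whose four-way overlap spans 205 km. Each species carries periodic
#' along-shore structure at a wavelength in the 75-220 km band (the
#' wide-ranging species also a weaker 600-km component), and the two
#' easternmost species are coupled to upstream habitat through a 100-km
#' dispersal kernel. Baseline CPUEs follow the relative-abundance ladder
#' typical of such guilds (1.35, 0.28, 0.28, 0.01 individuals per
#' observer-minute).
#'
#' @param length_km Coast length the ranges are laid out on.
#' @return List of four `species_field_config`s.
#' @export
default_species_configs <- function(length_km = 2850) {
  east <- length_km
  list(
    species_field_config(
      "parechinus", range_km = c(0, east), baseline_cpue = 1.35,
      periodic_components = list(c(150, 0.8, 0.0), c(600, 0.4, 1.0)),
      habitat_coupling = 0, overdispersion = 1),
    species_field_config(
      "stomopneustes", range_km = c(east - 300, east - 95), baseline_cpue = 0.28,
      periodic_components = list(c(120, 0.8, 0.7)),
      habitat_coupling = 0, overdispersion = 1),
    species_field_config(
      "echinometra", range_km = c(east - 462, east), baseline_cpue = 0.28,
      periodic_components = list(c(176, 0.8, 2.1)),
      habitat_coupling = 2, dispersal_window_km = 100, overdispersion = 1),
    species_field_config(
      "diadema", range_km = c(east - 462, east), baseline_cpue = 0.01,
      periodic_components = list(c(120, 0.8, 4.0)),
      habitat_coupling = 2, dispersal_window_km = 100, overdispersion = 1)
  )
}

#' Default synthetic observer pool: six observers with mixed shore focus
#'
#' @return List of six `observer_config`s: one mid-shore specialist, one
#'   low-shore specialist, four generalists, with detection efficiencies
#'   spread over roughly +/-20% and activity weights mirroring the
#'   strongly unequal coverage of real survey teams (the most active
#'   observer reaches almost every site, the least about a quarter).
#' @export
default_observer_configs <- function() {
  list(
    observer_config("obs1", 1.2, "mid", activity = 3.0),
    observer_config("obs2", 1.1, "low", activity = 1.7),
    observer_config("obs3", 1.0, "full", activity = 1.2),
    observer_config("obs4", 0.9, "full", activity = 0.6),
    observer_config("obs5", 1.0, "full", activity = 1.1),
    observer_config("obs6", 0.8, "full", activity = 1.0)
  )
}

#' Simulate a timed-search visits table
#'
#' Sites are placed on randomly chosen rocky cells. Each site receives one
#' to four observers (sampled from the configured pool, honouring
#' `sites_covered`); each observer makes one visit. Counts per species are
#' drawn from a negative binomial with mean
#' `expected CPUE x search minutes x detection efficiency` and the
#' species' overdispersion parameter. Search durations are log-normal
#' (median ~45 min), clamped to the realistic 15-257 min band, except that
#' a configurable fraction of visits is made deliberately short (< 15 min)
#' and a further fraction is made at high water (> 0.83 m tide), so the
#' downstream exclusion filters are exercised. Tide heights are normal
#' (mean 0.48 m, sd 0.22 m) truncated to \[0.09, 1.43\] m; that
#' distribution already exceeds the 0.83 m filter threshold on ~5% of
#' visits, so `high_fraction` (extra visits forced above the threshold)
#' defaults to 0.
#'
#' @param map A `coast_map`.
#' @param fields A `species_fields` from [generate_species_fields()].
#' @param observer_configs Nonempty list of `observer_config`s.
#' @param n_sites Number of survey sites (must not exceed the number of
#'   rocky cells).
#' @param effort_cfg List: `meanlog`, `sdlog` of the log-normal duration
#'   (minutes), clamp bounds `min_minutes`, `max_minutes`, and
#'   `short_fraction` — the fraction of visits forced below 15 minutes.
#' @param tide_cfg List: `mean`, `sd`, `min`, `max` (metres) and
#'   `high_fraction` — the fraction of visits forced above 0.83 m.
#' @param seed Integer seed.
#' @return A data.frame of visits: `visit_id`, `site_id`, `alongshore_km`,
#'   `observer_id`, `date`, `search_minutes`, `tide_start_m`,
#'   `tide_end_m`, and one `count_<species>` column per species.
#' @export
generate_survey <- function(map, fields, observer_configs,
                            n_sites = 105,
                            effort_cfg = list(meanlog = log(45), sdlog = 0.5,
                                              min_minutes = 15, max_minutes = 257,
                                              short_fraction = 0.07),
                            tide_cfg = list(mean = 0.48, sd = 0.22,
                                            min = 0.09, max = 1.43,
                                            high_fraction = 0),
                            seed = 1L) {
  stop_if_not(inherits(map, "coast_map"), "map must be a coast_map")
  stop_if_not(inherits(fields, "species_fields"),
              "fields must come from generate_species_fields()")
  stop_if_not(length(observer_configs) >= 1, "observer list must be nonempty")
  stop_if_not(n_sites >= 1, "n_sites must be >= 1")
  rocky_cells <- which(map$rocky == 1L)
  stop_if_not(n_sites <= length(rocky_cells),
              "n_sites exceeds the number of rocky cells")
  species <- colnames(fields$mu)
  obs_ids <- vapply(observer_configs, `[[`, "", "observer")
  with_seed(seed, {
    cells <- sort(sample(rocky_cells, n_sites))
    site_km <- cells - 0.5
    site_id <- sprintf("S%03d", seq_len(n_sites))
    # 1-4 observers per site; team sizes average ~3, as in range-wide
    # multi-observer surveys
    n_obs <- sample(1:4, n_sites, replace = TRUE, prob = c(0.15, 0.2, 0.3, 0.35))
    act <- vapply(observer_configs, function(oc) oc$activity %||% 1, 0)
    rows <- vector("list", n_sites)
    for (i in seq_len(n_sites)) {
      eligible <- vapply(observer_configs, function(oc) {
        is.null(oc$sites_covered) || site_id[i] %in% oc$sites_covered
      }, logical(1))
      pool <- which(eligible)
      stop_if_not(length(pool) >= 1,
                  sprintf("no observer covers site %s", site_id[i]))
      k <- min(n_obs[i], length(pool))
      picked <- if (length(pool) == 1) pool else sample(pool, k, prob = act[pool])
      rows[[i]] <- data.frame(site_idx = i, obs_idx = picked)
    }
    vis <- do.call(rbind, rows)
    nv <- nrow(vis)
    minutes <- stats::rlnorm(nv, effort_cfg$meanlog, effort_cfg$sdlog)
    minutes <- pmin(pmax(minutes, effort_cfg$min_minutes), effort_cfg$max_minutes)
    short <- stats::runif(nv) < effort_cfg$short_fraction
    minutes[short] <- stats::runif(sum(short), 5, 14.5)
    tide_start <- pmin(pmax(stats::rnorm(nv, tide_cfg$mean, tide_cfg$sd),
                            tide_cfg$min), tide_cfg$max)
    tide_end <- pmin(pmax(tide_start + stats::rnorm(nv, 0, 0.05),
                          tide_cfg$min), tide_cfg$max)
    high <- stats::runif(nv) < tide_cfg$high_fraction
    tide_start[high] <- stats::runif(sum(high), 0.84, tide_cfg$max)
    tide_end[high] <- pmin(pmax(tide_start[high] + stats::rnorm(sum(high), 0, 0.05),
                                0.84), tide_cfg$max)
    dates <- as.Date("2019-09-01") + sample(0:210, nv, replace = TRUE)
    counts <- matrix(0L, nrow = nv, ncol = length(species))
    colnames(counts) <- species
    for (j in seq_along(species)) {
      cfg <- fields$configs[[j]]
      mu_site <- fields$mu[cells[vis$site_idx], j]
      eff <- vapply(observer_configs, `[[`, 0, "detection_efficiency")[vis$obs_idx]
      mu_visit <- mu_site * minutes * eff
      nz <- mu_visit > 0
      if (any(nz)) {
        counts[nz, j] <- stats::rnbinom(sum(nz), mu = mu_visit[nz],
                                        size = cfg$overdispersion)
      }
    }
    out <- data.frame(
      visit_id = sprintf("V%04d", seq_len(nv)),
      site_id = site_id[vis$site_idx],
      alongshore_km = site_km[vis$site_idx],
      observer_id = obs_ids[vis$obs_idx],
      date = dates,
      search_minutes = round(minutes, 1),
      tide_start_m = round(tide_start, 2),
      tide_end_m = round(tide_end, 2),
      stringsAsFactors = FALSE
    )
    for (sp in species) out[[paste0("count_", sp)]] <- counts[, sp]
    attr(out, "seed") <- seed
    out
  })
}

#' Write / read the habitat-map CSV dialect
#'
#' Columns: `cell_km` (0-based cell index; cell covers \[km, km+1)),
#' `rocky` (0/1), `upstream_sign` (+1/-1).
#' @param map A `coast_map`.
#' @param path File path.
#' @export
write_habitat_csv <- function(map, path) {
  stop_if_not(inherits(map, "coast_map"), "map must be a coast_map")
  utils::write.csv(
    data.frame(cell_km = seq_len(map$length_km) - 1L,
               rocky = map$rocky,
               upstream_sign = map$upstream_sign),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_habitat_csv
#' @export
read_habitat_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("cell_km", "rocky", "upstream_sign")
  missing <- setdiff(need, names(df))
  stop_if_not(length(missing) == 0,
              paste("habitat CSV is missing column(s):",
                    paste(missing, collapse = ", ")))
  stop_if_not(all(df$rocky %in% c(0L, 1L)), "rocky must be 0/1")
  stop_if_not(all(df$upstream_sign %in% c(-1L, 1L)), "upstream_sign must be +/-1")
  structure(
    list(length_km = nrow(df),
         rocky = as.integer(df$rocky),
         upstream_sign = as.integer(df$upstream_sign),
         meta = list(source = path)),
    class = "coast_map"
  )
}

#' Write / read the visits CSV dialect
#'
#' Required columns: `site_id`, `alongshore_km`, `observer_id`,
#' `search_minutes`, `tide_start_m`, `tide_end_m`, plus one
#' `count_<species>` column per species; extra columns are preserved.
#' @param visits Visits data.frame.
#' @param path File path.
#' @export
write_visits_csv <- function(visits, path) {
  utils::write.csv(visits, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_visits_csv
#' @export
read_visits_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "alongshore_km", "observer_id", "search_minutes",
            "tide_start_m", "tide_end_m")
  missing <- setdiff(need, names(df))
  stop_if_not(length(missing) == 0,
              paste("visits CSV is missing column(s):",
                    paste(missing, collapse = ", ")))
  stop_if_not(length(visit_species(df)) >= 1,
              "visits CSV has no count_<species> column")
  df
}

#' Deterministic QC demonstration fixture: 164 visits at 116 sites
#'
#' Builds, in code, a visits table with the removal bookkeeping of a real
#' multi-observer coastal survey: 164 visits across 116 sites of which 14
#' visits fail the bias filters — 6 on duration only (< 15 min), 3 on tide
#' only (> 0.83 m), and 5 on both — arranged so that exactly 11 sites lose
#' every visit, leaving 105 analysable sites. Useful for demonstrating and
#' testing [apply_exclusion_filters()] end to end.
#'
#' @param seed Seed for the (cosmetic) count and metadata noise.
#' @return A visits data.frame in the standard dialect with one species
#'   column `count_urchin`.
#' @export
filter_demo_visits <- function(seed = 42L) {
  n_sites <- 116L
  site_id <- sprintf("S%03d", seq_len(n_sites))
  site_km <- seq(5, 2845, length.out = n_sites)
  # sites S001..S011 carry only failing visits: S001-S008 one visit each,
  # S009-S011 two visits each (8 + 6 = 14 failing visits in total)
  bad_site_of_visit <- c(sprintf("S%03d", 1:8), rep(sprintf("S%03d", 9:11), each = 2))
  fail_class <- c(rep("duration", 6), rep("tide", 3), rep("both", 5))
  with_seed(seed, {
    good_sites <- site_id[12:116]                       # 105 sites
    extra <- sample(good_sites, 150 - length(good_sites), replace = TRUE)
    good_site_of_visit <- c(good_sites, extra)          # 150 passing visits
    site_of_visit <- c(bad_site_of_visit, good_site_of_visit)
    nv <- length(site_of_visit)                         # 164
    minutes <- round(stats::runif(nv, 20, 120), 1)
    tide <- round(stats::runif(nv, 0.15, 0.70), 2)
    is_dur <- fail_class %in% c("duration", "both")
    is_tide <- fail_class %in% c("tide", "both")
    minutes[seq_len(14)][is_dur] <- round(stats::runif(sum(is_dur), 8, 14.5), 1)
    tide[seq_len(14)][is_tide] <- round(stats::runif(sum(is_tide), 0.9, 1.4), 2)
    km <- site_km[match(site_of_visit, site_id)]
    data.frame(
      visit_id = sprintf("V%04d", seq_len(nv)),
      site_id = site_of_visit,
      alongshore_km = km,
      observer_id = sample(sprintf("obs%d", 1:6), nv, replace = TRUE),
      date = as.Date("2019-09-01") + sample(0:210, nv, replace = TRUE),
      search_minutes = minutes,
      tide_start_m = tide,
      tide_end_m = round(pmin(pmax(0.09, tide + stats::rnorm(nv, 0, 0.03)), 0.80), 2),
      count_urchin = stats::rnbinom(nv, mu = 20, size = 1),
      stringsAsFactors = FALSE
    )
  })
}
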
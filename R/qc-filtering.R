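# Bias filtering and CPUE standardisation.
#
# Raw visits are converted to catch-per-unit-effort (individuals per
# observer-minute) after removing visits likely to yield false negatives:
# very short searches (< 15 min) and searches at high water (> 0.83 m
# predicted tide). Zero counts from adequate searches are kept as true
# zeros. Observer concordance over shared sites is reported so that
# downstream spatial analyses can be run per observer when agreement is
# poor.

#' Catch per unit effort
#'
#' CPUE standardises a timed-search count to individuals per
#' observer-minute, the package's relative abundance index.
#'
#' @param count Nonnegative count(s) of individuals.
#' @param search_minutes Positive search duration(s) in minutes.
#' @return `count / search_minutes`, vectorised.
#' @examples
#' compute_cpue(30, 60)   # 0.5
#' compute_cpue(22, 219)  # ~0.1 ind. per observer-minute
#' @export
compute_cpue <- function(count, search_minutes) {
  stop_if_not(all(search_minutes > 0), "search_minutes must be positive")
  stop_if_not(all(count >= 0), "count must be nonnegative")
  count / search_minutes
}

#' Remove visits prone to false-negative detections
#'
#' A visit is removed iff `search_minutes < min_duration` OR
#' `max(tide_start_m, tide_end_m) > max_tide`; both comparisons are strict,
#' so a 15-minute search at exactly 0.83 m is kept. The higher of the two
#' tide readings is used because detection is limited by the worst water
#' level experienced during the search. A site is removed only when all of
#' its visits are removed.
#'
#' @param visits Visits data.frame (see [read_visits_csv()] for required
#'   columns). A `visit_id` column is added if absent.
#' @param min_duration Minimum acceptable search duration (minutes).
#' @param max_tide Maximum acceptable tidal height (metres).
#' @return List of class `qc_result` with:
#'   \describe{
#'     \item{kept}{data.frame of surviving visits}
#'     \item{removal_log}{list: per-visit `flags` data.frame
#'       (`visit_id`, `duration_fail`, `tide_fail`, `removed`), counts
#'       `n_duration_only`, `n_tide_only`, `n_both`, removed visit ids,
#'       `removed_sites` (sites losing every visit), `n_sites_removed`,
#'       `n_sites_kept`}
#'   }
#' @export
apply_exclusion_filters <- function(visits, min_duration = 15, max_tide = 0.83) {
  stop_if_not(is.data.frame(visits) && nrow(visits) >= 1,
              "visits must be a nonempty data.frame")
  stop_if_not(min_duration > 0 && max_tide > 0, "thresholds must be positive")
  if (is.null(visits$visit_id)) {
    visits$visit_id <- sprintf("V%04d", seq_len(nrow(visits)))
  }
  duration_fail <- visits$search_minutes < min_duration
  tide_fail <- pmax(visits$tide_start_m, visits$tide_end_m) > max_tide
  removed <- duration_fail | tide_fail
  flags <- data.frame(visit_id = visits$visit_id,
                      site_id = visits$site_id,
                      duration_fail = duration_fail,
                      tide_fail = tide_fail,
                      removed = removed,
                      stringsAsFactors = FALSE)
  all_sites <- unique(visits$site_id)
  kept_sites <- unique(visits$site_id[!removed])
  removed_sites <- setdiff(all_sites, kept_sites)
  log <- list(
    flags = flags,
    n_visits = nrow(visits),
    n_visits_removed = sum(removed),
    n_duration_only = sum(duration_fail & !tide_fail),
    n_tide_only = sum(tide_fail & !duration_fail),
    n_both = sum(duration_fail & tide_fail),
    removed_visit_ids = visits$visit_id[removed],
    removed_sites = removed_sites,
    n_sites_removed = length(removed_sites),
    n_sites_kept = length(kept_sites),
    min_duration = min_duration,
    max_tide = max_tide
  )
  structure(list(kept = visits[!removed, , drop = FALSE], removal_log = log),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  l <- x$removal_log
  cat(sprintf(paste0(
    "QC filter (< %g min or > %g m tide):\n",
    "  visits: %d in, %d removed (%d duration-only, %d tide-only, %d both)\n",
    "  sites:  %d removed entirely, %d kept\n"),
    l$min_duration, l$max_tide, l$n_visits, l$n_visits_removed,
    l$n_duration_only, l$n_tide_only, l$n_both,
    l$n_sites_removed, l$n_sites_kept))
  invisible(x)
}

#' Per-observer site abundance table
#'
#' Aggregates kept visits to one CPUE per (species, observer, site),
#' pooling multiple visits by the same observer to the same site as the
#' ratio of summed counts to summed minutes — i.e. effort-weighted, and
#' invariant to splitting a search into sub-visits.
#'
#' @param kept_visits Nonempty data.frame of visits that passed QC.
#' @return A data.frame of class `site_abundance` with columns `species`,
#'   `observer_id`, `site_id`, `alongshore_km`, `n_visits`,
#'   `total_count`, `total_minutes`, `cpue`.
#' @seealso [site_mean_cpue()] for the per-site across-observer mean used
#'   by the co-occurrence and habitat-window analyses.
#' @export
site_abundance_table <- function(kept_visits) {
  stop_if_not(is.data.frame(kept_visits) && nrow(kept_visits) >= 1,
              "kept_visits must be a nonempty data.frame")
  species <- visit_species(kept_visits)
  stop_if_not(length(species) >= 1, "no count_<species> columns found")
  pieces <- lapply(species, function(sp) {
    cc <- kept_visits[[paste0("count_", sp)]]
    key <- interaction(kept_visits$observer_id, kept_visits$site_id, drop = TRUE)
    agg <- data.frame(
      observer_id = tapply(kept_visits$observer_id, key, `[`, 1),
      site_id = tapply(kept_visits$site_id, key, `[`, 1),
      alongshore_km = as.numeric(tapply(kept_visits$alongshore_km, key, `[`, 1)),
      n_visits = as.integer(tapply(cc, key, length)),
      total_count = as.numeric(tapply(cc, key, sum)),
      total_minutes = as.numeric(tapply(kept_visits$search_minutes, key, sum)),
      stringsAsFactors = FALSE
    )
    agg$species <- sp
    agg
  })
  out <- do.call(rbind, pieces)
  out$cpue <- compute_cpue(out$total_count, out$total_minutes)
  out <- out[order(out$species, out$observer_id, out$alongshore_km),
             c("species", "observer_id", "site_id", "alongshore_km",
               "n_visits", "total_count", "total_minutes", "cpue")]
  rownames(out) <- NULL
  class(out) <- c("site_abundance", "data.frame")
  out
}

#' Per-site mean CPUE across observers
#'
#' @param site_table A `site_abundance` table.
#' @return data.frame `species`, `site_id`, `alongshore_km`, `n_observers`,
#'   `mean_cpue` — the unweighted mean across observers who surveyed the
#'   site.
#' @export
site_mean_cpue <- function(site_table) {
  stop_if_not(is.data.frame(site_table) && nrow(site_table) >= 1,
              "site_table must be a nonempty data.frame")
  key <- interaction(site_table$species, site_table$site_id, drop = TRUE)
  out <- data.frame(
    species = tapply(site_table$species, key, `[`, 1),
    site_id = tapply(site_table$site_id, key, `[`, 1),
    alongshore_km = as.numeric(tapply(site_table$alongshore_km, key, `[`, 1)),
    n_observers = as.integer(tapply(site_table$cpue, key, length)),
    mean_cpue = as.numeric(tapply(site_table$cpue, key, mean)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$species, out$alongshore_km), ]
  rownames(out) <- NULL
  out
}

#' Observer concordance over shared sites
#'
#' For every observer pair and species, correlates the two observers' CPUE
#' across the sites both surveyed, provided they share at least
#' `min_shared_sites` sites (pairs below the threshold are skipped with a
#' message). Low concordance is the signal to analyse observers
#' separately downstream.
#'
#' @param site_table A `site_abundance` table.
#' @param min_shared_sites Minimum shared sites for a pair to be evaluated
#'   (default 3).
#' @return data.frame `species`, `observer_a`, `observer_b`, `n_shared`,
#'   `rho`, `p_value` (one row per evaluated pair x species).
#' @export
observer_concordance <- function(site_table, min_shared_sites = 3) {
  stop_if_not(min_shared_sites >= 3, "min_shared_sites must be >= 3")
  rows <- list()
  for (sp in unique(site_table$species)) {
    tab <- site_table[site_table$species == sp, ]
    obs <- sort(unique(tab$observer_id))
    if (length(obs) < 2) next
    for (i in seq_len(length(obs) - 1)) {
      for (j in seq((i + 1), length(obs))) {
        a <- tab[tab$observer_id == obs[i], ]
        b <- tab[tab$observer_id == obs[j], ]
        shared <- intersect(a$site_id, b$site_id)
        if (length(shared) < min_shared_sites) {
          message(sprintf(
            "observer_concordance: %s / %s share %d site(s) for %s (< %d); skipped",
            obs[i], obs[j], length(shared), sp, min_shared_sites))
          next
        }
        va <- a$cpue[match(shared, a$site_id)]
        vb <- b$cpue[match(shared, b$site_id)]
        r <- spearman_rho(va, vb)
        rows[[length(rows) + 1]] <- data.frame(
          species = sp, observer_a = obs[i], observer_b = obs[j],
          n_shared = length(shared), rho = r$rho, p_value = r$p_value,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(species = character(), observer_a = character(),
                      observer_b = character(), n_shared = integer(),
                      rho = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
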
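# Upstream/downstream habitat-window correlation scan.
#
# The amount of rocky habitat within a sliding along-shore window up- or
# down-stream of each site (relative to the prevailing current) is
# correlated with site abundance across a ladder of window sizes, with
# Benjamini-Hochberg false-discovery control within each
# (species, observer, direction) family of windows. Upstream habitat acts
# as a proxy for larval source populations.

#' Window-size ladder for the habitat scan
#'
#' @param min_km,max_km,step_km Bounds and step of the arithmetic ladder
#'   (defaults 5, 140, 5 — i.e. 28 windows per direction).
#' @return Numeric vector of window sizes.
#' @examples
#' length(window_sizes())  # 28
#' @export
window_sizes <- function(min_km = 5, max_km = 140, step_km = 5) {
  stop_if_not(step_km > 0, "step_km must be positive")
  stop_if_not(min_km > 0 && min_km <= max_km,
              "need 0 < min_km <= max_km")
  seq(min_km, max_km, by = step_km)
}

#' Amount of rocky habitat within a directional window of a site
#'
#' Sums the rocky indicator over the `window_km` whole-km cells adjacent
#' to the site's cell in the requested direction, where "upstream" is the
#' direction given by the map's `upstream_sign` at the site's own cell
#' (and "downstream" its opposite). The site's own cell is excluded — the
#' window measures neighbouring habitat, not the site's own shore.
#' Windows overrunning a map edge are truncated, and the truncated length
#' is reported via the `"truncated_km"` attribute for auditing.
#'
#' @param map A `coast_map`.
#' @param site_km Along-shore site position(s), in \[0, length_km\].
#' @param direction `"upstream"` or `"downstream"`.
#' @param window_km Window length (km, > 0).
#' @return Numeric vector of rocky km within the window for each site,
#'   with attribute `truncated_km` (km of window lost to the map edge).
#' @export
habitat_amount <- function(map, site_km, direction = c("upstream", "downstream"),
                           window_km) {
  direction <- match.arg(direction)
  stop_if_not(inherits(map, "coast_map"), "map must be a coast_map")
  stop_if_not(window_km > 0, "window_km must be positive")
  stop_if_not(all(site_km >= 0) && all(site_km <= map$length_km),
              "site position outside the map")
  L <- map$length_km
  w <- as.integer(round(window_km))
  cs <- c(0, cumsum(map$rocky))
  cell <- pmin(pmax(floor(site_km) + 1L, 1L), L)   # 1-based cell index
  sgn <- map$upstream_sign[cell]
  if (direction == "downstream") sgn <- -sgn
  # window cells: cell+1 .. cell+w when sgn = +1, cell-w .. cell-1 when -1
  a <- ifelse(sgn > 0, cell + 1L, cell - w)
  b <- ifelse(sgn > 0, cell + w, cell - 1L)
  a_cl <- pmax(a, 1L); b_cl <- pmin(b, L)
  amount <- ifelse(b_cl >= a_cl, cs[b_cl + 1L] - cs[a_cl], 0)
  truncated <- (a_cl - a) + (b - b_cl)
  attr(amount, "truncated_km") <- as.numeric(truncated)
  amount
}

#' Scan window sizes for abundance-habitat correlations
#'
#' For every species, observer, direction and window size, computes the
#' Spearman correlation between per-site CPUE and the amount of rocky
#' habitat in that window, over the sites falling inside the species'
#' distributional range. BH adjustment is applied within each
#' (species, observer, direction) family of window sizes. Families with
#' fewer than 3 usable sites are skipped with a message.
#'
#' @param site_table A `site_abundance` table (per-observer CPUE). Any
#'   table with columns `species`, `observer_id`, `site_id`,
#'   `alongshore_km`, `cpue` works, so site-mean tables can be scanned by
#'   setting `observer_id` to a constant label.
#' @param map A `coast_map`.
#' @param windows Window ladder (default [window_sizes()]).
#' @param alpha FDR level for the BH adjustment (default 0.05).
#' @param ranges Optional named list `species -> c(lo_km, hi_km)`
#'   overriding the detection-based pooled range (e.g. to restrict to a
#'   biogeographic province).
#' @return data.frame with one row per (species, observer, direction,
#'   window): `species`, `observer_id`, `direction`, `window_km`,
#'   `n_sites`, `rho`, `p_value`, `p_adjusted`, `significant`,
#'   `mean_truncated_frac`.
#' @export
window_correlation_scan <- function(site_table, map,
                                    windows = window_sizes(),
                                    alpha = 0.05,
                                    ranges = NULL) {
  stop_if_not(inherits(map, "coast_map"), "map must be a coast_map")
  stop_if_not(is.data.frame(site_table) && nrow(site_table) >= 1,
              "site_table must be a nonempty data.frame")
  pooled_ranges <- species_range(site_table)
  rows <- list()
  for (sp in unique(site_table$species)) {
    if (!is.null(ranges) && !is.null(ranges[[sp]])) {
      rng <- ranges[[sp]]
    } else {
      pr <- pooled_ranges[pooled_ranges$species == sp &
                            pooled_ranges$observer == "pooled", ]
      if (!pr$detected) {
        message(sprintf("window scan: '%s' never detected; skipped", sp))
        next
      }
      rng <- c(pr$lo_km, pr$hi_km)
    }
    tab_sp <- site_table[site_table$species == sp &
                           site_table$alongshore_km >= rng[1] &
                           site_table$alongshore_km <= rng[2], ]
    for (obs in sort(unique(tab_sp$observer_id))) {
      tab <- tab_sp[tab_sp$observer_id == obs, ]
      if (nrow(tab) < 3) {
        message(sprintf(
          "window scan: %s / %s has %d site(s) in range (< 3); family skipped",
          sp, obs, nrow(tab)))
        next
      }
      for (dir in c("downstream", "upstream")) {
        fam <- lapply(windows, function(w) {
          amt <- habitat_amount(map, tab$alongshore_km, dir, w)
          r <- spearman_rho(tab$cpue, as.numeric(amt))
          data.frame(species = sp, observer_id = obs, direction = dir,
                     window_km = w, n_sites = nrow(tab),
                     rho = r$rho, p_value = r$p_value,
                     mean_truncated_frac = mean(attr(amt, "truncated_km")) / w,
                     stringsAsFactors = FALSE)
        })
        fam <- do.call(rbind, fam)
        if (all(is.na(fam$p_value))) {
          fam$p_adjusted <- NA_real_
          fam$significant <- FALSE
        } else {
          usable <- !is.na(fam$p_value)
          adj <- bh_adjust(fam$p_value[usable], alpha = alpha)
          fam$p_adjusted <- NA_real_
          fam$significant <- FALSE
          fam$p_adjusted[usable] <- adj$p_adjusted
          fam$significant[usable] <- adj$reject
        }
        rows[[length(rows) + 1]] <- fam
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(species = character(), observer_id = character(),
                      direction = character(), window_km = numeric(),
                      n_sites = integer(), rho = numeric(),
                      p_value = numeric(), p_adjusted = numeric(),
                      significant = logical(),
                      mean_truncated_frac = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[, c("species", "observer_id", "direction", "window_km",
                 "n_sites", "rho", "p_value", "p_adjusted", "significant",
                 "mean_truncated_frac")]
  rownames(out) <- NULL
  out
}
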
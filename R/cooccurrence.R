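# Pairwise species co-occurrence: rank correlations of per-site mean
# abundance within the interval where all species' ranges overlap.

#' Pairwise species abundance correlations within an interval
#'
#' Restricts the per-site mean CPUE (across observers) to sites inside
#' `interval` and computes the Spearman correlation for every unordered
#' species pair. Pairs with fewer than 3 shared sites, or with a constant
#' abundance vector (e.g. a species never detected inside the interval),
#' are marked not computed (`NA`).
#'
#' @param site_table A `site_abundance` table.
#' @param interval The interval to restrict to: a [sympatric_interval()]
#'   result or a length-2 numeric `c(lo_km, hi_km)`.
#' @return Object of class `pairwise_matrix`: list with `species`, `rho`
#'   and `p_value` matrices (symmetric, `NA` diagonal), `n` matrix of
#'   shared-site counts, and a tidy `pairs` data.frame (`species_a`,
#'   `species_b`, `n_sites`, `rho`, `p_value`).
#' @examples
#' # four species yield choose(4, 2) = 6 pairs
#' @export
pairwise_species_correlations <- function(site_table, interval) {
  if (is.list(interval) && !is.null(interval$lo_km)) {
    stop_if_not(!isTRUE(interval$empty), "interval is empty")
    lo <- interval$lo_km; hi <- interval$hi_km
  } else {
    stop_if_not(length(interval) == 2 && interval[1] <= interval[2],
                "interval must be c(lo, hi)")
    lo <- interval[1]; hi <- interval[2]
  }
  means <- site_mean_cpue(site_table)
  means <- means[means$alongshore_km >= lo & means$alongshore_km <= hi, ]
  stop_if_not(nrow(means) >= 1, "no sites inside the interval")
  species <- sort(unique(means$species))
  k <- length(species)
  stop_if_not(k >= 2, "need at least 2 species")
  rho_m <- matrix(NA_real_, k, k, dimnames = list(species, species))
  p_m <- rho_m
  n_m <- matrix(0L, k, k, dimnames = list(species, species))
  pairs <- list()
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      a <- means[means$species == species[i], ]
      b <- means[means$species == species[j], ]
      shared <- intersect(a$site_id, b$site_id)
      n_m[i, j] <- n_m[j, i] <- length(shared)
      rho <- NA_real_; p <- NA_real_
      if (length(shared) >= 3) {
        va <- a$mean_cpue[match(shared, a$site_id)]
        vb <- b$mean_cpue[match(shared, b$site_id)]
        r <- spearman_rho(va, vb)
        if (!r$degenerate) {
          rho <- r$rho; p <- r$p_value
        }
      }
      rho_m[i, j] <- rho_m[j, i] <- rho
      p_m[i, j] <- p_m[j, i] <- p
      pairs[[length(pairs) + 1]] <- data.frame(
        species_a = species[i], species_b = species[j],
        n_sites = length(shared), rho = rho, p_value = p,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(species = species, rho = rho_m, p_value = p_m, n = n_m,
                 pairs = do.call(rbind, pairs),
                 interval = c(lo_km = lo, hi_km = hi)),
            class = "pairwise_matrix")
}

#' @export
print.pairwise_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("Pairwise abundance correlations within [%.0f, %.0f] km:\n",
              x$interval["lo_km"], x$interval["hi_km"]))
  stars <- function(p) {
    if (is.na(p)) return("")
    if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else " n.s."
  }
  disp <- x$rho
  txt <- matrix("", nrow(disp), ncol(disp), dimnames = dimnames(disp))
  for (i in seq_len(nrow(disp))) {
    for (j in seq_len(ncol(disp))) {
      if (i == j) { txt[i, j] <- "-"; next }
      if (is.na(disp[i, j])) { txt[i, j] <- "n.c."; next }
      txt[i, j] <- paste0(format(round(disp[i, j], digits)),
                          stars(x$p_value[i, j]))
    }
  }
  print(txt, quote = FALSE)
  invisible(x)
}
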
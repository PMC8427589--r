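# Coastline geometry: projecting planar site coordinates onto a coastal
# polyline to obtain 1-D along-shore distances, and deriving species
# ranges and the sympatric interval from detection positions.

#' Build a coastline polyline with cumulative arc length
#'
#' @param x,y Planar coordinates (km) of at least two ordered vertices.
#' @return Object of class `coast_polyline`: data.frame `x`, `y`,
#'   `arc_km` (cumulative arc length, starting at 0).
#' @export
coast_polyline <- function(x, y) {
  stop_if_not(length(x) == length(y) && length(x) >= 2,
              "polyline needs >= 2 (x, y) vertices")
  stop_if_not(all(is.finite(x)) && all(is.finite(y)),
              "vertices must be finite")
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  stop_if_not(all(seg > 0), "consecutive vertices must be distinct")
  out <- data.frame(x = x, y = y, arc_km = c(0, cumsum(seg)))
  class(out) <- c("coast_polyline", "data.frame")
  out
}

#' Equirectangular projection of lon/lat to planar km
#'
#' Adequate for along-shore distance work at the few-thousand-km scale:
#' longitudes are scaled by the cosine of the mean latitude of the input,
#' so east-west distances are correct near the coastline's latitude band.
#'
#' @param lon,lat Coordinates in decimal degrees.
#' @param lat0 Reference latitude (degrees); defaults to `mean(lat)`.
#' @return data.frame `x`, `y` in km.
#' @export
lonlat_to_xy <- function(lon, lat, lat0 = mean(lat)) {
  r_earth <- 6371
  data.frame(x = r_earth * cos(lat0 * pi / 180) * lon * pi / 180,
             y = r_earth * lat * pi / 180)
}

#' Project points onto a coastline polyline
#'
#' Each point is snapped to its nearest point on the polyline and assigned
#' the cumulative arc length there (km). When a point is equidistant from
#' two parts of the polyline the smaller arc length wins, so the mapping
#' is deterministic. Points already on the polyline map to their own arc
#' position (idempotence).
#'
#' @param points data.frame or matrix with columns `x`, `y` (km).
#' @param polyline A [coast_polyline()].
#' @param snap_tol_km Maximum allowed point-to-polyline distance; farther
#'   points raise an error (default `Inf`).
#' @return Numeric vector of along-shore positions (km).
#' @export
alongshore_project <- function(points, polyline, snap_tol_km = Inf) {
  stop_if_not(inherits(polyline, "coast_polyline"),
              "polyline must come from coast_polyline()")
  pts <- as.data.frame(points)
  stop_if_not(all(c("x", "y") %in% names(pts)),
              "points must have columns x and y")
  stop_if_not(all(is.finite(pts$x)) && all(is.finite(pts$y)),
              "points must be finite")
  vx <- polyline$x; vy <- polyline$y; arc <- polyline$arc_km
  ax <- vx[-length(vx)]; ay <- vy[-length(vy)]
  bx <- vx[-1]; by <- vy[-1]
  dx <- bx - ax; dy <- by - ay
  len2 <- dx^2 + dy^2
  n <- nrow(pts)
  pos <- numeric(n)
  for (i in seq_len(n)) {
    px <- pts$x[i]; py <- pts$y[i]
    t <- ((px - ax) * dx + (py - ay) * dy) / len2
    t <- pmin(pmax(t, 0), 1)
    qx <- ax + t * dx; qy <- ay + t * dy
    d2 <- (px - qx)^2 + (py - qy)^2
    cand_pos <- arc[-length(arc)] + t * sqrt(len2)
    best_d2 <- min(d2)
    if (sqrt(best_d2) > snap_tol_km) {
      stop(sprintf("point %d is %.2f km from the polyline (tolerance %.2f km)",
                   i, sqrt(best_d2), snap_tol_km), call. = FALSE)
    }
    # ties (within numerical noise) resolve to the smallest arc position
    tied <- which(d2 <= best_d2 + 1e-12)
    pos[i] <- min(cand_pos[tied])
  }
  pos
}

#' Species distributional ranges from detection positions
#'
#' The range of a species is the along-shore interval between its most
#' extreme sites with nonzero CPUE. Computed per observer and pooled over
#' observers; species never detected are flagged as absent.
#'
#' @param site_table A `site_abundance` table.
#' @return data.frame `species`, `observer` (`"pooled"` plus each
#'   observer id), `detected`, `n_detection_sites`, `lo_km`, `hi_km`,
#'   `extent_km` (NA when absent).
#' @export
species_range <- function(site_table) {
  stop_if_not(is.data.frame(site_table) && nrow(site_table) >= 1,
              "site_table must be a nonempty data.frame")
  one <- function(sp, obs_label, tab) {
    det <- tab[tab$cpue > 0, ]
    if (nrow(det) == 0) {
      data.frame(species = sp, observer = obs_label, detected = FALSE,
                 n_detection_sites = 0L, lo_km = NA_real_, hi_km = NA_real_,
                 extent_km = NA_real_, stringsAsFactors = FALSE)
    } else {
      lo <- min(det$alongshore_km); hi <- max(det$alongshore_km)
      data.frame(species = sp, observer = obs_label, detected = TRUE,
                 n_detection_sites = length(unique(det$site_id)),
                 lo_km = lo, hi_km = hi, extent_km = hi - lo,
                 stringsAsFactors = FALSE)
    }
  }
  rows <- list()
  for (sp in unique(site_table$species)) {
    tab <- site_table[site_table$species == sp, ]
    rows[[length(rows) + 1]] <- one(sp, "pooled", tab)
    for (obs in sort(unique(tab$observer_id))) {
      rows[[length(rows) + 1]] <- one(sp, obs, tab[tab$observer_id == obs, ])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Interval where all species ranges overlap (sympatric range)
#'
#' @param ranges Either the data.frame from [species_range()] (its pooled
#'   rows are used) or a list of length-2 numeric `c(lo, hi)` intervals.
#' @return List `lo_km`, `hi_km`, `length_km`, `empty`. When the
#'   intersection is empty, `empty = TRUE` and the bounds are `NA`.
#' @examples
#' sympatric_interval(list(c(0, 10), c(5, 20)))  # [5, 10]
#' @export
sympatric_interval <- function(ranges) {
  if (is.data.frame(ranges)) {
    pooled <- ranges[ranges$observer == "pooled" & ranges$detected, ]
    stop_if_not(nrow(pooled) >= 2, "need >= 2 detected species ranges")
    los <- pooled$lo_km; his <- pooled$hi_km
  } else {
    stop_if_not(is.list(ranges) && length(ranges) >= 2, "need >= 2 ranges")
    los <- vapply(ranges, `[`, 0, 1)
    his <- vapply(ranges, `[`, 0, 2)
  }
  stop_if_not(all(los <= his), "each range must satisfy lo <= hi")
  lo <- max(los); hi <- min(his)
  if (lo > hi) {
    list(lo_km = NA_real_, hi_km = NA_real_, length_km = 0, empty = TRUE)
  } else {
    list(lo_km = lo, hi_km = hi, length_km = hi - lo, empty = FALSE)
  }
}
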
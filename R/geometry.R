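#' Length of a survey route polyline
#'
#' Sums great-circle (haversine) segment lengths along an ordered set of
#' WGS84 points, using the mean Earth radius 6371.0088 km. Routes longer
#' than 20 km trigger a protocol warning (surveys are designed to take at
#' most about two hours, roughly 20 km by car or motorcycle); the length
#' is still returned.
#'
#' @param polyline two-column matrix or data frame of latitude and
#'   longitude in decimal degrees, one row per vertex, in traversal
#'   order. Column names `lat`/`lon` are used when present, otherwise
#'   the first column is taken as latitude.
#' @param warn_protocol if `TRUE` (default), warn when the total exceeds
#'   the 20 km protocol guideline.
#' @return length in kilometres (0 for a single point).
#' @examples
#' route_length_km(cbind(lat = c(0, 0), lon = c(0, 0.01)))
#' @export
route_length_km <- function(polyline, warn_protocol = TRUE) {
  pl <- as_polyline(polyline)
  n <- nrow(pl)
  if (n < 2) return(0)
  p <- cbind(pl[, "lon"], pl[, "lat"])
  seg <- geosphere::distHaversine(p[-n, , drop = FALSE], p[-1, , drop = FALSE],
                                  r = EARTH_RADIUS_KM * 1000)
  total <- sum(seg) / 1000
  if (warn_protocol && total > 20 + 1e-6) {
    warning(sprintf(
      "route length %.2f km exceeds the 20 km protocol guideline (~2 h survey)",
      total
    ), call. = FALSE)
  }
  total
}

# Validate and normalise a polyline to a matrix with lat/lon columns.
as_polyline <- function(polyline) {
  pl <- as.matrix(polyline)
  if (!is.numeric(pl) || ncol(pl) < 2) {
    stop("polyline must be a numeric matrix/data frame with lat and lon columns",
         call. = FALSE)
  }
  cn <- tolower(colnames(pl))
  if (!is.null(colnames(pl)) && all(c("lat", "lon") %in% cn)) {
    pl <- pl[, match(c("lat", "lon"), cn), drop = FALSE]
  } else {
    pl <- pl[, 1:2, drop = FALSE]
  }
  colnames(pl) <- c("lat", "lon")
  if (nrow(pl) < 1) stop("polyline must contain at least one point", call. = FALSE)
  bad_lat <- which(pl[, "lat"] < -90 | pl[, "lat"] > 90 | is.na(pl[, "lat"]))
  bad_lon <- which(pl[, "lon"] < -180 | pl[, "lon"] > 180 | is.na(pl[, "lon"]))
  bad <- sort(unique(c(bad_lat, bad_lon)))
  if (length(bad)) {
    stop(sprintf("coordinate out of range at point index %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  pl
}

# Point at a given distance (km) along a polyline, by linear interpolation
# over great-circle segments. Used to place simulated dogs on a route.
point_along_polyline <- function(polyline, dist_km) {
  pl <- as_polyline(polyline)
  n <- nrow(pl)
  if (n == 1) return(pl[1, ])
  p <- cbind(pl[, "lon"], pl[, "lat"])
  seg <- geosphere::distHaversine(p[-n, , drop = FALSE], p[-1, , drop = FALSE],
                                  r = EARTH_RADIUS_KM * 1000) / 1000
  cum <- c(0, cumsum(seg))
  d <- min(max(dist_km, 0), cum[n])
  i <- findInterval(d, cum, rightmost.closed = TRUE)
  i <- min(i, n - 1)
  f <- if (seg[i] > 0) (d - cum[i]) / seg[i] else 0
  c(lat = pl[i, "lat"] + f * (pl[i + 1, "lat"] - pl[i, "lat"]),
    lon = pl[i, "lon"] + f * (pl[i + 1, "lon"] - pl[i, "lon"]))
}
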
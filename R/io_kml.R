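#' Read a survey route from a KML file
#'
#' Routes are drawn in web mapping tools and exported as KML; the first
#' `LineString` in the file is taken as the route (multi-segment routes
#' must be merged before export so route identity stays unambiguous).
#' KML stores coordinates as `lon,lat[,alt]` tuples; these are converted
#' to lat/lon order.
#'
#' @param path KML file.
#' @param route_id,location,route_type metadata for the [route()].
#' @return a `dog_route`.
#' @export
read_route_kml <- function(path, route_id, location,
                           route_type = c("representative", "hotspot")) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed KML: ", conditionMessage(e), call. = FALSE)
  })
  ls <- xml2::xml_find_first(doc, ".//*[local-name()='LineString']")
  if (inherits(ls, "xml_missing")) {
    stop("no LineString found in KML file '", path, "'", call. = FALSE)
  }
  coords <- xml2::xml_find_first(ls, ".//*[local-name()='coordinates']")
  if (inherits(coords, "xml_missing")) {
    stop("LineString has no coordinates element", call. = FALSE)
  }
  txt <- trimws(xml2::xml_text(coords))
  tuples <- strsplit(txt, "\\s+")[[1]]
  tuples <- tuples[nzchar(tuples)]
  if (!length(tuples)) stop("LineString coordinates are empty", call. = FALSE)
  parts <- lapply(strsplit(tuples, ","), as.numeric)
  if (any(vapply(parts, length, integer(1)) < 2)) {
    stop("KML coordinate tuples must be lon,lat[,alt]", call. = FALSE)
  }
  lon <- vapply(parts, `[`, numeric(1), 1)
  lat <- vapply(parts, `[`, numeric(1), 2)
  route(route_id, location, match.arg(route_type), cbind(lat = lat, lon = lon))
}

#' Write a route to a KML file
#'
#' Inverse of [read_route_kml()]: a single Placemark holding one
#' LineString with `lon,lat,0` coordinate tuples.
#'
#' @param route a `dog_route`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_route_kml <- function(route, path) {
  stopifnot(inherits(route, "dog_route"))
  coords <- paste(sprintf("%.8f,%.8f,0", route$polyline[, "lon"],
                          route$polyline[, "lat"]), collapse = " ")
  doc <- xml2::xml_new_root("kml", xmlns = "http://www.opengis.net/kml/2.2")
  dm <- xml2::xml_add_child(doc, "Document")
  pm <- xml2::xml_add_child(dm, "Placemark")
  xml2::xml_add_child(pm, "name", route$route_id)
  xml2::xml_add_child(pm, "description",
                      sprintf("%s (%s route)", route$location, route$route_type))
  ls <- xml2::xml_add_child(pm, "LineString")
  xml2::xml_add_child(ls, "coordinates", coords)
  xml2::write_xml(doc, path)
  invisible(path)
}
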
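#' Default waypoint label map
#'
#' Observation apps in the OSMtracker family record one waypoint per
#' dog, with the tapped button's label as the waypoint name. The
#' default map covers the seven protocol classes; welfare is appended
#' to the base label as optional tokens: `BCS1`..`BCS5` for the body
#' condition score, and `Skin` / `NoSkin` for a visible skin condition
#' scored present / absent (no token = unrecorded). Example:
#' `"Lactating female BCS2 Skin"`. The exact button labels are a
#' package convention and can be overridden with any named character
#' vector mapping label to class.
#'
#' @return named character vector: `names()` are waypoint base labels,
#'   values are protocol classes.
#' @export
default_label_map <- function() {
  c("Male" = "male",
    "Female" = "female",
    "Lactating female" = "lactating_female",
    "Unknown adult" = "unknown_adult",
    "Pup" = "pup",
    "Sterilised male" = "sterilised_male",
    "Sterilised female" = "sterilised_female")
}

# Split a waypoint name into (class, bcs, skin); NULL if the base label
# is not in the map.
parse_dog_label <- function(name, label_map) {
  tokens <- strsplit(trimws(name), "\\s+")[[1]]
  bcs <- NA_integer_
  skin <- NA_character_
  while (length(tokens) > 1) {
    last <- tokens[length(tokens)]
    if (grepl("^BCS[1-5]$", last)) {
      bcs <- as.integer(sub("BCS", "", last))
    } else if (last == "Skin") {
      skin <- "present"
    } else if (last == "NoSkin") {
      skin <- "absent"
    } else break
    tokens <- tokens[-length(tokens)]
  }
  base <- paste(tokens, collapse = " ")
  if (!base %in% names(label_map)) return(NULL)
  list(dog_class = unname(label_map[[base]]), bcs = bcs, skin = skin)
}

# Compose the waypoint name for a record row (inverse of parse_dog_label).
make_dog_label <- function(dog_class, bcs, skin, label_map = default_label_map()) {
  base <- names(label_map)[match(as.character(dog_class), label_map)]
  out <- base
  if (!is.na(bcs)) out <- paste0(out, " BCS", bcs)
  if (!is.na(skin)) out <- paste0(out, if (skin == "present") " Skin" else " NoSkin")
  out
}

#' Read one replicate's observation log from a GPX file
#'
#' Each GPX waypoint (`wpt`) is one observed dog; the waypoint name is
#' looked up in the label map (see [default_label_map()]). Track points
#' (`trkpt`), which record the observers' actual path and speed for
#' route-adherence checks, are kept in `protocol_meta$track`.
#'
#' @param path GPX 1.1 file.
#' @param label_map named character vector mapping waypoint base labels
#'   to protocol classes.
#' @param survey_date `Date` of the replicate; waypoints timestamped on
#'   a different date are an error (guards against concatenated logs).
#'   Waypoints without a `<time>` element are assumed taken on
#'   `survey_date` (at 12:00 UTC).
#' @param route_id route the log belongs to (GPX carries no route id).
#' @return a [replicate_survey()].
#' @export
read_event_log_gpx <- function(path, label_map = default_label_map(),
                               survey_date, route_id = "unknown") {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed GPX: ", conditionMessage(e), call. = FALSE)
  })
  survey_date <- as.Date(survey_date)
  wpts <- xml2::xml_find_all(doc, ".//*[local-name()='wpt']")
  n <- length(wpts)
  lat <- lon <- numeric(n)
  cls <- skin <- character(n)
  bcs <- integer(n)
  ts <- rep(as.POSIXct(paste(survey_date, "12:00:00"), tz = "UTC"), length.out = n)
  unmapped <- character()
  for (i in seq_len(n)) {
    w <- wpts[[i]]
    la <- as.numeric(xml2::xml_attr(w, "lat"))
    lo <- as.numeric(xml2::xml_attr(w, "lon"))
    if (is.na(la) || is.na(lo)) {
      stop(sprintf("waypoint %d has no coordinates", i), call. = FALSE)
    }
    nm <- xml2::xml_text(xml2::xml_find_first(w, ".//*[local-name()='name']"))
    parsed <- parse_dog_label(nm, label_map)
    if (is.null(parsed)) {
      unmapped <- c(unmapped, nm)
      next
    }
    tnode <- xml2::xml_find_first(w, ".//*[local-name()='time']")
    if (!inherits(tnode, "xml_missing")) {
      ts[i] <- as.POSIXct(xml2::xml_text(tnode), tz = "UTC",
                          format = "%Y-%m-%dT%H:%M:%S")
    }
    lat[i] <- la; lon[i] <- lo
    cls[i] <- parsed$dog_class; bcs[i] <- parsed$bcs; skin[i] <- parsed$skin
  }
  if (length(unmapped)) {
    stop("waypoint label(s) not in label map: ",
         paste(sQuote(unique(unmapped)), collapse = ", "), call. = FALSE)
  }
  records <- dog_records(timestamp = ts, lat = lat, lon = lon, dog_class = cls,
                         bcs = bcs, skin = skin)
  meta <- list()
  trk <- xml2::xml_find_all(doc, ".//*[local-name()='trkpt']")
  if (length(trk)) {
    meta$track <- data.frame(
      lat = as.numeric(xml2::xml_attr(trk, "lat")),
      lon = as.numeric(xml2::xml_attr(trk, "lon"))
    )
  }
  replicate_survey(route_id, survey_date, records, meta)
}

#' Write one replicate's observations as a GPX file
#'
#' Inverse of [read_event_log_gpx()]: one `wpt` per dog, named with the
#' label-map grammar, with ISO timestamps.
#'
#' @param survey a `replicate_survey`.
#' @param path output file.
#' @param label_map label map used to compose waypoint names.
#' @return `path`, invisibly.
#' @export
write_event_log_gpx <- function(survey, path, label_map = default_label_map()) {
  stopifnot(inherits(survey, "replicate_survey"))
  doc <- xml2::xml_new_root("gpx", version = "1.1", creator = "streetcount",
                            xmlns = "http://www.topografix.com/GPX/1/1")
  rec <- survey$records
  for (i in seq_len(nrow(rec))) {
    w <- xml2::xml_add_child(doc, "wpt",
                             lat = sprintf("%.8f", rec$lat[i]),
                             lon = sprintf("%.8f", rec$lon[i]))
    xml2::xml_add_child(w, "time",
                        format(rec$timestamp[i], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
    xml2::xml_add_child(w, "name",
                        make_dog_label(rec$dog_class[i], rec$bcs[i],
                                       as.character(rec$skin[i]), label_map))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
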
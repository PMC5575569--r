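#' Construct a survey route
#'
#' A route is a named polyline along public streets, fixed once and
#' re-surveyed identically on every occasion. `route_type`
#' distinguishes "representative" routes (drawn blind to expected dog
#' density; valid for extrapolation to area totals) from "hotspot"
#' routes (drawn through reported high-density areas; valid only for
#' within-route trends).
#'
#' @param route_id unique route identifier.
#' @param location name of the city/region the route belongs to.
#' @param route_type `"representative"` or `"hotspot"`.
#' @param polyline ordered lat/lon vertices (see [route_length_km()]);
#'   at least two points.
#' @return an object of class `dog_route` with fields `route_id`,
#'   `location`, `route_type`, `polyline` and derived `length_km`.
#' @export
route <- function(route_id, location, route_type = c("representative", "hotspot"),
                  polyline) {
  route_type <- match.arg(route_type)
  pl <- as_polyline(polyline)
  if (nrow(pl) < 2) stop("a route polyline needs at least two points", call. = FALSE)
  len <- route_length_km(pl)
  if (len <= 0) stop("route has zero length", call. = FALSE)
  structure(
    list(route_id = as.character(route_id), location = as.character(location),
         route_type = route_type, polyline = pl, length_km = len),
    class = "dog_route"
  )
}

#' @export
print.dog_route <- function(x, ...) {
  cat(sprintf("<route '%s'> %s (%s), %.2f km, %d vertices\n",
              x$route_id, x$location, x$route_type, x$length_km,
              nrow(x$polyline)))
  invisible(x)
}

#' Build a table of individual dog observations
#'
#' Each observed dog carries its protocol class (gender/age, including
#' sterilisation-marked classes where marking is used), an optional
#' 5-point body condition score (1 = emaciated, 2 = thin), an optional
#' visible-skin-condition flag, and the observer's GPS position and time
#' at the moment of recording. `NA` in `bcs` or `skin` means
#' "unrecorded" (e.g. abbreviated protocols that only score emaciated
#' dogs).
#'
#' @param timestamp POSIXct (UTC) observation times.
#' @param lat,lon observer position, WGS84 decimal degrees.
#' @param dog_class one of `r paste(DOG_CLASSES, collapse = ", ")`.
#' @param bcs integer 1-5 or `NA`.
#' @param skin `"present"`, `"absent"` or `NA`.
#' @return a tibble with one row per dog.
#' @export
dog_records <- function(timestamp = as.POSIXct(character(), tz = "UTC"),
                        lat = numeric(), lon = numeric(),
                        dog_class = character(), bcs = NA_integer_,
                        skin = NA_character_) {
  n <- length(dog_class)
  bcs <- rep_len(as.integer(bcs), n)
  skin <- rep_len(as.character(skin), n)
  dog_class <- as.character(dog_class)
  bad <- setdiff(unique(dog_class), DOG_CLASSES)
  if (length(bad)) {
    stop("unknown dog class: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(!is.na(bcs) & !(bcs %in% 1:5))) {
    stop("bcs must be 1-5 or NA", call. = FALSE)
  }
  if (any(!is.na(skin) & !(skin %in% c("present", "absent")))) {
    stop("skin must be 'present', 'absent' or NA", call. = FALSE)
  }
  tibble::tibble(
    timestamp = as.POSIXct(timestamp, tz = "UTC"),
    lat = rep_len(as.numeric(lat), n), lon = rep_len(as.numeric(lon), n),
    dog_class = factor(dog_class, levels = DOG_CLASSES),
    bcs = bcs,
    skin = factor(skin, levels = c("present", "absent"))
  )
}

#' Construct one replicate survey of a route
#'
#' A replicate is a single pass along a route on one day. The protocol
#' requires at least two replicates on consecutive days per survey
#' event, so that day-to-day variation can be measured.
#'
#' @param route_id route surveyed.
#' @param survey_date `Date` of the replicate.
#' @param records a [dog_records()] tibble (may have zero rows).
#' @param protocol_meta free-form list (start time, transport mode,
#'   observers, GPX track points, ...).
#' @return an object of class `replicate_survey`.
#' @export
replicate_survey <- function(route_id, survey_date, records = dog_records(),
                             protocol_meta = list()) {
  survey_date <- as.Date(survey_date)
  if (length(survey_date) != 1 || is.na(survey_date)) {
    stop("survey_date must be a single date", call. = FALSE)
  }
  stopifnot(is.data.frame(records))
  if (nrow(records)) {
    rec_date <- as.Date(records$timestamp, tz = "UTC")
    off <- which(!is.na(rec_date) & rec_date != survey_date)
    if (length(off)) {
      stop(sprintf(
        "%d record(s) fall outside survey_date %s (first at row %d); refusing concatenated logs",
        length(off), format(survey_date), off[1]
      ), call. = FALSE)
    }
  }
  structure(
    list(route_id = as.character(route_id), survey_date = survey_date,
         records = records, protocol_meta = protocol_meta),
    class = "replicate_survey"
  )
}

#' @export
print.replicate_survey <- function(x, ...) {
  cat(sprintf("<replicate survey> route '%s' on %s: %d dogs\n",
              x$route_id, format(x$survey_date), nrow(x$records)))
  invisible(x)
}

#' Construct a survey event (a set of replicates of one route)
#'
#' One monitoring time point for one route: the same route surveyed on
#' two or more (usually consecutive) days under the same protocol.
#'
#' @param route_id route surveyed; all replicates must agree.
#' @param event_label label for the monitoring occasion (e.g. `"2016-06"`).
#' @param replicates list of [replicate_survey()] objects with distinct
#'   dates.
#' @return an object of class `survey_event`.
#' @export
survey_event <- function(route_id, event_label, replicates) {
  if (!length(replicates)) stop("a survey event needs at least one replicate", call. = FALSE)
  ids <- vapply(replicates, function(r) r$route_id, character(1))
  if (!all(ids == as.character(route_id))) {
    stop("all replicates must share the event's route_id", call. = FALSE)
  }
  dates <- as.Date(vapply(replicates, function(r) format(r$survey_date), character(1)))
  if (anyDuplicated(dates)) stop("replicate dates must be distinct", call. = FALSE)
  replicates <- replicates[order(dates)]
  structure(
    list(route_id = as.character(route_id), event_label = as.character(event_label),
         replicates = replicates),
    class = "survey_event"
  )
}

#' @export
print.survey_event <- function(x, ...) {
  cat(sprintf("<survey event '%s'> route '%s', %d replicate(s)\n",
              x$event_label, x$route_id, length(x$replicates)))
  invisible(x)
}

# Pool the record tables of all replicates of an event.
pooled_records <- function(event) {
  do.call(rbind, lapply(event$replicates, function(r) r$records))
}
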
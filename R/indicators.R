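#' Dogs seen per kilometre on one replicate survey
#'
#' The core relative-abundance index: number of dogs recorded divided
#' by route length. Under a constant protocol (constant detectability)
#' changes in this index track changes in roaming-dog density.
#'
#' @param replicate a [replicate_survey()].
#' @param route the surveyed `dog_route`; ids must match.
#' @return dogs per km (>= 0).
#' @export
dogs_per_km <- function(replicate, route) {
  stopifnot(inherits(replicate, "replicate_survey"), inherits(route, "dog_route"))
  if (replicate$route_id != route$route_id) {
    stop(sprintf("replicate is for route '%s', not '%s'",
                 replicate$route_id, route$route_id), call. = FALSE)
  }
  if (route$length_km <= 0) stop("route length must be positive", call. = FALSE)
  nrow(replicate$records) / route$length_km
}

#' Event-average density
#'
#' The per-route density reported for a survey event is the arithmetic
#' mean of its replicates' dogs-per-km values (two or more consecutive
#' days).
#'
#' @param event a [survey_event()].
#' @param route the surveyed `dog_route`.
#' @return mean dogs per km over the event's replicates.
#' @export
event_density <- function(event, route) {
  stopifnot(inherits(event, "survey_event"))
  if (!length(event$replicates)) stop("event has no replicates", call. = FALSE)
  mean(vapply(event$replicates, dogs_per_km, numeric(1), route = route))
}

#' Composition and welfare indicators for a set of observations
#'
#' Computes the percentage indicators over a record table:
#' \describe{
#'   \item{pct_lactating}{lactating females as a percentage of all
#'     identified females. The female denominator includes sterilised
#'     females when `females_include_sterilised` is `TRUE` (default);
#'     pups and unknown adults are never females.}
#'   \item{pct_bcs1, pct_bcs1or2}{emaciated (BCS 1) and emaciated-or-thin
#'     (BCS 1 or 2) dogs as a percentage of BCS-scored dogs.}
#'   \item{pct_skin}{dogs with a visible skin condition as a percentage
#'     of skin-assessed dogs.}
#' }
#' A zero denominator makes the corresponding percentage `NA`
#' (undefined — not 0), and `NA` propagates into downstream tests as a
#' missing value.
#'
#' @param records a [dog_records()] tibble.
#' @param females_include_sterilised whether sterilised females count in
#'   the female denominator.
#' @return one-row tibble with counts (`n_dogs`, `n_females`,
#'   `n_lactating`, `n_bcs_scored`, `n_skin_assessed`) and percentages.
#' @export
composition <- function(records, females_include_sterilised = TRUE) {
  cls <- as.character(records$dog_class)
  fem_classes <- if (females_include_sterilised) FEMALE_CLASSES else
    c("female", "lactating_female")
  n_dogs <- length(cls)
  n_fem <- sum(cls %in% fem_classes)
  n_lact <- sum(cls == "lactating_female")
  bcs <- records$bcs[!is.na(records$bcs)]
  n_bcs <- length(bcs)
  skin <- records$skin[!is.na(records$skin)]
  n_skin <- length(skin)
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  tibble::tibble(
    n_dogs = n_dogs, n_females = n_fem, n_lactating = n_lact,
    n_bcs_scored = n_bcs, n_skin_assessed = n_skin,
    pct_lactating = pct(n_lact, n_fem),
    pct_bcs1 = pct(sum(bcs == 1), n_bcs),
    pct_bcs1or2 = pct(sum(bcs <= 2), n_bcs),
    pct_skin = pct(sum(skin == "present"), n_skin)
  )
}

#' Extrapolate representative-route density to an area total
#'
#' Mean dogs-per-km along representative routes, multiplied by the
#' total street length of the area, estimates the number of dogs
#' visibly roaming at survey time; dividing by an externally estimated
#' detectability (fraction of dogs present that observers record)
#' extrapolates further to the total roaming population. Only
#' representative routes support this: hotspot routes oversample
#' high-density areas by design.
#'
#' @param mean_density mean dogs per km over representative routes.
#' @param total_street_km total street length of the area (km).
#' @param detectability fraction in (0, 1]; 1 (default) gives the
#'   visibly-roaming estimate.
#' @param route_type type of the routes the density came from; anything
#'   but `"representative"` is an error.
#' @return estimated number of dogs.
#' @export
extrapolate_total <- function(mean_density, total_street_km, detectability = 1,
                              route_type = "representative") {
  if (!identical(route_type, "representative")) {
    stop("extrapolation to an area total requires representative routes; ",
         "hotspot routes oversample high-density areas", call. = FALSE)
  }
  if (total_street_km <= 0) stop("total_street_km must be positive", call. = FALSE)
  if (detectability <= 0 || detectability > 1) {
    stop("detectability must be in (0, 1]", call. = FALSE)
  }
  mean_density * total_street_km / detectability
}

#' Per-route indicator table for a set of survey events
#'
#' One row per route per survey event: the event-average density plus
#' composition/welfare percentages computed on the raw records pooled
#' across the event's replicates (pooling raw counts stabilises small
#' per-replicate denominators; density, by contrast, is the mean of
#' per-replicate densities).
#'
#' @param events list of [survey_event()] objects.
#' @param routes list of `dog_route` objects covering every event's
#'   route.
#' @param females_include_sterilised passed to [composition()].
#' @return tibble in standard indicator-table column order (see
#'   [read_indicator_csv()]), plus the count columns.
#' @export
indicator_table <- function(events, routes, females_include_sterilised = TRUE) {
  route_ids <- vapply(routes, function(r) r$route_id, character(1))
  rows <- lapply(events, function(ev) {
    i <- match(ev$route_id, route_ids)
    if (is.na(i)) stop("no route supplied for event route '", ev$route_id, "'",
                       call. = FALSE)
    rt <- routes[[i]]
    comp <- composition(pooled_records(ev), females_include_sterilised)
    tibble::tibble(
      location = rt$location, route_type = rt$route_type,
      route_id = rt$route_id, event_label = ev$event_label,
      dogs_per_km = event_density(ev, rt),
      pct_lactating = comp$pct_lactating, pct_bcs1 = comp$pct_bcs1,
      pct_bcs1or2 = comp$pct_bcs1or2, pct_skin = comp$pct_skin,
      n_dogs = comp$n_dogs, n_females = comp$n_females,
      n_lactating = comp$n_lactating, n_bcs_scored = comp$n_bcs_scored,
      n_skin_assessed = comp$n_skin_assessed
    )
  })
  if (!length(rows)) {
    return(tibble::tibble(
      location = character(), route_type = character(), route_id = character(),
      event_label = character(), dogs_per_km = numeric(),
      pct_lactating = numeric(), pct_bcs1 = numeric(), pct_bcs1or2 = numeric(),
      pct_skin = numeric(), n_dogs = integer(), n_females = integer(),
      n_lactating = integer(), n_bcs_scored = integer(),
      n_skin_assessed = integer()
    ))
  }
  do.call(rbind, rows)
}
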
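#' Write observation records to CSV
#'
#' Flat-file stand-in for the survey database: one row per observed
#' dog, with its route, date, class, welfare scores and position.
#' Unrecorded BCS and skin values are written as empty cells (never 0),
#' so abbreviated protocols stay distinguishable from scored absence.
#'
#' @param surveys list of [replicate_survey()] objects.
#' @param path output CSV.
#' @return number of observation rows written, invisibly `path` as
#'   attribute.
#' @export
write_observations_csv <- function(surveys, path) {
  rows <- lapply(surveys, function(s) {
    rec <- s$records
    data.frame(
      route_id = rep(s$route_id, nrow(rec)),
      survey_date = rep(format(s$survey_date), nrow(rec)),
      timestamp = format(rec$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      dog_class = as.character(rec$dog_class),
      bcs = ifelse(is.na(rec$bcs), "", as.character(rec$bcs)),
      skin = ifelse(is.na(rec$skin), "", as.character(rec$skin)),
      lat = sprintf("%.17g", rec$lat), lon = sprintf("%.17g", rec$lon),
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(route_id = character(), survey_date = character(),
               timestamp = character(), dog_class = character(),
               bcs = character(), skin = character(),
               lat = character(), lon = character())
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  n <- nrow(out)
  structure(n, path = path)
}

#' Read observation records from CSV
#'
#' Inverse of [write_observations_csv()]: rows are grouped by route and
#' date back into replicate surveys.
#'
#' @param path CSV written by [write_observations_csv()].
#' @return list of [replicate_survey()] objects, ordered by route then
#'   date.
#' @export
read_observations_csv <- function(path) {
  df <- read.csv(path, colClasses = "character")
  if (!nrow(df)) return(list())
  key <- paste(df$route_id, df$survey_date, sep = "\r")
  lapply(split(seq_len(nrow(df)), factor(key, levels = unique(key))), function(idx) {
    g <- df[idx, ]
    rec <- dog_records(
      timestamp = as.POSIXct(g$timestamp, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S"),
      lat = as.numeric(g$lat), lon = as.numeric(g$lon),
      dog_class = g$dog_class,
      bcs = ifelse(g$bcs == "", NA_integer_, as.integer(g$bcs)),
      skin = ifelse(g$skin == "", NA_character_, g$skin)
    )
    replicate_survey(g$route_id[1], as.Date(g$survey_date[1]), rec)
  }) |> unname()
}

#' Read an indicator table from CSV
#'
#' Loads a per-route indicator table (one row per route per survey
#' event) with the standard columns `location`, `route_type`,
#' `route_id`, `event_label`, `dogs_per_km`, `pct_lactating`,
#' `pct_bcs1`, `pct_bcs1or2`, `pct_skin`. Empty percentage cells are
#' read as `NA` (undefined: zero denominator or unrecorded under an
#' abbreviated protocol), never as 0.
#'
#' @param path CSV file.
#' @return a tibble.
#' @export
read_indicator_csv <- function(path) {
  df <- read.csv(path, colClasses = c(rep("character", 4), rep("numeric", 5)))
  tibble::as_tibble(df)
}

#' Write an indicator table to CSV
#'
#' Inverse of [read_indicator_csv()]; `NA` percentages become empty
#' cells.
#'
#' @param tbl indicator tibble.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_indicator_csv <- function(tbl, path) {
  out <- as.data.frame(tbl)
  for (j in seq_along(out)) {
    x <- out[[j]]
    out[[j]] <- ifelse(is.na(x), "", as.character(x))
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Packaged between-location indicator table
#'
#' Route-level indicators (dogs per km, percent of females lactating,
#' percent BCS 1, percent BCS 1 or 2, percent with visible skin
#' condition) for 30 routes in seven locations across Europe, Latin
#' America and Asia, as published for this survey protocol. The
#' Kathmandu rows have `pct_bcs1or2` undefined because only emaciated
#' (BCS 1) dogs were scored there; one skin cell is undefined.
#'
#' @return a 30-row tibble (see [read_indicator_csv()] for columns).
#' @export
street_survey_table1 <- function() {
  read_indicator_csv(system.file("extdata", "table1_indicators.csv",
                                 package = "streetcount", mustWork = TRUE))
}

#' Packaged monitoring series (repeat survey events)
#'
#' Event-average dogs per km for repeat surveys of standard routes in
#' five locations, at approximate (mid-month) survey dates. The Panama
#' City series spans five survey events over three years; its Casco
#' Viejo route underwent a multi-year spay/neuter intervention.
#'
#' @return a tibble with columns `location`, `route_type`, `route_id`,
#'   `survey_date` (Date), `dogs_per_km`.
#' @export
street_survey_monitoring <- function() {
  df <- read.csv(system.file("extdata", "table2_monitoring.csv",
                             package = "streetcount", mustWork = TRUE),
                 colClasses = c(rep("character", 4), "numeric"))
  df$survey_date <- as.Date(df$survey_date)
  tibble::as_tibble(df)
}
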
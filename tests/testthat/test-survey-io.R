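# KML fixture text written inline: one LineString plus point Placemarks
# that must be ignored.
kml_text <- function(coords = "0,0,0 0.009,0,0 0.009,0.009,0") {
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<kml xmlns="http://www.opengis.net/kml/2.2"><Document>',
    '<Placemark><name>poi</name><Point><coordinates>1,1,0</coordinates></Point></Placemark>',
    '<Placemark><name>route</name><LineString><coordinates>', coords,
    '</coordinates></LineString></Placemark>',
    '</Document></kml>'
  )
}

gpx_wpt <- function(name, lat = "0.001", lon = "0.002",
                    time = "2016-06-01T08:30:00Z") {
  sprintf('<wpt lat="%s" lon="%s"><time>%s</time><name>%s</name></wpt>',
          lat, lon, time, name)
}

gpx_text <- function(...) {
  paste0('<?xml version="1.0"?>',
         '<gpx version="1.1" creator="test" xmlns="http://www.topografix.com/GPX/1/1">',
         paste0(..., collapse = ""), '</gpx>')
}

test_that("KML routes are read from the first LineString, Placemark points ignored", {
  f <- withr::local_tempfile(fileext = ".kml")
  writeLines(kml_text(), f)
  r <- read_route_kml(f, "r1", "testville", "representative")
  expect_s3_class(r, "dog_route")
  expect_equal(nrow(r$polyline), 3)
  # KML is lon,lat; the route must be lat,lon
  expect_equal(unname(r$polyline[2, ]), c(0, 0.009))
  expect_equal(r$length_km, oracle_polyline_km(r$polyline), tolerance = 1e-9)
})

test_that("KML without a LineString or with malformed XML errors", {
  f <- withr::local_tempfile(fileext = ".kml")
  writeLines('<?xml version="1.0"?><kml><Document></Document></kml>', f)
  expect_error(read_route_kml(f, "r", "x"), "LineString")
  writeLines('<kml><unclosed>', f)
  expect_error(read_route_kml(f, "r", "x"), "malformed")
})

test_that("KML write/read round-trips a route", {
  r <- tiny_route()
  f <- withr::local_tempfile(fileext = ".kml")
  write_route_kml(r, f)
  r2 <- read_route_kml(f, r$route_id, r$location, r$route_type)
  expect_equal(r2$polyline, r$polyline, tolerance = 1e-7)
  expect_equal(r2$length_km, r$length_km, tolerance = 1e-5)
})

test_that("GPX waypoints become classified dog records", {
  f <- withr::local_tempfile(fileext = ".gpx")
  writeLines(gpx_text(
    gpx_wpt("Male"),
    gpx_wpt("Lactating female BCS2 Skin", time = "2016-06-01T08:31:00Z"),
    gpx_wpt("Pup BCS1 NoSkin", time = "2016-06-01T08:32:00Z")
  ), f)
  s <- read_event_log_gpx(f, survey_date = as.Date("2016-06-01"), route_id = "r1")
  expect_equal(nrow(s$records), 3)
  expect_equal(as.character(s$records$dog_class),
               c("male", "lactating_female", "pup"))
  expect_equal(s$records$bcs, c(NA, 2L, 1L))
  expect_equal(as.character(s$records$skin), c(NA, "present", "absent"))
  expect_equal(s$records$lat, rep(0.001, 3))
})

test_that("empty GPX gives an empty replicate; bad waypoints error", {
  f <- withr::local_tempfile(fileext = ".gpx")
  writeLines(gpx_text(""), f)
  s <- read_event_log_gpx(f, survey_date = as.Date("2016-06-01"))
  expect_equal(nrow(s$records), 0)

  writeLines(gpx_text(gpx_wpt("Cat")), f)
  expect_error(read_event_log_gpx(f, survey_date = as.Date("2016-06-01")),
               "'Cat'")

  writeLines(gpx_text('<wpt><name>Male</name></wpt>'), f)
  expect_error(read_event_log_gpx(f, survey_date = as.Date("2016-06-01")),
               "coordinates")
})

test_that("records timestamped outside the survey date are rejected", {
  f <- withr::local_tempfile(fileext = ".gpx")
  writeLines(gpx_text(gpx_wpt("Male", time = "2016-06-02T08:00:00Z")), f)
  expect_error(read_event_log_gpx(f, survey_date = as.Date("2016-06-01")),
               "outside survey_date")
})

test_that("GPX parsing is deterministic", {
  f <- withr::local_tempfile(fileext = ".gpx")
  writeLines(gpx_text(gpx_wpt("Male"), gpx_wpt("Female BCS3")), f)
  s1 <- read_event_log_gpx(f, survey_date = as.Date("2016-06-01"), route_id = "r")
  s2 <- read_event_log_gpx(f, survey_date = as.Date("2016-06-01"), route_id = "r")
  expect_identical(s1, s2)
})

test_that("GPX -> records -> CSV -> records is lossless for every field", {
  f <- withr::local_tempfile(fileext = ".gpx")
  writeLines(gpx_text(
    gpx_wpt("Male"),
    gpx_wpt("Female BCS3 Skin", lat = "0.003", time = "2016-06-01T08:40:10Z"),
    gpx_wpt("Sterilised female BCS4 NoSkin", lon = "0.005",
            time = "2016-06-01T09:01:59Z")
  ), f)
  s <- read_event_log_gpx(f, survey_date = as.Date("2016-06-01"), route_id = "rt")
  csv <- withr::local_tempfile(fileext = ".csv")
  n <- write_observations_csv(list(s), csv)
  expect_equal(as.numeric(n), 3)
  back <- read_observations_csv(csv)
  expect_length(back, 1)
  expect_equal(back[[1]]$records, s$records)
  expect_equal(back[[1]]$route_id, "rt")
  expect_equal(back[[1]]$survey_date, s$survey_date)
})

test_that("observation CSV handles empty input and unrecorded welfare cells", {
  csv <- withr::local_tempfile(fileext = ".csv")
  n <- write_observations_csv(list(), csv)
  expect_equal(as.numeric(n), 0)
  expect_equal(length(readLines(csv)), 1)  # header only

  s <- tiny_survey(c("male", "female"), bcs = c(NA, 2L), skin = c(NA, "absent"))
  write_observations_csv(list(s), csv)
  raw <- read.csv(csv, colClasses = "character")
  expect_equal(raw$bcs, c("", "2"))   # unrecorded is empty, never "0"
  expect_equal(raw$skin, c("", "absent"))
  back <- read_observations_csv(csv)
  expect_equal(back[[1]]$records, s$records)
})

test_that("simulator-emitted GPX re-ingests to the identical record table", {
  p <- sim_params(n_routes = 1, route_length_km = 3, lambda_per_km = 4, seed = 5)
  r <- simulate_route(p, 1)
  s <- simulate_replicate(r, p, 1)
  f <- withr::local_tempfile(fileext = ".gpx")
  write_event_log_gpx(s, f)
  s2 <- read_event_log_gpx(f, survey_date = s$survey_date, route_id = r$route_id)
  expect_equal(nrow(s2$records), nrow(s$records))
  expect_equal(as.character(s2$records$dog_class), as.character(s$records$dog_class))
  expect_equal(s2$records$bcs, s$records$bcs)
  expect_equal(as.character(s2$records$skin), as.character(s$records$skin))
  expect_equal(s2$records$timestamp, s$records$timestamp)
  expect_equal(s2$records$lat, s$records$lat, tolerance = 1e-7)
})
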
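#!/usr/bin/env Rscript
# Re-ingest the simulated programme from its field-format files (KML +
# GPX), exactly as real survey exports would be processed, and check
# that nothing is lost relative to the in-memory dataset.

suppressPackageStartupMessages(library(streetcount))

in_dir <- "scratch/sim_program"
if (!dir.exists(in_dir)) stop("run analysis/01_simulate_program.R first")
dir.create("results", showWarnings = FALSE)

kmls <- list.files(in_dir, pattern = "\\.kml$", full.names = TRUE)
routes <- lapply(kmls, function(f) {
  read_route_kml(f, sub("\\.kml$", "", basename(f)), "simulated-city")
})
cat(sprintf("Read %d routes; lengths %.2f-%.2f km.\n", length(routes),
            min(vapply(routes, `[[`, 0, "length_km")),
            max(vapply(routes, `[[`, 0, "length_km"))))

gpxs <- list.files(in_dir, pattern = "\\.gpx$", full.names = TRUE)
surveys <- lapply(gpxs, function(f) {
  parts <- sub("\\.gpx$", "", basename(f))
  date <- as.Date(substr(parts, nchar(parts) - 9, nchar(parts)))
  read_event_log_gpx(f, survey_date = date,
                     route_id = substr(parts, 1, nchar(parts) - 11))
})
n <- write_observations_csv(surveys, "results/observations.csv")
cat(sprintf("Ingested %d GPX logs -> %d dog records -> results/observations.csv\n",
            length(surveys), as.numeric(n)))

# round-trip check against the emitted CSV
back <- read_observations_csv(file.path(in_dir, "observations.csv"))
stopifnot(sum(vapply(back, function(s) nrow(s$records), integer(1))) ==
            as.numeric(n))
cat("Record counts match the simulator's own CSV export.\n")
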
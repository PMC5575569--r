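Package: streetcount
Title: Index Monitoring of Roaming Dog Populations from Street Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for monitoring roaming dog populations by direct
    observation along standard survey routes. Reads route geometry from
    KML and observation event logs from GPX (OSMtracker-style waypoint
    labels), computes per-route density (dogs per km) and composition and
    welfare indicators (percent of females lactating, percent emaciated
    or thin by body condition score, percent with visible skin
    condition), estimates the minimum detectable change in density from
    replicate surveys via a Student-t threshold, tests composition
    changes with a pooled two-proportion statistic and finds the second
    sample size needed to detect a given shift, compares locations with
    one-way ANOVA and tie-corrected Kruskal-Wallis tests, fits density
    trends over time, and simulates whole survey programmes (Poisson
    counts with log-normal day and route effects) for power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    stats,
    tibble,
    utils,
    withr,
    xml2
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
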
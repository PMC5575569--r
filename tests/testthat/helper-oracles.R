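# Independent oracles and tiny fixture builders used across the suite.
# These re-derive expected values by different routes than the package
# (hand-coded formulas, enumeration, base-R reference tests) and must
# stay independent of the implementation they check.

# Hand-coded haversine (mean Earth radius 6371.0088 km).
oracle_haversine_km <- function(lat1, lon1, lat2, lon2) {
  r <- 6371.0088
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

oracle_polyline_km <- function(pl) {
  if (nrow(pl) < 2) return(0)
  sum(oracle_haversine_km(pl[-nrow(pl), 1], pl[-nrow(pl), 2],
                          pl[-1, 1], pl[-1, 2]))
}

# Exact two-sample binomial resampling test under the pooled null:
# p-value of |p1* - p2*| >= |p1 - p2| with k1* ~ Bin(n1, p_hat),
# k2* ~ Bin(n2, p_hat) independent.
oracle_exact_two_prop_p <- function(k1, n1, k2, n2) {
  p_hat <- (k1 + k2) / (n1 + n2)
  obs <- abs(k1 / n1 - k2 / n2)
  pk1 <- dbinom(0:n1, n1, p_hat)
  pk2 <- dbinom(0:n2, n2, p_hat)
  diff <- abs(outer(0:n1, 0:n2, function(a, b) a / n1 - b / n2))
  sum(outer(pk1, pk2) * (diff >= obs - 1e-12))
}

# Kruskal-Wallis H computed from scratch (midranks, tie correction),
# kept textually independent of the package's internals.
oracle_kw_h <- function(x, g) {
  n <- length(x)
  rk <- rank(x, ties.method = "average")
  ssum <- tapply(rk, g, sum)
  cnt <- tapply(rk, g, length)
  h_raw <- 12 / (n * (n + 1)) * sum(ssum^2 / cnt) - 3 * (n + 1)
  tt <- table(x)
  h_raw / (1 - sum(tt^3 - tt) / (n^3 - n))
}

# Full permutation null of H: all n! orderings of x against the fixed
# group template (equivalent to enumerating distinct assignments with
# uniform weight).
oracle_kw_perm_p <- function(x, g) {
  h_obs <- oracle_kw_h(x, g)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  all_p <- perms(x)
  hs <- vapply(all_p, oracle_kw_h, numeric(1), g = g)
  mean(hs >= h_obs - 1e-9)
}

# A small fixed route for io/indicator tests: ~2 km L-shape near the
# equator (1 deg lon at equator = 111.195 km).
tiny_route <- function(route_id = "r1", location = "testville",
                       route_type = "representative") {
  route(route_id, location, route_type,
        cbind(lat = c(0, 0, 0.009), lon = c(0, 0.009, 0.009)))
}

tiny_records <- function(classes, bcs = NA_integer_, skin = NA_character_,
                         date = as.Date("2016-06-01")) {
  n <- length(classes)
  dog_records(
    timestamp = as.POSIXct(paste(date, "08:00:00"), tz = "UTC") + seq_len(n),
    lat = rep(0, n), lon = seq(0, 0.008, length.out = n),
    dog_class = classes, bcs = bcs, skin = skin
  )
}

tiny_survey <- function(classes, date = as.Date("2016-06-01"), route_id = "r1",
                        bcs = NA_integer_, skin = NA_character_) {
  replicate_survey(route_id, date, tiny_records(classes, bcs, skin, date))
}
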
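test_that("replicate differences are first-minus-second by date", {
  r <- tiny_route()
  d <- as.Date("2016-06-01")
  mk <- function(n, day) tiny_survey(rep("male", n), date = d + day)
  # replicates supplied out of date order on purpose
  ev <- survey_event("r1", "jun", list(mk(9, 1), mk(10, 0)))
  expect_equal(unname(replicate_differences(list(ev), list(r))),
               (10 - 9) / r$length_km)
  # >2 replicates: earliest pair only
  ev3 <- survey_event("r1", "jun", list(mk(10, 0), mk(9, 1), mk(50, 2)))
  expect_equal(unname(replicate_differences(list(ev3), list(r))),
               (10 - 9) / r$length_km)
  ev1 <- survey_event("r1", "jun", list(mk(10, 0)))
  expect_error(replicate_differences(list(ev1), list(r)), "r1")
})

test_that("null simulator differences centre on zero", {
  p <- sim_params(n_routes = 40, route_length_km = 5, lambda_per_km = 6,
                  seed = 31)
  ds <- simulate_program(p, n_events = 1, replicates_per_event = 2)
  d <- replicate_differences(ds$events, ds$routes)
  # mean difference within 2 s.e. of zero
  expect_lt(abs(mean(d)), 2 * sd(d) / sqrt(length(d)))
})

test_that("minimum detectable change matches a t-table hand computation", {
  # five differences, worked by hand with the tabulated t(0.975, 4) = 2.776
  diffs <- c(0.2, -0.1, 0.4, 0.0, -0.3)
  pr <- min_detectable_change(diffs, baseline_mean = 2)
  expect_equal(pr$mean_diff, 0.04)
  expect_equal(pr$se_diff, sqrt(0.073) / sqrt(5), tolerance = 1e-12)
  expect_equal(pr$min_detectable_abs, 2.776 * sqrt(0.073 / 5), tolerance = 1e-3)
  expect_equal(pr$min_detectable_pct, 100 * pr$min_detectable_abs / 2)
})

test_that("degenerate and invalid power inputs are handled", {
  expect_equal(min_detectable_change(rep(0.2, 4),
                                     baseline_mean = 1)$min_detectable_abs, 0)
  expect_error(min_detectable_change(c(0.1), baseline_mean = 1), "two")
  expect_error(min_detectable_change(c(0.1, 0.2), baseline_mean = 1, alpha = 1.2),
               "alpha")
  expect_error(min_detectable_change(c(0.1, 0.2), baseline_mean = 0), "positive")
})

test_that("threshold shrinks with more routes (simulation)", {
  set.seed(123)
  mean_mda <- vapply(c(5, 10, 20, 40), function(n) {
    mean(vapply(1:200, function(i) {
      min_detectable_change(rnorm(n, 0, 1), baseline_mean = 1)$min_detectable_abs
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_mda) < 0))
})

test_that("pooled two-proportion test matches the chi-square identity", {
  # pooled z^2 equals the 2x2 Pearson chi-square without continuity correction
  set.seed(17)
  for (i in 1:50) {
    n1 <- sample(5:60, 1); n2 <- sample(5:60, 1)
    k1 <- rbinom(1, n1, 0.3); k2 <- rbinom(1, n2, 0.45)
    if (k1 + k2 == 0 || k1 + k2 == n1 + n2) next
    ours <- composition_change_test(k1, n1, k2, n2)
    ref <- suppressWarnings(
      stats::prop.test(c(k1, k2), c(n1, n2), correct = FALSE))
    expect_equal(ours$z^2, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$significant, ref$p.value < 0.05)
  }
})

test_that("equal observed fractions are never significant", {
  expect_false(composition_change_test(8, 100, 4, 50)$significant)
  expect_false(composition_change_test(0, 30, 0, 40)$significant)
  tst <- composition_change_test(10, 100, 10, 100)
  expect_equal(tst$sd_null,
               sqrt((1 / 100 + 1 / 100) * 0.1 * 0.9), tolerance = 1e-12)
})

test_that("null SD is maximised at pooled fraction one half", {
  n1 <- 40; n2 <- 60
  sds <- vapply(0:(n1 + n2), function(k_tot) {
    k1 <- min(k_tot, n1)
    composition_change_test(k1, n1, k_tot - k1, n2)$sd_null
  }, numeric(1))
  best <- which.max(sds) - 1
  expect_equal(best / (n1 + n2), 0.5, tolerance = 0.02)
})

test_that("required second sample agrees with a fresh integer search", {
  cases <- list(c(3236, 0.08, 0.11), c(500, 0.10, 0.20), c(120, 0.30, 0.10))
  for (cs in cases) {
    res <- required_second_sample(cs[1], cs[2], cs[3])
    expect_true(res$reachable)
    # independent ascending search using the z formula directly
    k1 <- round(cs[2] * cs[1]); z <- qnorm(0.975)
    oracle <- NA
    for (n2 in 1:20000) {
      k2 <- round(cs[3] * n2)
      pp <- (k1 + k2) / (cs[1] + n2)
      s <- sqrt((1 / cs[1] + 1 / n2) * pp * (1 - pp))
      if (abs(k1 / cs[1] - k2 / n2) > z * s) { oracle <- n2; break }
    }
    expect_equal(res$n2, oracle)
    # the found n2 is significant and (for n2 > 1) n2 - 1 is not
    expect_true(composition_change_test(k1, cs[1], round(cs[3] * res$n2),
                                        res$n2)$significant)
  }
})

test_that("tiny shifts are reported unreachable, larger shifts never need more", {
  res <- required_second_sample(50, 0.10, 0.11)
  expect_false(res$reachable)
  expect_true(is.na(res$n2))
  a <- required_second_sample(3236, 0.08, 0.11)$n2
  b <- required_second_sample(3236, 0.08, 0.14)$n2
  expect_lte(b, a)
})

test_that("one-way ANOVA reproduces the classical F", {
  set.seed(23)
  g <- list(rnorm(6), rnorm(5, 1), rnorm(7, 0.5), rnorm(4))
  ours <- one_way_anova(g)
  ref <- stats::oneway.test(
    unlist(g) ~ factor(rep(seq_along(g), lengths(g))), var.equal = TRUE)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(ours$df, 3)
  expect_equal(ours$df_resid, 18)
})

test_that("two-group F equals the squared pooled t statistic", {
  set.seed(29)
  x <- rnorm(8); y <- rnorm(6, 0.8)
  f <- one_way_anova(list(x, y))$statistic
  t2 <- unname(stats::t.test(x, y, var.equal = TRUE)$statistic)^2
  expect_equal(f, t2, tolerance = 1e-10)
})

test_that("ANOVA degenerate cases and affine invariance", {
  expect_equal(one_way_anova(list(c(2, 2), c(2, 2, 2)))$statistic, 0)
  set.seed(31)
  g <- list(rnorm(5), rnorm(6, 1))
  f0 <- one_way_anova(g)$statistic
  f1 <- one_way_anova(lapply(g, function(v) -3.2 * v + 7))$statistic
  expect_equal(f1, f0, tolerance = 1e-10)
  expect_error(one_way_anova(list(1:3)), "two")
})

test_that("Kruskal-Wallis matches the base-R reference on tied data", {
  set.seed(37)
  for (i in 1:20) {
    g <- lapply(1:3, function(j) sample(c(0, 0, 2.5, 5, 11.1), sample(3:8, 1),
                                        replace = TRUE))
    ours <- kruskal_wallis(g)
    ref <- stats::kruskal.test(unlist(g),
                               factor(rep(seq_along(g), lengths(g))))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Kruskal-Wallis drops undefined values and needs two groups", {
  g <- list(c(1, 2, NA), c(NA, NA), c(3, 0))
  ours <- kruskal_wallis(g)
  expect_equal(ours$df, 1)  # the all-NA group vanished
  expect_error(kruskal_wallis(list(c(1, 2), c(NA_real_, NA))), "two")
})

test_that("Kruskal-Wallis is invariant under strictly monotone transforms", {
  set.seed(41)
  g <- lapply(1:3, function(j) runif(5, 0, 30))
  h0 <- kruskal_wallis(g)$statistic
  expect_equal(kruskal_wallis(lapply(g, log1p))$statistic, h0)
  expect_equal(kruskal_wallis(lapply(g, function(v) v^3))$statistic, h0)
})

test_that("exact Kruskal-Wallis p equals full permutation enumeration", {
  x <- c(3, 7, 1, 9, 4, 4, 8)           # includes a tie
  g <- factor(rep(1:3, c(3, 2, 2)))
  ours <- kruskal_wallis(split(x, g), p_method = "exact")
  expect_equal(ours$p_value, oracle_kw_perm_p(x, g), tolerance = 1e-12)
})

test_that("linear trend handles exact, constant and real series", {
  d <- as.Date(c("2014-01-01", "2015-01-01", "2016-01-01", "2017-01-01"))
  perfect <- linear_trend(d, c(1, 2, 3, 4))
  expect_equal(perfect$r_squared, 1)
  expect_equal(perfect$slope, 1, tolerance = 1e-6)
  flat <- linear_trend(d, rep(2.5, 4))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
  expect_error(linear_trend(d[1:2], c(1, 2)), "three")
  expect_error(linear_trend(rep(d[1], 3), c(1, 2, 3)), "distinct")
})

test_that("monitoring-series trend matches the normal-equations oracle", {
  m <- street_survey_monitoring()
  cv <- m[m$route_id == "Casco Viejo", ]
  tr <- linear_trend(cv$survey_date, cv$dogs_per_km)
  expect_lt(tr$slope, 0)
  # closed-form least squares on decimal years
  t <- streetcount:::decimal_year(cv$survey_date)
  y <- cv$dogs_per_km
  b <- sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
  r2 <- b^2 * sum((t - mean(t))^2) / sum((y - mean(y))^2)
  expect_equal(tr$slope, b, tolerance = 1e-12)
  expect_equal(tr$r_squared, r2, tolerance = 1e-12)
})
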
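#' Per-route replicate density differences
#'
#' For each survey event (all of which must have at least two
#' replicates), the difference between the densities recorded on the
#' first and second replicate, ordered by date. Events with more than
#' two replicates contribute their earliest pair, keeping the paired
#' structure on which the Student-t threshold of
#' [min_detectable_change()] rests. Under a constant protocol these
#' differences have zero expectation and their spread measures
#' day-to-day variation.
#'
#' @param events list of [survey_event()] objects, one per route.
#' @param routes list of `dog_route` objects covering every event.
#' @return named numeric vector of differences (first minus second
#'   replicate), one per event, named by route id.
#' @export
replicate_differences <- function(events, routes) {
  route_ids <- vapply(routes, function(r) r$route_id, character(1))
  vapply(events, function(ev) {
    if (length(ev$replicates) < 2) {
      stop("event for route '", ev$route_id,
           "' has fewer than two replicates; cannot measure day-to-day variation",
           call. = FALSE)
    }
    i <- match(ev$route_id, route_ids)
    if (is.na(i)) stop("no route supplied for event route '", ev$route_id, "'",
                       call. = FALSE)
    # replicates are date-ordered by the survey_event constructor
    dogs_per_km(ev$replicates[[1]], routes[[i]]) -
      dogs_per_km(ev$replicates[[2]], routes[[i]])
  }, numeric(1)) |>
    setNames(vapply(events, function(ev) ev$route_id, character(1)))
}

#' Minimum detectable change in density
#'
#' Converts replicate-survey noise into the smallest change a future
#' survey must show to be declared significant. The per-route replicate
#' differences, averaged over the `n` routes and divided by their
#' standard error, follow a Student-t distribution with `n - 1` degrees
#' of freedom under the null of no change; the minimum detectable
#' absolute change is therefore `se_diff * t(1 - alpha/2, n - 1)`, and
#' the percentage version expresses it relative to the baseline mean
#' density. The test is two-sided: a future density lower *or* higher
#' by more than this amount is significant.
#'
#' Either supply the raw `diffs` (from [replicate_differences()]), or
#' — for published summaries — the pre-computed `n` and `se_diff`.
#'
#' @param diffs per-route replicate density differences (dogs/km).
#' @param baseline_mean baseline mean density (dogs/km, > 0).
#' @param alpha two-sided significance level, in (0, 1).
#' @param n,se_diff alternative entry point: number of routes and
#'   standard error of the mean difference, when the raw differences
#'   are not available.
#' @return object of class `power_result`: `n_routes`, `diffs`,
#'   `mean_diff`, `se_diff`, `t_crit`, `min_detectable_abs` (dogs/km),
#'   `min_detectable_pct` (% of baseline), `baseline_mean`, `alpha`.
#' @examples
#' # 21 routes surveyed twice, SE of the mean difference 0.29 dogs/km,
#' # baseline mean 10.54 dogs/km:
#' min_detectable_change(baseline_mean = 10.54, n = 21, se_diff = 0.29)
#' @export
min_detectable_change <- function(diffs = NULL, baseline_mean, alpha = 0.05,
                                  n = NULL, se_diff = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (baseline_mean <= 0) stop("baseline_mean must be positive", call. = FALSE)
  if (!is.null(diffs)) {
    n <- length(diffs)
    if (n < 2) stop("need at least two replicate differences", call. = FALSE)
    mean_diff <- mean(diffs)
    se_diff <- sd(diffs) / sqrt(n)
  } else {
    if (is.null(n) || is.null(se_diff)) {
      stop("supply either diffs, or both n and se_diff", call. = FALSE)
    }
    if (n < 2) stop("need at least two routes", call. = FALSE)
    if (se_diff < 0) stop("se_diff must be non-negative", call. = FALSE)
    mean_diff <- NA_real_
  }
  t_crit <- qt(1 - alpha / 2, df = n - 1)
  mda <- se_diff * t_crit
  structure(
    list(n_routes = n, diffs = diffs, mean_diff = mean_diff, se_diff = se_diff,
         t_crit = t_crit, min_detectable_abs = mda,
         min_detectable_pct = 100 * mda / baseline_mean,
         baseline_mean = baseline_mean, alpha = alpha),
    class = "power_result"
  )
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(
    paste0("Minimum detectable change in density\n",
           "  routes: %d, SE of mean replicate difference: %.4g dogs/km\n",
           "  two-sided alpha %.3g, t crit (df %d): %.4f\n",
           "  minimum detectable change: %.4g dogs/km = %.3g%% of baseline %.4g\n"),
    x$n_routes, x$se_diff, x$alpha, x$n_routes - 1, x$t_crit,
    x$min_detectable_abs, x$min_detectable_pct, x$baseline_mean))
  invisible(x)
}

#' Pooled two-proportion test for a composition change
#'
#' Tests whether an observed fraction (e.g. the fraction of females
#' seen lactating) differs between two surveys, treating the counts as
#' binomial. Under the null of no change the difference of observed
#' fractions has zero mean and standard deviation
#' `sqrt((1/n1 + 1/n2) * p * (1 - p))` with `p` the pooled fraction
#' from both surveys combined; a difference exceeding `z(1 - alpha/2)`
#' times that standard deviation rejects the null (two-sided).
#'
#' @param k1,n1 count of interest and denominator in survey 1.
#' @param k2,n2 same for survey 2.
#' @param alpha two-sided significance level.
#' @return object of class `composition_change_result`: `n1`, `n2`,
#'   `p1`, `p2`, `p_pooled`, `sd_null`, `z_crit`, `z` (observed
#'   standardised difference), `p_value`, `significant`.
#' @export
composition_change_test <- function(k1, n1, k2, n2, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (n1 < 1 || n2 < 1) stop("both surveys need at least one counted female",
                             call. = FALSE)
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) {
    stop("counts must satisfy 0 <= k <= n", call. = FALSE)
  }
  p1 <- k1 / n1
  p2 <- k2 / n2
  p_pooled <- (k1 + k2) / (n1 + n2)
  sd_null <- sqrt((1 / n1 + 1 / n2) * p_pooled * (1 - p_pooled))
  z_crit <- qnorm(1 - alpha / 2)
  z <- if (sd_null > 0) (p1 - p2) / sd_null else 0
  structure(
    list(n1 = n1, n2 = n2, p1 = p1, p2 = p2, p_pooled = p_pooled,
         sd_null = sd_null, z_crit = z_crit, z = z,
         p_value = 2 * pnorm(-abs(z)),
         significant = abs(p1 - p2) > z_crit * sd_null, alpha = alpha),
    class = "composition_change_result"
  )
}

#' @export
print.composition_change_result <- function(x, ...) {
  cat(sprintf(
    paste0("Two-proportion composition change test (pooled z)\n",
           "  p1 = %.4g (n1 = %d), p2 = %.4g (n2 = %d), pooled p = %.4g\n",
           "  null SD of difference = %.4g, z = %.3f, p = %.4g -> %s at alpha %.3g\n"),
    x$p1, x$n1, x$p2, x$n2, x$p_pooled, x$sd_null, x$z, x$p_value,
    if (x$significant) "significant" else "not significant", x$alpha))
  invisible(x)
}

#' Second sample size needed to detect a composition change
#'
#' Smallest number of females `n2` that a second survey must count so
#' that an observed shift from fraction `p1` (seen among `n1` females
#' in the first survey) to fraction `p2` is significant under
#' [composition_change_test()]. Expected counts are rounded to the
#' nearest integer at each candidate `n2` and the pooled fraction is
#' recomputed, so the search is faithful to the test actually applied.
#' If the shift is too small ever to reach significance given `n1`
#' (the null SD does not shrink below `sqrt(p(1-p)/n1)` as `n2` grows),
#' the result is flagged unreachable rather than an error.
#'
#' @param n1 females counted in the first survey.
#' @param p1,p2 observed fraction in survey 1 and anticipated fraction
#'   in survey 2; both in (0, 1) and different.
#' @param alpha two-sided significance level.
#' @param n2_max search cap (default 1e6).
#' @return list of class `required_sample_result`: `n2` (NA when
#'   unreachable), `reachable`, `n1`, `p1`, `p2`, `alpha`, plus the
#'   test at the returned `n2`.
#' @export
required_second_sample <- function(n1, p1, p2, alpha = 0.05, n2_max = 1e6) {
  if (p1 <= 0 || p1 >= 1 || p2 <= 0 || p2 >= 1) {
    stop("p1 and p2 must be in (0, 1)", call. = FALSE)
  }
  if (p1 == p2) stop("p1 and p2 must differ", call. = FALSE)
  k1 <- round(p1 * n1)
  # n2 -> Inf limit: observed p2 -> p2, pooled p -> p2, variance -> p2(1-p2)/n1
  z_crit <- qnorm(1 - alpha / 2)
  lim_sd <- sqrt(p2 * (1 - p2) / n1)
  reachable_limit <- abs(k1 / n1 - p2) > z_crit * lim_sd
  result <- function(n2, test) {
    structure(list(n2 = n2, reachable = !is.na(n2), n1 = n1, p1 = p1, p2 = p2,
                   alpha = alpha, test = test),
              class = "required_sample_result")
  }
  if (!reachable_limit) return(result(NA_integer_, NULL))
  for (n2 in seq_len(n2_max)) {
    tst <- composition_change_test(k1, n1, round(p2 * n2), n2, alpha)
    if (tst$significant) return(result(n2, tst))
  }
  result(NA_integer_, NULL)
}

#' @export
print.required_sample_result <- function(x, ...) {
  if (x$reachable) {
    cat(sprintf(
      "Required second sample: n2 = %d females (n1 = %d, p1 = %.3g -> p2 = %.3g, alpha = %.3g)\n",
      x$n2, x$n1, x$p1, x$p2, x$alpha))
  } else {
    cat(sprintf(
      "Shift p1 = %.3g -> p2 = %.3g is unreachable at alpha = %.3g for any n2 given n1 = %d\n",
      x$p1, x$p2, x$alpha, x$n1))
  }
  invisible(x)
}

#' One-way analysis of variance from its sums of squares
#'
#' Classical fixed-effects one-way ANOVA on route-level values grouped
#' by location: `F = (SSB / (k - 1)) / (SSW / (N - k))` with the
#' between- and within-group sums of squares, compared to an F
#' distribution on `(k - 1, N - k)` degrees of freedom. `NA` values
#' (undefined indicators) are dropped first. When all values are
#' identical the statistic is 0 by convention.
#'
#' @param groups list of numeric vectors, one per group.
#' @return object of class `group_comparison`: `statistic`, `df`,
#'   `df_resid`, `p_value`, `method`.
#' @export
one_way_anova <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  groups <- groups[vapply(groups, length, integer(1)) > 0]
  k <- length(groups)
  if (k < 2) stop("need at least two non-empty groups", call. = FALSE)
  nj <- vapply(groups, length, integer(1))
  if (!any(nj >= 2)) stop("at least one group needs two or more values", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  grand <- mean(x)
  mj <- vapply(groups, mean, numeric(1))
  ssb <- sum(nj * (mj - grand)^2)
  ssw <- sum(vapply(seq_len(k), function(j) sum((groups[[j]] - mj[j])^2),
                    numeric(1)))
  df1 <- k - 1
  df2 <- N - k
  f <- if (ssb == 0) 0 else (ssb / df1) / (ssw / df2)
  structure(
    list(statistic = f, df = df1, df_resid = df2,
         p_value = pf(f, df1, df2, lower.tail = FALSE),
         method = "one-way ANOVA"),
    class = "group_comparison"
  )
}

# Tie-corrected Kruskal-Wallis H for a value vector and group factor.
kw_statistic <- function(x, g) {
  N <- length(x)
  r <- rank(x)  # midranks
  Rj <- tapply(r, g, sum)
  nj <- tapply(r, g, length)
  h <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr > 0) h / corr else 0
}

#' Kruskal-Wallis rank test with tie correction
#'
#' Nonparametric between-group comparison of route-level percentage
#' indicators, which tie frequently (many routes record 0%). Uses
#' midranks and the standard tie-corrected statistic
#' `H / (1 - sum(t^3 - t) / (N^3 - N))`; the p-value comes from the
#' chi-square approximation on `k - 1` degrees of freedom or, for small
#' samples, from full enumeration of the permutation null.
#' `NA` values (undefined indicators) are removed before ranking.
#'
#' @param groups list of numeric vectors, one per group.
#' @param p_method `"chisq"` (default) or `"exact"` (full enumeration
#'   of group assignments; only for small totals).
#' @param exact_limit maximum number of assignments the exact method
#'   will enumerate.
#' @return object of class `group_comparison`: `statistic` (H), `df`,
#'   `p_value`, `method`.
#' @export
kruskal_wallis <- function(groups, p_method = c("chisq", "exact"),
                           exact_limit = 5e5) {
  p_method <- match.arg(p_method)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  groups <- groups[vapply(groups, length, integer(1)) > 0]
  k <- length(groups)
  if (k < 2) {
    stop("need at least two non-empty groups after missing-value removal",
         call. = FALSE)
  }
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_len(k), times = vapply(groups, length, integer(1))))
  h <- kw_statistic(x, g)
  p <- if (p_method == "chisq") {
    pchisq(h, df = k - 1, lower.tail = FALSE)
  } else {
    kw_exact_p(x, as.integer(table(g)), h, exact_limit)
  }
  structure(
    list(statistic = h, df = k - 1, p_value = p,
         method = paste0("Kruskal-Wallis (tie-corrected, ", p_method, " p)")),
    class = "group_comparison"
  )
}

# Exact permutation p-value: enumerate every distinct assignment of the
# observations to groups of the observed sizes and count assignments
# with H >= observed (with a small numeric tolerance).
kw_exact_p <- function(x, sizes, h_obs, exact_limit) {
  total <- prod(choose(cumsum(rev(sizes)), rev(sizes)))
  if (total > exact_limit) {
    stop(sprintf("exact enumeration needs %.0f assignments (limit %g)",
                 total, exact_limit), call. = FALSE)
  }
  N <- length(x)
  count <- 0L
  n_assign <- 0L
  recurse <- function(remaining, gi, assigned_groups) {
    if (gi == length(sizes)) {
      g <- integer(N)
      for (j in seq_along(assigned_groups)) g[assigned_groups[[j]]] <- j
      g[remaining] <- gi  # last group takes the rest
      h <- kw_statistic(x, factor(g, levels = seq_along(sizes)))
      n_assign <<- n_assign + 1L
      if (h >= h_obs - 1e-9) count <<- count + 1L
      return(invisible())
    }
    combs <- utils::combn(remaining, sizes[gi], simplify = FALSE)
    for (cc in combs) {
      recurse(setdiff(remaining, cc), gi + 1L, c(assigned_groups, list(cc)))
    }
  }
  recurse(seq_len(N), 1L, list())
  count / n_assign
}

#' @export
print.group_comparison <- function(x, ...) {
  extra <- if (!is.null(x$df_resid)) sprintf(", %d", x$df_resid) else ""
  cat(sprintf("%s: statistic = %.4f, df = %d%s, p = %.4g\n",
              x$method, x$statistic, x$df, extra, x$p_value))
  invisible(x)
}

# Convert a Date to a decimal year (year + elapsed fraction).
decimal_year <- function(date) {
  date <- as.Date(date)
  yr <- as.integer(format(date, "%Y"))
  start <- as.Date(sprintf("%d-01-01", yr))
  end <- as.Date(sprintf("%d-01-01", yr + 1L))
  yr + as.numeric(date - start) / as.numeric(end - start)
}

#' Linear trend of an indicator over survey dates
#'
#' Ordinary least-squares regression of event-average indicator values
#' on time in decimal years, for monitoring series with unequal survey
#' spacing. The p-value is the two-sided test of zero slope.
#'
#' @param dates survey dates (`Date`), all distinct, at least three.
#' @param values event-average indicator values (e.g. dogs per km).
#' @return object of class `trend_result`: `slope` (per year),
#'   `intercept`, `r_squared`, `p_value`, `n_points`.
#' @export
linear_trend <- function(dates, values) {
  dates <- as.Date(dates)
  if (length(dates) != length(values)) stop("dates and values lengths differ",
                                            call. = FALSE)
  keep <- !is.na(values) & !is.na(dates)
  dates <- dates[keep]; values <- values[keep]
  if (length(dates) < 3) stop("need at least three points", call. = FALSE)
  if (anyDuplicated(dates)) stop("dates must be distinct", call. = FALSE)
  if (sd(values) == 0) {
    return(structure(
      list(slope = 0, intercept = values[1], r_squared = 0, p_value = 1,
           n_points = length(values)),
      class = "trend_result"
    ))
  }
  t <- decimal_year(dates)
  fit <- lm(values ~ t)
  sm <- suppressWarnings(summary(fit))  # perfect fits warn harmlessly
  slope <- unname(coef(fit)[2])
  p <- if (sm$sigma == 0) {
    if (slope == 0) 1 else 0  # perfect fit: slope exactly (non)zero
  } else {
    unname(coef(sm)[2, 4])
  }
  structure(
    list(slope = slope, intercept = unname(coef(fit)[1]),
         r_squared = sm$r.squared, p_value = p, n_points = length(values)),
    class = "trend_result"
  )
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf(
    "Linear trend: slope = %.4g per year, R^2 = %.4f, p = %.4g (n = %d)\n",
    x$slope, x$r_squared, x$p_value, x$n_points))
  invisible(x)
}
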
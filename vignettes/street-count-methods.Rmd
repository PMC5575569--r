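---
title: "Street-count monitoring of roaming dogs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Street-count monitoring of roaming dogs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streetcount)
```

## The monitoring problem

Many cities run dog population management (DPM) programmes —
spay/neuter campaigns, vaccination, sheltering — without an affordable
way to tell whether the roaming-dog population is actually changing.
Estimating *absolute* abundance needs mark–resight effort and still
inherits hard-to-quantify biases. This package implements the cheaper
alternative of **index monitoring**: count dogs along fixed routes
under a rigidly standardised protocol and track *dogs seen per km of
street*. If search effort, season, time of day, transport mode and
routes are all held constant, average detectability is constant too,
and changes in the index track changes in density. Density per km is
also the quantity residents experience — it predicts how many dogs one
meets on a commute — which makes it more meaningful to stakeholders
than a city-wide total.

Two kinds of routes are supported. *Representative* routes are drawn
by someone naïve to the expected dog distribution and support
extrapolation to an area total via `extrapolate_total()` (mean density
× total street length ÷ detectability). *Hotspot* routes deliberately
bisect known high-density areas; they are efficient for within-route
trend monitoring but `extrapolate_total()` refuses them.

## Data model and file formats

A `route()` is a WGS84 polyline (first `LineString` of a KML file;
`read_route_kml()`); its length is the sum of haversine segment
lengths on a sphere of radius 6371.0088 km. The spherical
approximation errs by well under 0.5%, far below day-to-day count
noise; ellipsoidal geodesics would add a dependency without changing
any decision. Lengths above 20 km raise a *warning* (the protocol aims
at routes finishable within about two hours), never an error.

Observations arrive as GPX waypoints, one per dog
(`read_event_log_gpx()`): the waypoint name is the label of the button
the observer tapped. Since button layouts vary between deployments,
parsing goes through a label map (`default_label_map()`); a label
absent from the map is a hard error listing the offending name, so a
misconfigured layout cannot silently drop dogs. The default grammar is
`"<class> [BCS1..BCS5] [Skin|NoSkin]"`, e.g. `"Lactating female BCS2
Skin"`; a missing token means *unrecorded*, which is deliberately
distinct from *absent*. Waypoints timestamped outside the declared
survey date are rejected to guard against concatenated multi-day logs.
Dog classes are the seven protocol classes (male, female, lactating
female, unknown adult, pup, and the two sterilisation-marked classes
used where dogs are visibly marked).

## Indicators

For one replicate survey, `dogs_per_km()` is simply count ÷ route
length. A *survey event* is the same route surveyed on two or more
consecutive days; `event_density()` averages the per-replicate
densities. Composition and welfare indicators (`composition()`):

* `pct_lactating` — lactating females / identified females × 100. The
  denominator includes sterilised females by default
  (`females_include_sterilised = TRUE`): they are identified females,
  and excluding them would make the indicator jump mechanically as a
  spay programme marks more animals. Pups and unknown adults are never
  counted as females.
* `pct_bcs1`, `pct_bcs1or2` — emaciated (BCS 1) and emaciated-or-thin
  dogs over *BCS-scored* dogs. Abbreviated protocols used in very
  dense populations score only emaciated dogs; then `pct_bcs1or2` is
  undefined.
* `pct_skin` — visible skin conditions over skin-assessed dogs.

A zero denominator yields `NA` (undefined), never 0, and `NA`
propagates into downstream tests as a missing value. Within an event,
percentages are computed on the raw records pooled across replicates
(small per-replicate denominators would otherwise be unstable), while
density averages per-replicate densities; `indicator_table()` applies
both conventions to produce one row per route per event.

## Power to detect a change in density

Replicating the baseline survey turns day-to-day noise into a usable
error estimate. Let $d_i$ be the difference between the densities of
the first and second replicate on route $i$ ($i = 1..n$,
`replicate_differences()`; events with more than two replicates
contribute their earliest pair so the paired-difference distribution
theory stays intact). Under no true change, $\bar d / \mathrm{SE}(\bar
d)$ is Student-$t$ with $n-1$ degrees of freedom, so the smallest
observed change a future survey must show is

$$\Delta_{\min} = \mathrm{SE}(\bar d)\; t_{1-\alpha/2,\,n-1},$$

reported by `min_detectable_change()` in dogs/km and as a percentage
of the baseline mean. Both tails count (a significant *increase* is as
reportable as a decrease), so quantiles are taken at $\alpha/2$ per
tail. The function also accepts published summaries (`n`, `se_diff`)
directly: for a 21-route baseline with mean 10.54 dogs/km and
$\mathrm{SE}(\bar d) = 0.29$, it gives $0.29 \times t_{0.975,20} =
0.60$ dogs/km, i.e. a minimum detectable change of about 6%.

The Monte-Carlo checker `power_null_calibration()` verifies the
threshold's size under the simulator's null. One subtlety is designed
in: the statistic is exactly $t$-sized for the mean over routes of
*(one future count − one independent baseline count)*, because that
difference has the same per-route variance as $d_i$. Comparing means
of fully replicated events against the same threshold halves the
variance of the observed change and is therefore *conservative*.
The calibration simulates the exactly-sized comparison (a baseline
replicate pair to estimate the threshold, plus two further independent
single surveys per route); with the default parameters the empirical
rejection rate over 2000 programmes sits inside the 99% binomial
envelope of 0.05.

If a monitoring *series* exists, picking out a pair of surveys that
happens to show a change would invalidate the test size; series belong
to `linear_trend()` instead.

## Power to detect a change in composition

Fractions such as "% of females lactating" need no replication:
treating the $k$ lactating among $n$ females as binomial, the
difference between two surveys' observed fractions has, under the
null, standard deviation $\sqrt{(1/n_1 + 1/n_2)\,p(1-p)}$ with $p$
pooled from both surveys. `composition_change_test()` declares a
change significant when $|p_1 - p_2|$ exceeds $z_{1-\alpha/2}$ times
that SD. `required_second_sample()` inverts the test by ascending
integer search on $n_2$, rounding expected counts to integers and
re-pooling at every candidate — faithful to the test actually applied
later. Because the null SD cannot drop below $\sqrt{p(1-p)/n_1}$ as
$n_2 \to \infty$, shifts below that limit are reported as
*unreachable* rather than hitting the search cap. The normal
approximation's adequacy is quantified in the test suite against an
exact two-sample binomial resampling oracle (≥95% decision agreement
over 500 random small surveys; in practice close to 100%).

## Comparing locations and fitting trends

Route-level event averages — the granularity of the packaged
seven-location table — are compared across locations with
`one_way_anova()` (density) and `kruskal_wallis()` (percentage
indicators). Both statistics are computed from their defining
formulas; the suite cross-checks them against `stats::oneway.test()`
and `stats::kruskal.test()`. The Kruskal–Wallis implementation uses
midranks with the standard tie correction $1 - \sum (t^3 - t)/(N^3 -
N)$ — essential here because percentage indicators tie at 0.0% on many
routes — and offers an exact permutation p-value (`p_method =
"exact"`, full enumeration of group assignments) for small samples
where the $\chi^2$ approximation is doubtful.

One reproducibility caveat is documented rather than hidden: the
route-level ANOVA on the packaged table reproduces the originally
reported F (10.94) essentially exactly, and the BCS 1-or-2 H closely
(8.94 vs 8.91), but the originally reported H values for % lactating
and % skin are not recoverable from route-level percentages under any
rank/tie-handling variant; they were evidently computed on
per-replicate percentages that were plotted but never published. The
package reports what its stated inputs give.

`linear_trend()` regresses event averages on time in decimal years
(survey spacing is irregular; packaged monitoring dates use a
mid-month convention, day 15, since only month precision is
available). On the monitored intervention route the event-average
series declines significantly; its $R^2$ on event averages is not
comparable to values computed on replicate-level points.

No multiple-testing correction is applied across indicators — each
indicator answers its own monitoring question — and none of the
results change qualitatively under Bonferroni at these p-values.

## The survey simulator

`sim_params()` + `simulate_program()` generate whole programmes with
the statistical structure the analysis assumes, so every pipeline
stage is testable without field data:

* **Counts**: route $i$, survey $j$ has count $\sim$ Poisson$(\lambda
  L\, m_i e_{ij})$ with log-normal route effect $m_i$ (SD
  `sigma_route`, mean 1) and day effect $e_{ij}$ (SD `sigma_day`,
  mean 1). Marginally this gives overdispersed (negative-binomial-like)
  counts, the simplest model consistent with observed between-route
  heterogeneity and day-to-day variation.
* **Attributes**: each dog independently draws one of the seven
  classes (females become lactating with
  `p_lactating_given_female`), a BCS from `bcs_probs`, and a Bernoulli
  skin condition; `bcs_mode = "bcs1_only"` emulates the abbreviated
  high-density protocol.
* **Geometry**: routes are street-grid-like polylines of 0.25 km
  segments hitting the target length to within 0.1%; dogs are placed
  uniformly along the route with monotone timestamps (the survey is
  paced to finish in two hours).

Defaults are pinned to the best-documented replicated baseline: 21
routes, 10.54 dogs/km, 8% of females lactating, two replicates. Route
length defaults to 20 km (the protocol's vehicle-survey maximum; the
actual route lengths were not published) and `sigma_day = 0.0566` is
calibrated so the delta-method SE of the mean replicate difference,
$\sqrt{2(\lambda/L + \lambda^2(e^{\sigma^2}-1))/n}$, equals the
published 0.29 dogs/km at those defaults. Notably, at $L = 10$ km pure
Poisson noise alone would already exceed that SE, which independently
supports route lengths near 20 km. BCS defaults (1%, 14%, 50%, 30%,
5%) and `p_skin = 0.10` sit in the middle of the published
between-route ranges.

All randomness flows from the single `seed`: each route/replicate
stream derives its own sub-seed through a collision-resistant hash
plus one scrambling pass of the generator (naïve linear sub-seeds
leave first draws across streams correlated, which measurably biased
mean replicate differences during development). Equal seeds give
bit-identical datasets; `write_sim_dataset()` round-trips through
KML/GPX/CSV to the same record tables.

What the simulator does *not* emulate — and what passing tests
therefore cannot certify about field data: dogs are placed
independently (no packs or clustering), there is no double-counting
mechanism (the field protocol is designed to avoid it), detectability
is folded into $\lambda$ rather than modelled (so simulated "density"
is visible-dog density), and there is no seasonal structure (the
protocol mandates same-season comparisons instead).

## Numerical choices and problem sizes

Quantiles ($t$, $z$, $\chi^2$, $F$) come from base R. Ties use
midranks. `required_second_sample()` caps its search at $10^6$ but
reports unreachability analytically before searching. The exact
Kruskal–Wallis enumerator refuses instances above $5\times10^5$
assignments. Degenerate inputs return defined values rather than
errors where a value is meaningful: zero-variance differences give a
zero minimum detectable change, all-identical ANOVA inputs give $F =
0$, constant trend series give slope 0 with $R^2 = 0$.

The test suite sizes its simulations to be decisive yet quick: 2000
Monte-Carlo programmes for the type-I calibration (99% binomial
envelope half-width ±0.0126), 1000 replicates for density-parameter
recovery (2-s.e. check), 500 random configurations for the
pooled-z-vs-exact comparison, and full enumeration (≤ 40,320
permutations) for exact Kruskal–Wallis checks. The whole suite runs in
about two minutes on one CPU.
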
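---
title: "flocknet: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{flocknet: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flocknet)
```

`flocknet` analyses the temporal stability of social networks and
group-foraging behaviour in winter bird flocks recorded at RFID feeders.
One antenna per site produces a stream of time-stamped visits by
PIT-tagged individuals; from that single data type the package derives
foraging events, weekly association networks, a permutation test of
network consistency, repeatability estimates for network and foraging
metrics, an entropy-based measure of how clumped activity is in time, and
an information-theoretic model-selection layer for habitat comparisons.
This vignette documents the models, the tunable parameters, and the design
choices made where the methods literature leaves the details open.

## 1. Foraging events from visit streams

Feeder activity is bursty: a flock arrives, members trade places on the
perch for some minutes, and the feeder then sits idle. `detect_events()`
segments one site-day by fitting one-dimensional Gaussian mixtures to the
arrival timestamps, selecting the number of components K by minimum BIC
(K = 1..`max_components`, 3K − 1 free parameters), hard-assigning every
visit to its maximum-responsibility component, and merging components
whose assigned arrival-to-departure spans overlap. The result is an
ordered, non-overlapping partition of the day's visits: every visit
belongs to exactly one foraging event.

Numerical choices that matter:

* **Variance floor** (`min_sd_s`, default 10 s). Timestamps are integer
  seconds and a tight burst can put several reads at the same second;
  without a floor BIC happily shreds bursts into per-read singleton
  components. Ten seconds is roughly the granularity at which a single
  perch antenna distinguishes visits.
* **EM initialisation.** Best of 5 restarts per K: a deterministic
  split-at-the-largest-gaps seeding, a quantile seeding, an incremental
  split of the widest component of the (K−1)-fit, and k-means++ draws.
  Component variances are seeded from the nearest-centre partition — a
  shared global variance would swamp the centre separation and collapse
  the means. The restart RNG is seeded from `(seed, site, day)`, so
  detection is reproducible and invariant to a constant time shift.
* **BIC scan.** The BIC curve is locally bumpy at small K; the scan never
  stops before K = 10 and thereafter stops after 3 consecutive
  non-improvements.
* **Small days.** With fewer than 3 visits BIC is meaningless; such days
  are segmented at arrival gaps larger than `bridge_s` (default 600 s).

Residency filters follow the field convention: a bird is *present* in a
sampling week only when recorded strictly more than 5 times that week
(`strict = FALSE` relaxes this to ≥, since the verbal rule "greater than
five separate times" is ambiguous), and birds present in fewer than 5
weeks are excluded everywhere. Events and retained individuals form a
binary group-by-individual (GBI) matrix per site-week, with per-row day
labels kept for the permutation scheme.

## 2. Weekly networks

Under the gambit of the group, co-membership in a foraging event is
association. Edges are the simple ratio index
SRI(a,b) = x / (x + y_a + y_b), with x the events containing both and
y_a, y_b the events containing only one of them; with a single feeder
there are no simultaneous separate sightings, so the denominator is just
the number of events containing a or b. Node metrics are weighted degree
(row sums of the SRI matrix) and eigenvector centrality (principal
eigenvector of the full weighted matrix, non-negative, rescaled to max 1).
On a disconnected weekly network the whole-matrix eigenvector — the limit
of power iteration — puts the mass on the dominant component;
`componentwise = TRUE` rescales per component instead. Individuals seen in
no event that week are excluded from that week's network rather than
given zero scores, because the index is undefined for them.

For cross-week comparison each metric is converted to a normalized rank:
ascending ranks with average ties, divided by the number of individuals
ranked that week, giving values in (0, 1] regardless of network size.
Without this size normalisation the sum of rank variances below would
scale with flock size and weeks could not be pooled.

## 3. Network consistency: the SV permutation test

For one site, stack the weekly normalized ranks into an individual × week
table and compute SV — the sum over individuals of the sample variance
(n−1 denominator) of their ranks across the weeks they were ranked in.
Small SV means individuals hold the same relative positions week after
week. Significance comes from data-stream permutations: within each week,
individuals are swapped between events *on the same day* by checkerboard
swaps that preserve every event size, every individual's observation
count, and the per-day event structure. Each week's matrix runs its own
cumulative chain; every `swaps_between_saves` (default 10) swaps a
checkpoint is taken, SV is recomputed across the randomized weeks, and
after `n_networks` (default 1,000) checkpoints the p-value is the
proportion of randomized SV values *below* the observed one. Positions are
significantly consistent when p < 0.05.

Two subtleties are worth stating plainly:

* **What the null preserves.** The margins of a GBI are sufficient for
  any attendance process in which birds visit independently with
  bird-specific rates. Such data are, conditional on the margins,
  *uniform on the permutation fiber* — the test can only detect pairwise
  structure beyond attendance rates (who forages *with* whom, not how
  often each bird forages). This is not a defect; it is what
  "controlling for gregariousness and sampling" means.
* **Chain proposal.** `single_swap()` picks uniformly among the currently
  valid checkerboard quadruples (rejection sampling with an exhaustive
  fallback). A retry-until-valid chain has a stationary law weighted by
  each state's checkerboard count rather than exactly uniform — the
  classical trial-swap caveat. The bias is small on the matrices at hand
  and the enumeration-based test budgets for it; the alternative (no-op
  proposals) was rejected because a matrix with exactly one checkerboard
  must swap deterministically under the documented contract.

## 4. Repeatability

`adjusted_repeatability()` fits a mixed model with the stated fixed
effects and a random intercept for the grouping factor and returns
R = σ²_group / (σ²_group + σ²_other + σ²_residual) — the proportion of
the variance left by the fixed effects that is attributable to the
grouping factor. Gaussian models are fitted by REML; Poisson models use a
log link with an observation-level random effect for overdispersion and
report R on the latent scale, adding the distribution variance
log(1/λ + 1) at the marginal mean. Confidence intervals are percentile
intervals from a seeded parametric bootstrap (simulate from the fit,
refit, recompute R; default 1,000 draws — the pipeline's desk-scale
default is 100, which widens nothing but adds Monte-Carlo noise to the CI
endpoints). A group variance collapsing to ~0 is reported as R = 0 with a
degeneracy flag.

Two p-value routes exist, matching how the two metric families are
treated: network-metric repeatabilities are compared against R computed
on ensembles of randomized networks (p = proportion of null R larger than
observed), while foraging-metric repeatabilities use a boundary-corrected
likelihood-ratio test of the random effect (LRT statistic against a
χ²₁, p halved).

Habitat contrasts use the 84% confidence-interval rule: two
repeatabilities differ when their 84% CIs are disjoint, an approximation
to a 5%-level test on the difference. With only 4 sites per habitat, site
enters the subset models as a fixed effect (a 4-level variance component
is not estimable); the grouping factor is unchanged.

## 5. Clumpiness

For a day with window [t₀, t₁] and a set of items — either points (every
individual's first arrival to every event, duplicates kept) or spans
(event start to last departure) — form the interval vector including the
two boundary intervals, normalize to proportions p, and compute
H_p = Σ p·log p (natural log, 0·log 0 ≡ 0). The rescaled statistic is
1 + H_p / log(n+1) for n items: exactly 0 for even spacing, 1 in the
fully clumped limit. The original construction leaves the rescaling
unstated; the theoretical-bound rescaling was chosen over an empirical
min–max because it is day-window invariant, needs no reference ensemble,
and makes days with different item counts comparable. Spans straddling
the window are clipped; a day whose events fill the window has no gap
time and the statistic is undefined (`NA` with a warning). The recording
window defaults to the civil 06:00–18:00 day — feeder activity is
diurnal and "end of the day" needs a convention; it is configurable per
run.

## 6. Model selection

For each foraging response (per-event duration and group size; daily
event count, visit count, and the two clumpiness measures) the candidate
set comprises every fixed-effect structure over {habitat, month,
group size} and their two-way interactions that respects marginality,
plus the null model — 18 candidates — each with a site random intercept.
Candidates are fitted by maximum likelihood (not REML), so AICc
(−2ℓ + 2k + 2k(k+1)/(n−k−1), n = rows) is comparable across fixed-effect
structures. Akaike weights rank the set, and the ΔAICc < 2 candidates are
model-averaged conditionally (a coefficient is averaged over the models
containing it) with unconditional standard errors combining within-model
variance and between-model spread. Poisson candidates use `nAGQ = 0` — a
deliberate speed/accuracy trade documented here because the pipeline
refits these models hundreds of times during bootstraps and permutation
ensembles.

## 7. The synthetic world

`simulate_dataset()` exists so that every downstream stage has a
parameter-recovery oracle. It emulates: 4 urban and 4 rural sites; one
roster of 10 birds per site; 13 weeks × 7 recorded days; a Poisson number
(mean 8) of non-overlapping foraging events per day placed in a 06:00–
18:00 window; per-event attendance; and 1–several visits per attending
bird with normal within-burst spread (sd 60 s) and exponential dwell.
Timestamps are integer seconds from an epoch date, so days and weeks fall
out of plain arithmetic.

Three dials deserve explanation:

* **Clumpiness** of event starts. The m starts of a day are placed at the
  cumulative sums of m+1 interval proportions drawn from a symmetric
  Dirichlet(α). For that family E[Σ p log p] = ψ(α+1) − ψ((m+1)α+1), so
  the α achieving any target expected rescaled clumpiness has a closed
  form inverted by bisection (`clumpiness_concentration()`) — an exact
  calibration where a precomputed lookup table would interpolate. The
  day-to-day jitter of the target is habitat-specific (urban 0.05, rural
  0.15): urban foraging schedules are the more repeatable ones, which is
  the contrast the repeatability layer is designed to detect.
* **Rank structure and subflocks.** Each bird has a quality score; weekly
  latent ranks are the order of quality plus N(0, `rank_noise_sd`) noise,
  so 0 freezes the hierarchy and large values make weekly orders
  exchangeable. Attendance declines with rank on the logit scale
  (`attendance_slope`). Crucially, rates alone cannot make the
  consistency test fire (§3): a rates-only stream is, conditional on its
  margins, a draw from the permutation null. The generator therefore
  organises each week's flock into `n_subflocks` (default 3) contiguous
  blocks of the weekly rank order — the consistent foraging subgroups
  winter flocks actually show. Every event belongs to one subflock,
  drawn uniformly; members attend with probability `subflock_in` (0.9),
  outsiders leak in with `subflock_out` (0.05), and the slope, seasonal
  and activity terms tilt both on the logit scale. This stable
  co-membership structure is precisely what day-restricted swaps destroy,
  so the consistency test has strong power when ranks are stable, and the
  structure dissolves as `rank_noise_sd` grows (block membership
  reshuffles weekly). Because the event's subflock is uniform, every
  bird's marginal attendance law is identical at `attendance_slope = 0`
  whatever the block sizes — the symmetry property holds with the
  structure on. Weekly per-bird activity noise (`activity_sd` = 1, logit
  scale) makes observation counts fluctuate the way field data do.
  An earlier design used a continuous per-event "rank centre" kernel;
  it was abandoned because resampling the centre independently for every
  event injects as much week-to-week noise into the observed networks as
  the permutation adds to the null, capping the test's power near 0.9 —
  stable within-week blocks are both more realistic and statistically
  cleaner. `n_subflocks = 1` recovers the rates-only regime.
* **Habitat trends.** Event duration drifts upward over the season at
  urban sites (+50% by the final week) and is flat at rural ones; event
  sizes drift down at urban sites and slightly up at rural ones — the
  kind of seasonal × habitat interaction the model-selection layer is
  meant to surface.

What the generator does **not** emulate: detection error or tag loss,
multiple feeders or spatial movement, within-day activity rhythms
(events are exchangeable within the window given their spacing),
immigration/emigration (rosters are closed), and any pairwise structure
beyond the rank band. A green test therefore establishes that the
pipeline recovers what this world contains — not that real chickadee
data contain it.

## 8. Desk-scale defaults and limitations

The permutation count (1,000) follows the field standard. The pipeline's
bootstrap default (100 draws) and permutation-repeatability ensemble (100)
are desk-scale choices so a full 8-site, 13-week run completes in minutes
on one CPU; for publication-grade intervals raise them to 1,000 in the run
config. AICc uses the row count as n — the usual, slightly anticonservative
convention for mixed models. The LRT p-values for variance components use
the halved-χ²₁ boundary correction, which is itself approximate. The
consistency chain starts at the observed matrix with no extra burn-in
(the first checkpoint is after `swaps_between_saves` swaps), matching the
"increasingly random networks" construction; both knobs are exposed in
the plan.
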
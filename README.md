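# flocknet

Temporal stability of social networks and group-foraging behaviour from
RFID feeder-visit streams.

Winter flocks of small passerines (the motivating system is black-capped
chickadees at urban and rural feeders) can be followed through an entire
nonbreeding season with a single RFID antenna per site: every visit by a
PIT-tagged bird is a time-stamped row. `flocknet` turns such streams into
a reproducible analysis of *how stable* flock social structure and group
foraging are through time, and whether that stability differs between
habitat types. The package is aimed at behavioural ecologists working
with automated visitation data (RFID feeders, nest-box loggers, barcode
trackers) who need the full chain — event detection through mixed-model
inference — under one seed.

## What it computes

* **Foraging events.** Bursts of feeder activity found per site-day by a
  1-D Gaussian mixture over arrival times with BIC selection of the
  number of components, hard assignment, and overlap merging
  (`detect_events()`).
* **Weekly association networks.** Gambit-of-the-group incidence
  matrices per site-week; edges weighted by the simple ratio index
  SRI(a,b) = x / (x + y_a + y_b) ∈ [0, 1]; weighted degree and
  eigenvector centrality with size-free normalized ranks
  (`sri_matrix()`, `weekly_network()`).
* **Network consistency.** SV = Σ_individuals Var(weekly normalized
  rank). Observed SV is compared with SV on ensembles of day-restricted
  data-stream permutations (checkerboard swaps preserving event sizes and
  individual totals); p = Pr(SV_random < SV_observed)
  (`consistency_test()`, `single_swap()`, `null_ensemble()`).
* **Repeatability.** Adjusted R = σ²_group / (σ²_group + σ²_other +
  σ²_residual) from lme4 mixed models (latent scale for Poisson), with
  seeded parametric-bootstrap CIs, permutation or boundary-corrected LRT
  p-values, and the 84%-CI rule for habitat contrasts
  (`adjusted_repeatability()`, `compare_habitats()`).
* **Clumpiness.** The interval-entropy statistic
  H_p = Σ p_i log p_i over the gaps between arrivals (or between whole
  events) within a day, rescaled to [0, 1] by its theoretical bounds:
  0 = evenly spread, 1 = maximally clustered (`raw_entropy()`,
  `rescaled_clumpiness()`, `clumpiness_of_arrivals()`,
  `clumpiness_of_events()`).
* **Model selection.** AICc-ranked candidate sets over {habitat, month,
  group size} with marginality-respecting two-way interactions, Akaike
  weights, and conditional model averaging of the ΔAICc < 2 set
  (`fit_candidates()`, `rank_models()`, `model_average()`).
* **Synthetic RFID worlds.** A generator with known ground truth —
  event schedules with a calibrated temporal-clumpiness dial, latent
  dominance ranks, rank-neighbourhood affinity, habitat-specific seasonal
  trends — so every stage has a parameter-recovery test
  (`sim_config()`, `simulate_dataset()`).
* **Pipeline.** `run_all(run_config(), out_dir)` chains everything from
  one seeded config into plain-CSV tables (consistency per site,
  repeatability per metric × {all, urban, rural}, model rankings) plus a
  YAML manifest; reruns are byte-identical. A `flocknet` CLI with
  `simulate/detect/networks/foraging/run` subcommands is installed under
  the package `exec/` directory.

## Worked example

```r
library(flocknet)

cfg <- sim_config(n_sites_urban = 1, n_sites_rural = 0, birds_per_site = 10,
                  n_weeks = 8, rank_noise_sd = 0, seed = 7)
sim  <- simulate_dataset(cfg)
nrow(sim$stream)
#> [1] 4362

dets <- detect_events_stream(sim$stream, seed = 7)
filt <- apply_inclusion_filters(sim$stream)
gbis <- build_weekly_gbis(dets, filt$roster)

nw <- weekly_network(gbis$U1[["1"]])
nw
#> <weekly_network> site U1 week 1: 10 individuals, mean SRI 0.299

res <- consistency_test(gbis$U1, permutation_plan(n_networks = 200, seed = 1))
res$degree
#> <consistency> site U1, degree ranks: SV_O = 0.7139, p = 0.010 (200 permutations)
res$eigen
#> <consistency> site U1, eigen ranks: SV_O = 0.6557, p = 0.000 (200 permutations)
```

The stream holds 4,362 antenna reads over eight weeks. Week 1's network
spans all ten birds with a mean association strength of 0.30. With the
rank-noise dial at zero the flock's latent hierarchy — and hence its
foraging-subflock structure — is frozen, so individuals occupy similar
relative network positions week after week: the observed sum of rank
variances (0.71 for weighted degree) sits below 98% of the 200
day-restricted permutations (p = 0.010), and below all of them for
eigenvector centrality (p = 0.000) — significantly consistent network
positions, as this ground truth should produce even after event
detection has blurred some burst boundaries. Full runs (`run_all`) add
repeatability tables, clumpiness summaries, and AICc model rankings per
response.

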
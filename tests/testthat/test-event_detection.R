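# Burst detection, inclusion filters, and group-by-individual construction.

test_that("well-separated visit clusters become two events", {
  v <- visits_df(c(100, 110, 120, 5000, 5010),
                 tags = c("A", "B", "A", "B", "C"))
  det <- detect_events(v, seed = 1)
  expect_identical(nrow(det$events), 2L)
  # oracle: single-linkage split at the 4,880 s gap
  expect_identical(det$assignment, c(1L, 1L, 1L, 2L, 2L))
  expect_setequal(det$membership$tag_id[det$membership$event_idx == 1],
                  c("A", "B"))
  expect_setequal(det$membership$tag_id[det$membership$event_idx == 2],
                  c("B", "C"))
})

test_that("a single visit gives one event spanning its dwell", {
  v <- visits_df(300, 320, tags = "A")
  det <- detect_events(v, seed = 1)
  expect_identical(nrow(det$events), 1L)
  expect_identical(det$events$start_s, 300L)
  expect_identical(det$events$end_s, 320L)
  expect_identical(det$membership$first_arrival_s, 300L)
})

test_that("empty input yields an empty event list, bad input errors", {
  expect_identical(nrow(detect_events(visits_df(integer(0)))$events), 0L)
  v <- visits_df(c(100, 200)); v$arrival_s[1] <- NA
  expect_error(detect_events(v), "non-finite")
})

test_that("every visit is assigned to exactly one event (partition)", {
  sim <- simulate_dataset(sim_config(
    n_sites_urban = 1, n_sites_rural = 0, birds_per_site = 8, n_weeks = 1,
    days_per_week = 3, seed = 31))
  day <- sim$stream$arrival_s %/% 86400
  for (d in unique(day)) {
    v <- sim$stream[day == d, ]
    det <- detect_events(v, seed = 2)
    expect_identical(length(det$assignment), nrow(v))
    expect_true(all(det$assignment %in% det$events$event_idx))
    # per-event member visit counts sum to the total visit count
    expect_identical(sum(tabulate(det$assignment)), nrow(v))
  }
})

test_that("returned events are ordered and non-overlapping in time", {
  sim <- simulate_dataset(sim_config(
    n_sites_urban = 1, n_sites_rural = 0, birds_per_site = 8, n_weeks = 1,
    days_per_week = 2, event_spacing_clumpiness = 0.8, seed = 17))
  day <- sim$stream$arrival_s %/% 86400
  for (d in unique(day)) {
    det <- detect_events(sim$stream[day == d, ], seed = 2)
    ev <- det$events
    if (nrow(ev) > 1) {
      expect_true(all(diff(ev$start_s) > 0))
      expect_true(all(ev$start_s[-1] > ev$end_s[-nrow(ev)]))
    }
  }
})

test_that("detection is invariant to a constant time shift", {
  v <- simulate_dataset(sim_config(
    n_sites_urban = 1, n_sites_rural = 0, birds_per_site = 6, n_weeks = 1,
    days_per_week = 1, seed = 13))$stream
  det1 <- detect_events(v, seed = 5)
  v2 <- v
  v2$arrival_s <- v2$arrival_s + 1000L
  v2$departure_s <- v2$departure_s + 1000L
  det2 <- detect_events(v2, seed = 5)
  expect_identical(det2$assignment, det1$assignment)
})

test_that("days with < 3 visits split on the bridge threshold", {
  v <- visits_df(c(100, 900), tags = c("A", "B"))
  expect_identical(nrow(detect_events(v, bridge_s = 600)$events), 2L)
  expect_identical(nrow(detect_events(v, bridge_s = 1000)$events), 1L)
})

test_that("inclusion filters implement the residency rules", {
  # bird K: >5 records in 5 weeks (kept); bird X: >5 records in 4 weeks
  # (excluded); bird E: exactly 5 records each week (never present)
  rows <- list()
  for (w in 1:5) {
    for (i in 1:6) rows[[length(rows) + 1L]] <-
        visits_df(86400 * 7 * (w - 1) + 30000 + i * 10, tags = "K")
    if (w <= 4) for (i in 1:6) rows[[length(rows) + 1L]] <-
        visits_df(86400 * 7 * (w - 1) + 40000 + i * 10, tags = "X")
    for (i in 1:5) rows[[length(rows) + 1L]] <-
        visits_df(86400 * 7 * (w - 1) + 50000 + i * 10, tags = "E")
  }
  stream <- do.call(rbind, rows)
  filt <- apply_inclusion_filters(stream, min_weeks = 5,
                                  min_weekly_records = 5)
  expect_identical(filt$roster$S1, "K")
  pres_E <- filt$presence[filt$presence$tag_id == "E", ]
  expect_identical(pres_E$n_records, rep(5L, 5))
  expect_false(any(pres_E$present))
  # relaxed inequality counts E's 5-record weeks as presence
  filt2 <- apply_inclusion_filters(stream, strict = FALSE)
  expect_setequal(filt2$roster$S1, c("K", "E"))
  # bird present in all weeks: presence row all TRUE
  pres_K <- filt$presence[filt$presence$tag_id == "K", ]
  expect_true(all(pres_K$present))
})

test_that("build_gbi transcribes events and drops emptied rows", {
  det <- structure(list(
    site_id = "S1", day = 0L,
    events = data.frame(event_idx = 1:3, start_s = c(0L, 100L, 200L),
                        end_s = c(50L, 150L, 250L),
                        n_individuals = c(2L, 1L, 1L),
                        duration_s = c(50L, 50L, 50L)),
    membership = data.frame(event_idx = c(1L, 1L, 2L, 3L),
                            tag_id = c("A", "B", "A", "C"),
                            first_arrival_s = c(0L, 1L, 100L, 200L)),
    assignment = c(1L, 1L, 2L, 3L)), class = "foraging_events")
  g <- build_gbi(list(det), roster = c("A", "B"))
  expect_identical(unclass(g)[seq_len(4)],
                   c(1L, 1L, 1L, 0L))  # rows {A,B}, {A}; row {C} dropped
  expect_identical(dim(g), c(2L, 2L))
  expect_identical(attr(g, "day"), c(0L, 0L))
  expect_error(build_gbi(list(det), roster = character(0)), "nonempty")
})

test_that("GBI row sums recover ground-truth attendance", {
  sim <- simulate_dataset(sim_config(
    n_sites_urban = 1, n_sites_rural = 0, birds_per_site = 6, n_weeks = 1,
    days_per_week = 7, seed = 41))
  g <- truth_gbis(sim)[["1"]]
  mem <- sim$truth$membership
  sizes <- as.integer(table(paste(mem$day, mem$event_idx)))
  expect_setequal(as.integer(rowSums(g)), sizes)
  expect_equal(colSums(g)[sort(unique(mem$tag_id))],
               vapply(split(mem$tag_id, mem$tag_id), length, 0)[
                 sort(unique(mem$tag_id))])
})

test_that("event-detection recovery on separated synthetic days", {
  # smaller replicate of the acceptance-scale check: clearly separated
  # bursts are recovered almost perfectly
  aris <- c()
  for (s in 1:4) {
    sim <- simulate_dataset(sim_config(
      n_sites_urban = 1, n_sites_rural = 0, birds_per_site = 8, n_weeks = 1,
      days_per_week = 4, events_per_day_mean = 5,
      event_spacing_clumpiness = 0.15, within_event_sd_s = 30,
      event_duration_mean_s = 200, seed = s))
    day <- sim$stream$arrival_s %/% 86400
    for (d in unique(day)) {
      ev <- sim$truth$events[sim$truth$events$day == d, ]
      if (nrow(ev) > 1 &&
          min(ev$start_s[-1] - ev$end_s[-nrow(ev)]) < 5 * 30) next
      det <- detect_events(sim$stream[day == d, ], seed = 7)
      aris <- c(aris, adjusted_rand_index(det$assignment,
                                          sim$truth$visit_event[day == d]))
    }
  }
  expect_gt(mean(aris), 0.9)
})
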
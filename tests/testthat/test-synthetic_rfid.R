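# Synthetic RFID generator: determinism, degenerate inputs, calibration of
# the clumpiness dial, rank-stability dial, stream round trips.

small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_sites_urban = 1, n_sites_rural = 0, birds_per_site = 6,
         n_weeks = 2, days_per_week = 2, events_per_day_mean = 4),
    list(...))
  do.call(sim_config, args)
}

test_that("identical configs give byte-identical streams and truth", {
  a <- simulate_dataset(small_cfg(seed = 11))
  b <- simulate_dataset(small_cfg(seed = 11))
  expect_identical(a, b)
  d <- simulate_dataset(small_cfg(seed = 12))
  expect_false(identical(a$stream, d$stream))
})

test_that("the generator leaves the caller's RNG stream untouched", {
  set.seed(1); before <- .Random.seed
  invisible(simulate_dataset(small_cfg(seed = 5)))
  expect_identical(.Random.seed, before)
})

test_that("every visit lies inside its day window and its event", {
  cfg <- small_cfg(seed = 3)
  sim <- simulate_dataset(cfg)
  tod <- sim$stream$arrival_s %% 86400
  expect_true(all(tod >= cfg$day_window[1] & tod <= cfg$day_window[2]))
  expect_true(all(sim$stream$departure_s >= sim$stream$arrival_s))
  # each visit maps to exactly one ground-truth event and falls inside it
  ev <- sim$truth$events[sim$truth$visit_event, ]
  expect_true(all(sim$stream$arrival_s >= ev$start_s &
                    sim$stream$arrival_s <= ev$end_s))
  expect_true(all(sim$stream$site_id == ev$site_id))
})

test_that("ground-truth events within a day never overlap", {
  sim <- simulate_dataset(small_cfg(seed = 9, event_spacing_clumpiness = 0.9))
  ev <- sim$truth$events
  for (key in unique(paste(ev$site_id, ev$day))) {
    e <- ev[paste(ev$site_id, ev$day) == key, ]
    e <- e[order(e$start_s), ]
    if (nrow(e) > 1)
      expect_true(all(e$start_s[-1] > e$end_s[-nrow(e)] - 1))
  }
})

test_that("birds_per_site = 0 yields an empty stream and membership", {
  sim <- simulate_dataset(small_cfg(birds_per_site = 0, seed = 2))
  expect_identical(nrow(sim$stream), 0L)
  expect_identical(nrow(sim$truth$membership), 0L)
})

test_that("a day too short for the requested events errors by name", {
  expect_error(sim_config(day_window = c(21600, 22600),
                          events_per_day_mean = 8,
                          event_duration_mean_s = 300),
               "too short")
})

test_that("ground-truth event count matches its Poisson design rate", {
  # 1 event/day, 1 day/week, 13 weeks -> mean 13 events per run
  n_ev <- vapply(1:200, function(s)
    nrow(simulate_dataset(sim_config(
      n_sites_urban = 1, n_sites_rural = 0, birds_per_site = 2,
      n_weeks = 13, days_per_week = 1, events_per_day_mean = 1,
      visits_per_attendance_mean = 1, seed = s))$truth$events), 0L)
  se <- sd(n_ev) / sqrt(length(n_ev))
  expect_lt(abs(mean(n_ev) - 13), 3 * se)
})

test_that("attendance_slope = 0 equalizes attendance across ranks", {
  # the subflock of an event is drawn uniformly, so at slope = 0 every
  # bird's marginal attendance law is identical: mean per-bird ground-truth
  # attendance must not depend on quality
  tot <- matrix(0, nrow = 100, ncol = 5)
  for (s in 1:100) {
    sim <- simulate_dataset(sim_config(
      n_sites_urban = 1, n_sites_rural = 0, birds_per_site = 5,
      n_weeks = 1, days_per_week = 3, events_per_day_mean = 5,
      attendance_slope = 0, size_trend_urban = 0, seed = s))
    tot[s, ] <- table(factor(sim$truth$membership$tag_id,
                             levels = sprintf("U1-B%02d", 1:5)))
  }
  m <- colMeans(tot)
  se <- apply(tot, 2, sd) / sqrt(nrow(tot))
  # every bird's mean attendance within ~3.5 SE of the grand mean
  expect_true(all(abs(m - mean(m)) < 3.5 * se))
})

test_that("rank-stability dial spans frozen to exchangeable orders", {
  sim0 <- simulate_dataset(small_cfg(rank_noise_sd = 0, n_weeks = 4, seed = 21))
  r0 <- sim0$truth$ranks
  byweek <- split(r0$latent_rank[order(r0$tag_id)], r0$week[order(r0$tag_id)])
  for (w in seq_along(byweek)[-1])
    expect_identical(byweek[[w]], byweek[[1]])
  # enormous noise: weekly orders uncorrelated on average
  cors <- unlist(lapply(1:40, function(s) {
    r <- simulate_dataset(small_cfg(rank_noise_sd = 100, n_weeks = 2,
                                    seed = s))$truth$ranks
    r <- r[order(r$week, r$tag_id), ]
    cor(r$latent_rank[r$week == 1], r$latent_rank[r$week == 2],
        method = "spearman")
  }))
  expect_lt(abs(mean(cors)), 3 * sd(cors) / sqrt(length(cors)) + 0.05)
})

test_that("clumpiness concentration inverts its expectation", {
  for (k in c(3, 6, 12)) for (target in c(0.1, 0.5, 0.9)) {
    a <- clumpiness_concentration(target, k)
    expect_equal(expected_clumpiness(a, k), target, tolerance = 1e-8)
  }
  # Monte-Carlo check of the closed form against direct Dirichlet draws
  set.seed(4)
  k <- 7; a <- clumpiness_concentration(0.5, k)
  sims <- replicate(4000, {
    g <- rgamma(k, a); p <- g / sum(g)
    1 + sum(p[p > 0] * log(p[p > 0])) / log(k)
  })
  expect_lt(abs(mean(sims) - 0.5), 3 * sd(sims) / sqrt(length(sims)))
})

test_that("stream files round-trip exactly", {
  sim <- simulate_dataset(small_cfg(seed = 6))
  path <- withr::local_tempfile(fileext = ".csv")
  write_stream(sim$stream, path)
  expect_identical(read_stream(path), sim$stream)
  # empty stream -> header-only file -> empty stream
  empty <- sim$stream[0, ]
  write_stream(empty, path)
  back <- read_stream(path)
  expect_identical(nrow(back), 0L)
  expect_identical(names(back), names(empty))
})

test_that("malformed stream rows are reported with line numbers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site_id,tag_id,arrival_s,departure_s",
               "S1,B01,100,110",
               "S1,B02,oops,120",
               "S1,B03,130,140"), path)
  expect_error(read_stream(path), "line\\(s\\) 3")
  writeLines(c("site_id,tag_id,arrival_s,departure_s",
               "S1,B01,200,110"), path)
  expect_error(read_stream(path), "departure before arrival")
})
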
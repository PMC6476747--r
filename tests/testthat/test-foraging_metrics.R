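# Entropy clumpiness statistic and daily summaries.

test_that("raw entropy matches closed forms", {
  expect_equal(raw_entropy(c(0.5, 0.5)), -log(2), tolerance = 1e-12)
  expect_equal(raw_entropy(c(1, 0)), 0)
  for (k in c(2, 5, 11))
    expect_equal(raw_entropy(rep(1 / k, k)), -log(k), tolerance = 1e-12)
  # scale invariance: proportions, not raw seconds
  expect_equal(raw_entropy(c(30, 60, 10)), raw_entropy(c(3, 6, 1)))
  expect_warning(v <- raw_entropy(c(0, 0)), "zero length")
  expect_true(is.na(v))
  expect_error(raw_entropy(c(-1, 2)), "nonnegative")
})

test_that("rescaled clumpiness hits its bounds and hand values", {
  for (n in c(1, 4, 9))
    expect_equal(rescaled_clumpiness(raw_entropy(rep(1, n + 1)), n), 0,
                 tolerance = 1e-12)
  expect_equal(rescaled_clumpiness(0, 5), 1)  # point mass
  expect_equal(rescaled_clumpiness(raw_entropy(c(0.01, 0.99)), 1),
               1 + (0.01 * log(0.01) + 0.99 * log(0.99)) / log(2),
               tolerance = 1e-12)
  expect_warning(v <- rescaled_clumpiness(-1, 0), "n < 1")
  expect_true(is.na(v))
})

test_that("clumpiness is weakly increasing under mass transfers", {
  # moving interval mass from a smaller to a larger interval never
  # decreases clumpiness (majorization)
  set.seed(2)
  for (i in 1:20) {
    x <- rexp(6)
    lo <- which.min(x); hi <- which.max(x)
    d <- 0.5 * x[lo]
    y <- x; y[lo] <- y[lo] - d; y[hi] <- y[hi] + d
    expect_gte(rescaled_clumpiness(raw_entropy(y), 5) + 1e-12,
               rescaled_clumpiness(raw_entropy(x), 5))
  }
})

test_that("clumpiness of arrivals matches hand-worked examples", {
  win <- c(0, 1000)
  # two birds at the same mid-window instant: intervals (.5, 0, .5)
  mem <- data.frame(first_arrival_s = c(500, 500))
  expect_equal(clumpiness_of_arrivals(mem, win), 1 - log(2) / log(3),
               tolerance = 1e-12)
  # one arrival mid-window: two equal intervals -> 0
  expect_equal(clumpiness_of_arrivals(
    data.frame(first_arrival_s = 500), win), 0, tolerance = 1e-12)
  # arrivals at centres of k equal cells -> near the minimum
  k <- 8
  mem3 <- data.frame(first_arrival_s = (seq_len(k) - 0.5) / k * 1000)
  expect_lt(clumpiness_of_arrivals(mem3, win), 0.02)
  expect_true(is.na(clumpiness_of_arrivals(
    data.frame(first_arrival_s = numeric(0)), win)))
})

test_that("clumpiness of events matches hand-worked examples", {
  win <- c(0, 1000)
  # one event exactly centred -> two equal gaps -> 0
  ev1 <- data.frame(start_s = 400, end_s = 600)
  expect_equal(clumpiness_of_events(ev1, win), 0, tolerance = 1e-12)
  # two back-to-back events mid-window: middle gap 0, equal outer gaps
  ev2 <- data.frame(start_s = c(400, 500), end_s = c(500, 600))
  expect_equal(clumpiness_of_events(ev2, win), 1 - log(2) / log(3),
               tolerance = 1e-12)
  # events filling the window -> degenerate
  ev3 <- data.frame(start_s = c(0, 500), end_s = c(500, 1000))
  expect_warning(v <- clumpiness_of_events(ev3, win), "zero length")
  expect_true(is.na(v))
  # scale invariance
  ev4 <- data.frame(start_s = c(100, 700), end_s = c(200, 750))
  expect_equal(clumpiness_of_events(ev4, win),
               clumpiness_of_events(ev4 * 7, win * 7), tolerance = 1e-12)
})

test_that("generator calibration closes the loop at moderate scale", {
  for (target in c(0.2, 0.8)) {
    sim <- simulate_dataset(sim_config(
      n_sites_urban = 1, n_sites_rural = 0, birds_per_site = 2,
      n_weeks = 6, days_per_week = 7, events_per_day_mean = 6,
      event_spacing_clumpiness = target, clump_jitter_sd_urban = 0,
      visits_per_attendance_mean = 1, seed = round(100 * target)))
    ev <- sim$truth$events
    cl <- vapply(split(ev, ev$day), function(e) {
      win <- e$day[1] * 86400 + c(21600, 64800)
      x <- diff(c(win[1], sort(e$start_s), win[2]))
      rescaled_clumpiness(raw_entropy(x), nrow(e))
    }, 0)
    expect_lt(abs(mean(cl) - target), 0.08)
  }
})

test_that("summarize_day aggregates events and visits consistently", {
  sim <- simulate_dataset(sim_config(
    n_sites_urban = 1, n_sites_rural = 0, birds_per_site = 6, n_weeks = 1,
    days_per_week = 2, seed = 19))
  day <- sim$stream$arrival_s %/% 86400
  d0 <- sort(unique(day))[1]
  det <- detect_events(sim$stream[day == d0, ], seed = 1)
  win <- d0 * 86400 + c(21600, 64800)
  out <- summarize_day(det, win)
  expect_identical(out$summary$n_visits, sum(day == d0))
  expect_identical(out$summary$n_events, nrow(det$events))
  expect_identical(sum(out$events$n_individuals), nrow(det$membership))
  expect_true(out$summary$clump_arrivals >= 0 &&
                out$summary$clump_arrivals <= 1)
  # a day with no visits
  empty <- detect_events(sim$stream[0, ])
  out0 <- summarize_day(empty, win)
  expect_identical(out0$summary$n_events, 0L)
  expect_true(is.na(out0$summary$clump_events))
})
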
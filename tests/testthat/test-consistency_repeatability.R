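# Sum-of-variance consistency statistic, permutation test, repeatability.

test_that("sum_of_variance matches hand computations", {
  # identical rank order every week -> SV = 0
  m <- cbind(c(1 / 3, 2 / 3, 1), c(1 / 3, 2 / 3, 1), c(1 / 3, 2 / 3, 1))
  expect_equal(sum_of_variance(m), 0)
  # two birds, two weeks, crossing normalized ranks -> 0.125 + 0.125
  m2 <- rbind(c(0.5, 1.0), c(1.0, 0.5))
  expect_equal(sum_of_variance(m2), 0.25)
  # additivity: constant birds contribute nothing
  alt <- c(1 / 3, 1, 1 / 3, 1)
  m3 <- rbind(rep(0.5, 4), rep(0.9, 4), rep(0.1, 4), alt)
  expect_equal(sum_of_variance(m3), var(alt))
  # week relabeling leaves SV unchanged
  perm <- sample(4)
  expect_equal(sum_of_variance(m3[, perm]), sum_of_variance(m3))
})

test_that("individuals with < 2 ranked weeks are excluded with a warning", {
  m <- rbind(c(0.5, 0.6, 0.7), c(0.2, NA, NA))
  expect_warning(sv <- sum_of_variance(m), "excluded")
  expect_equal(sv, var(c(0.5, 0.6, 0.7)))
})

test_that("consistency_test flags stable synthetic sites", {
  sim <- simulate_dataset(sim_config(
    n_sites_urban = 1, n_sites_rural = 0, birds_per_site = 10, n_weeks = 8,
    days_per_week = 7, rank_noise_sd = 0, seed = 3))
  gbis <- truth_gbis(sim)
  plan <- permutation_plan(n_networks = 100, swaps_between_saves = 10,
                           seed = 4)
  res <- suppressWarnings(consistency_test(gbis, plan))
  expect_named(res, c("degree", "eigen"))
  for (r in res) {
    expect_length(r$sv_null, 100)
    expect_equal(r$p, mean(r$sv_null < r$sv_obs))
    expect_lt(r$p, 0.05)
  }
  # identical plan -> identical result (seed determinism)
  res2 <- suppressWarnings(consistency_test(gbis, plan))
  expect_identical(res$degree$sv_null, res2$degree$sv_null)
  expect_error(consistency_test(gbis[1:3], plan), ">= 5 weekly networks")
})

test_that("SV_O grows with rank noise (consistency dial)", {
  mean_sv <- vapply(c(0, 0.5, 2), function(noise) {
    svs <- vapply(1:12, function(s) {
      sim <- simulate_dataset(sim_config(
        n_sites_urban = 1, n_sites_rural = 0, birds_per_site = 8,
        n_weeks = 6, days_per_week = 7, events_per_day_mean = 5,
        rank_noise_sd = noise, seed = 100 + s))
      rl <- lapply(truth_gbis(sim), flocknet:::ranks_from_gbi)
      flocknet:::sv_from_rank_list(lapply(rl, `[[`, "degree"))
    }, 0)
    mean(svs)
  }, 0)
  expect_true(all(diff(mean_sv) > 0))
})

test_that("repeatability recovers a known variance ratio", {
  # sigma2_group = sigma2_resid = 1 -> R = 0.5
  sim_rep <- function(seed, n_g = 40, n_per = 10, vg = 1) {
    set.seed(seed)
    g <- factor(rep(seq_len(n_g), each = n_per))
    data.frame(y = rnorm(n_g, 0, sqrt(vg))[as.integer(g)] +
                 rnorm(n_g * n_per), g = g)
  }
  d <- sim_rep(1)
  r <- adjusted_repeatability(d, "y", "g", n_boot = 100, seed = 2)
  expect_s3_class(r, "repeatability")
  expect_lt(abs(r$R - 0.5), 0.2)
  expect_true(r$ci[1] <= r$R && r$R <= r$ci[2])
  expect_lt(r$p, 0.01)
  # across replicates the mean estimate is close to truth
  ests <- vapply(1:15, function(s)
    adjusted_repeatability(sim_rep(s), "y", "g", n_boot = 0,
                           p_method = "none")$R, 0)
  expect_lt(abs(mean(ests) - 0.5), 0.05)
})

test_that("zero group variance is degenerate with R = 0", {
  set.seed(5)
  d <- data.frame(y = rnorm(200), g = factor(rep(1:20, each = 10)))
  r <- suppressWarnings(adjusted_repeatability(d, "y", "g", n_boot = 20,
                                               seed = 1))
  expect_true(r$degenerate)
  expect_lt(r$R, 0.05)
})

test_that("poisson repeatability works on the latent scale", {
  set.seed(8)
  n_g <- 30; n_per <- 8
  b <- rnorm(n_g, 0, 0.8)
  g <- factor(rep(seq_len(n_g), each = n_per))
  d <- data.frame(y = rpois(n_g * n_per, exp(1 + b[as.integer(g)])), g = g)
  r <- adjusted_repeatability(d, "y", "g", family = "poisson", n_boot = 0,
                              p_method = "lrt")
  expect_gt(r$R, 0.3)
  expect_lt(r$p, 0.01)
})

test_that("permutation p-value counts larger null repeatabilities", {
  expect_equal(repeatability_p_vs_null(0.9, c(0.1, 0.2, 0.3)), 0)
  expect_equal(repeatability_p_vs_null(0.2, c(0.1, 0.2, 0.3)), 1 / 3)
  expect_equal(repeatability_p_vs_null(0.15, seq(0, 0.3, length.out = 100)),
               0.5, tolerance = 0.02)
})

test_that("habitat comparison uses CI overlap", {
  mk <- function(lo, hi) structure(list(R = mean(c(lo, hi)), ci = c(lo, hi),
                                        ci_level = 0.84),
                                   class = "repeatability")
  expect_true(compare_habitats(mk(0.1, 0.3), mk(0.4, 0.6))$differs)
  cmp <- compare_habitats(mk(0.1, 0.45), mk(0.4, 0.6))
  expect_false(cmp$differs)
  expect_equal(cmp$overlap, 0.05)
  cmp2 <- compare_habitats(mk(0.2, 0.5), mk(0.2, 0.5))
  expect_false(cmp2$differs)
  expect_equal(cmp2$overlap, 0.3)
})
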
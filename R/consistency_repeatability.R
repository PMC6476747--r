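## Network consistency and repeatability. Consistency of individual network
## position is tested by the sum across individuals of the between-week
## variance of their normalized metric ranks (SV), compared against the same
## quantity on day-restricted data-stream permutations of every weekly
## matrix. Repeatability (the proportion of total variance explained by the
## grouping factor, after fixed-effect adjustment) is estimated from mixed
## models with parametric-bootstrap confidence intervals.

#' Individual-by-week table of normalized metric ranks
#'
#' @param networks list of `weekly_network` objects (one site).
#' @param metric `"degree"` or `"eigen"`.
#' @return numeric matrix, rows = individuals (union over weeks), columns =
#'   weeks; `NA` where an individual was not ranked that week.
#' @export
rank_table <- function(networks, metric = c("degree", "eigen")) {
  metric <- match.arg(metric)
  field <- if (metric == "degree") "rank_degree" else "rank_eigen"
  inds <- sort(unique(unlist(lapply(networks, `[[`, "individuals"))))
  out <- matrix(NA_real_, nrow = length(inds), ncol = length(networks),
                dimnames = list(inds, vapply(networks, function(n)
                  as.character(n$week_id), "")))
  for (j in seq_along(networks)) {
    v <- networks[[j]][[field]]
    out[names(v), j] <- v
  }
  out
}

#' Sum of rank variances (SV)
#'
#' Sums, over individuals, the sample variance (denominator n - 1) of each
#' individual's normalized rank across the weeks in which it was ranked.
#' Low SV means individuals hold similar relative positions week after week.
#' Individuals ranked in fewer than two weeks are excluded with a warning.
#'
#' @param ranks individual-by-week matrix from [rank_table()] (NAs allowed).
#' @return nonnegative numeric scalar.
#' @export
sum_of_variance <- function(ranks) {
  n_ok <- rowSums(!is.na(ranks))
  drop <- n_ok < 2
  if (any(drop))
    warning(sprintf("%d individual(s) with < 2 ranked weeks excluded from SV",
                    sum(drop)))
  ranks <- ranks[!drop, , drop = FALSE]
  if (nrow(ranks) == 0) return(0)
  sum(apply(ranks, 1, stats::var, na.rm = TRUE))
}

## fast path: normalized degree/eigen ranks straight from a binary matrix
ranks_from_gbi <- function(m) {
  mm <- matrix(as.numeric(m), nrow = nrow(m), dimnames = dimnames(m))
  seen <- colSums(mm) > 0
  if (sum(seen) < 2) return(NULL)
  mm <- mm[, seen, drop = FALSE]
  x <- crossprod(mm)
  n_i <- diag(x)
  sri <- x / (outer(n_i, n_i, "+") - x)
  diag(sri) <- 0
  wd <- rowSums(sri)
  ec <- if (all(sri == 0)) stats::setNames(numeric(nrow(sri)), rownames(sri))
  else {
    v <- abs(eigen(sri, symmetric = TRUE, only.values = FALSE)$vectors[, 1])
    stats::setNames(v / max(v), rownames(sri))
  }
  n <- length(wd)
  list(degree = rank(wd, ties.method = "average") / n,
       eigen = rank(ec, ties.method = "average") / n)
}

sv_from_rank_list <- function(rank_list, warn = FALSE) {
  rank_list <- Filter(Negate(is.null), rank_list)
  if (!length(rank_list)) return(0)
  inds <- sort(unique(unlist(lapply(rank_list, names))))
  m <- matrix(NA_real_, nrow = length(inds), ncol = length(rank_list),
              dimnames = list(inds, NULL))
  for (j in seq_along(rank_list)) m[names(rank_list[[j]]), j] <- rank_list[[j]]
  if (warn) return(sum_of_variance(m))
  n_ok <- rowSums(!is.na(m))
  m <- m[n_ok >= 2, , drop = FALSE]
  if (nrow(m) == 0) return(0)
  sum(apply(m, 1, stats::var, na.rm = TRUE))
}

#' Network-consistency permutation test for one site
#'
#' Computes the observed SV for weighted-degree and eigenvector-centrality
#' ranks across the site's weekly networks, then rebuilds both statistics at
#' every checkpoint of independent cumulative swap chains run on each weekly
#' group-by-individual matrix, giving the permutation null SV_R. The p-value
#' is the proportion of SV_R below SV_O (small observed variance = consistent
#' positions); positions are significantly consistent when p < 0.05.
#'
#' @param gbis list of `gbi` matrices, one per week of one site (>= 5 weekly
#'   networks required).
#' @param plan a [permutation_plan()].
#' @param metrics which metrics to test.
#' @return list of `consistency_result` objects (one per metric), each with
#'   `site_id`, `metric`, `n_individuals`, `sv_obs`, `sv_null` (length
#'   `plan$n_networks`) and `p`.
#' @export
consistency_test <- function(gbis, plan,
                             metrics = c("degree", "eigen")) {
  stopifnot(inherits(plan, "permutation_plan"))
  abort_if(length(gbis) < 5,
           "consistency_test: need >= 5 weekly networks, got %d", length(gbis))
  metrics <- match.arg(metrics, several.ok = TRUE)
  obs_ranks <- lapply(gbis, ranks_from_gbi)
  sv_obs <- vapply(metrics, function(mt)
    sv_from_rank_list(lapply(obs_ranks, `[[`, mt), warn = TRUE), 0)
  pair_list <- lapply(gbis, same_day_pairs)
  sv_null <- with_seed(plan$seed, {
    cur <- gbis
    out <- matrix(NA_real_, nrow = plan$n_networks, ncol = length(metrics),
                  dimnames = list(NULL, metrics))
    for (i in seq_len(plan$n_networks)) {
      for (w in seq_along(cur))
        cur[[w]] <- advance_chain(cur[[w]], plan$swaps_between_saves,
                                  pair_list[[w]])
      rl <- lapply(cur, ranks_from_gbi)
      for (mt in metrics)
        out[i, mt] <- sv_from_rank_list(lapply(rl, `[[`, mt))
    }
    out
  })
  n_ind <- length(unique(unlist(lapply(gbis, colnames))))
  site <- attr(gbis[[1]], "site_id")
  lapply(stats::setNames(metrics, metrics), function(mt) {
    structure(list(site_id = site, metric = mt, n_individuals = n_ind,
                   sv_obs = unname(sv_obs[mt]), sv_null = sv_null[, mt],
                   p = mean(sv_null[, mt] < sv_obs[mt])),
              class = "consistency_result")
  })
}

#' @export
print.consistency_result <- function(x, ...) {
  cat(sprintf("<consistency> site %s, %s ranks: SV_O = %.4g, p = %.3f (%d permutations)\n",
              x$site_id, x$metric, x$sv_obs, x$p, length(x$sv_null)))
  invisible(x)
}

## ---- adjusted repeatability ------------------------------------------------

## variance components + latent-scale distribution variance of a lme4 fit
variance_components <- function(fit, family, group) {
  vc <- lme4::VarCorr(fit)
  vars <- vapply(vc, function(m) m[1, 1], 0)
  if (family == "gaussian") {
    resid <- attr(vc, "sc")^2
  } else {
    # Poisson with log link: observation-level random effect absorbs
    # overdispersion; the distribution-specific variance on the latent scale
    # is log(1/lambda + 1) at the marginal mean (lognormal approximation)
    beta0 <- lme4::fixef(fit)[["(Intercept)"]]
    lambda <- exp(beta0 + 0.5 * sum(vars))
    resid <- log(1 / lambda + 1)
  }
  list(group = unname(vars[group]),
       other = sum(vars[setdiff(names(vars), group)]),
       residual = resid)
}

rep_from_fit <- function(fit, family, group) {
  v <- variance_components(fit, family, group)
  denom <- v$group + v$other + v$residual
  if (denom <= 0) return(0)
  v$group / denom
}

#' Adjusted repeatability from a mixed model
#'
#' Fits `response ~ fixed effects + (1 | group)` (plus an optional extra
#' random intercept) and returns the adjusted repeatability
#' `R = sigma^2_group / (sigma^2_group + sigma^2_other + sigma^2_residual)`,
#' i.e. the proportion of the variance not explained by the fixed effects
#' that is attributable to the grouping factor. Poisson responses use a log
#' link with an observation-level random effect for overdispersion, and R is
#' reported on the latent scale. Confidence intervals come from a seeded
#' parametric bootstrap (simulate from the fit, refit, percentile interval);
#' use `ci_level = 0.84` for the two-group interval-overlap comparison.
#'
#' @param data data.frame.
#' @param response name of the response column.
#' @param group name of the grouping-factor column (the repeatability
#'   target).
#' @param fixed character vector of fixed-effect terms (may include
#'   interactions), or `NULL` for intercept only.
#' @param random_extra optional name of an extra random-intercept column.
#' @param family `"gaussian"` or `"poisson"`.
#' @param n_boot parametric bootstrap draws (default 1,000).
#' @param ci_level central CI coverage (default 0.95).
#' @param p_method `"lrt"` for a boundary-corrected likelihood-ratio test of
#'   the group variance (p halved), `"none"` to skip (use
#'   [repeatability_p_vs_null()] against a permutation ensemble instead).
#' @param seed integer seed for the bootstrap.
#' @return object of class `repeatability`: list with `R`, `ci`, `ci_level`,
#'   `p`, `p_method`, `var_components`, `boot_R`, `n_boot_failed`,
#'   `degenerate` (TRUE when the group variance collapsed to ~0), `fit`.
#' @export
adjusted_repeatability <- function(data, response, group, fixed = NULL,
                                   random_extra = NULL,
                                   family = c("gaussian", "poisson"),
                                   n_boot = 1000L, ci_level = 0.95,
                                   p_method = c("lrt", "none"), seed = 1L) {
  family <- match.arg(family)
  p_method <- match.arg(p_method)
  abort_if(!response %in% names(data), "no column '%s' in data", response)
  abort_if(!group %in% names(data), "no column '%s' in data", group)
  data <- data[stats::complete.cases(
    data[, c(response, group, fixed_vars(fixed), random_extra), drop = FALSE]),
    , drop = FALSE]
  n_groups <- length(unique(data[[group]]))
  abort_if(n_groups < 2, "need >= 2 groups, got %d", n_groups)
  rhs <- c(if (is.null(fixed)) "1" else fixed,
           sprintf("(1 | %s)", group),
           if (!is.null(random_extra)) sprintf("(1 | %s)", random_extra))
  if (family == "poisson") {
    data$.obs <- factor(seq_len(nrow(data)))
    rhs <- c(rhs, "(1 | .obs)")
  }
  form <- stats::as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
  fit <- fit_mm(form, data, family)
  R <- rep_from_fit(fit, family, group)
  vcomp <- variance_components(fit, family, group)
  degenerate <- vcomp$group < 1e-8

  boot_R <- rep(NA_real_, n_boot)
  n_failed <- 0L
  if (n_boot > 0) {
    sims <- with_seed(seed, stats::simulate(fit, nsim = n_boot))
    for (b in seq_len(n_boot)) {
      boot_R[b] <- tryCatch(
        rep_from_fit(suppressWarnings(suppressMessages(
          lme4::refit(fit, newresp = sims[[b]]))), family, group),
        error = function(e) { n_failed <<- n_failed + 1L; NA_real_ })
    }
  }
  alpha <- (1 - ci_level) / 2
  ci <- if (all(is.na(boot_R))) c(NA_real_, NA_real_)
  else unname(stats::quantile(boot_R, c(alpha, 1 - alpha), na.rm = TRUE))

  p <- NA_real_
  if (p_method == "lrt") {
    rhs_red <- setdiff(rhs, sprintf("(1 | %s)", group))
    has_random <- any(grepl("\\(1 \\|", rhs_red))
    form_red <- stats::as.formula(
      paste(response, "~", paste(rhs_red, collapse = " + ")))
    fit_ml <- to_ml(fit, family)
    fit_red <- if (has_random) to_ml(fit_mm(form_red, data, family), family)
    else if (family == "gaussian") stats::lm(form_red, data)
    else stats::glm(form_red, data = data, family = stats::poisson())
    stat <- max(0, 2 * (as.numeric(stats::logLik(fit_ml)) -
                          as.numeric(stats::logLik(fit_red))))
    p <- 0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  structure(list(R = R, ci = ci, ci_level = ci_level, p = p,
                 p_method = p_method, var_components = vcomp,
                 boot_R = boot_R, n_boot_failed = n_failed,
                 degenerate = degenerate, response = response, group = group,
                 family = family, fit = fit), class = "repeatability")
}

fixed_vars <- function(fixed) {
  if (is.null(fixed)) return(NULL)
  unique(unlist(strsplit(fixed, "[:*]")))
}

fit_mm <- function(form, data, family) {
  if (family == "gaussian")
    suppressMessages(
      lme4::lmer(form, data = data, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore")))
  else
    suppressMessages(lme4::glmer(form, data = data, family = stats::poisson(),
                                 nAGQ = 0L,
                                 control = lme4::glmerControl(
                                   check.conv.singular = "ignore")))
}

to_ml <- function(fit, family) {
  if (family == "gaussian" && lme4::isREML(fit))
    suppressWarnings(lme4::refitML(fit))
  else fit
}

#' @export
print.repeatability <- function(x, ...) {
  cat(sprintf("<repeatability> %s by %s (%s): R = %.3f, %d%% CI [%.3f, %.3f], p = %s%s\n",
              x$response, x$group, x$family, x$R, round(100 * x$ci_level),
              x$ci[1], x$ci[2],
              if (is.na(x$p)) "NA" else format.pval(x$p, digits = 3),
              if (x$degenerate) " [degenerate: group variance ~ 0]" else ""))
  invisible(x)
}

#' Permutation p-value for a repeatability estimate
#'
#' @param observed observed repeatability (scalar or `repeatability`
#'   object).
#' @param null_R numeric vector of repeatabilities from randomized data.
#' @return proportion of null values larger than the observed one;
#'   significant repeatability at p < 0.05.
#' @export
repeatability_p_vs_null <- function(observed, null_R) {
  if (inherits(observed, "repeatability")) observed <- observed$R
  null_R <- null_R[!is.na(null_R)]
  abort_if(length(null_R) == 0, "null ensemble is empty")
  mean(null_R > observed)
}

#' Compare two repeatabilities by confidence-interval overlap
#'
#' Two groups are declared different when their 84% confidence intervals are
#' disjoint — approximately a 5%-level test of the difference, since
#' non-overlap of two 84% intervals corresponds to a 95% interval around the
#' difference excluding zero.
#'
#' @param rep_a,rep_b `repeatability` objects carrying CIs at matching
#'   levels (84% intended).
#' @return list with `differs` (logical) and `overlap` (length of the CI
#'   intersection; 0 when disjoint).
#' @export
compare_habitats <- function(rep_a, rep_b) {
  ci_a <- rep_a$ci; ci_b <- rep_b$ci
  abort_if(any(is.na(c(ci_a, ci_b))), "both results must carry finite CIs")
  overlap <- max(0, min(ci_a[2], ci_b[2]) - max(ci_a[1], ci_b[1]))
  list(differs = ci_a[2] < ci_b[1] || ci_b[2] < ci_a[1], overlap = overlap)
}
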
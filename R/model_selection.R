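## AICc-based mixed-model selection. For each foraging response the
## candidate set is every fixed-effect structure built from the main-effect
## atoms plus all two-way interactions that respect marginality (an
## interaction requires both its main effects), plus the null model
## (intercept + random effect). Candidates are fitted by maximum likelihood
## so their AICc values are comparable, ranked by Akaike weight, and the
## dAICc < 2 set is model-averaged.

#' Enumerate candidate fixed-effect structures
#'
#' @param atoms character vector of main-effect terms.
#' @param interactions include all marginality-respecting two-way
#'   interactions?
#' @return character vector of right-hand sides (`"1"` is the null model).
#' @export
candidate_formulas <- function(atoms = c("habitat", "month", "group_size"),
                               interactions = TRUE) {
  out <- character(0)
  n <- length(atoms)
  for (mask in 0:(2^n - 1)) {
    mains <- atoms[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    if (length(mains) == 0) { out <- c(out, "1"); next }
    pairs <- if (interactions && length(mains) >= 2)
      utils::combn(mains, 2, paste, collapse = ":") else character(0)
    np <- length(pairs)
    for (imask in 0:(2^np - 1)) {
      ints <- pairs[bitwAnd(imask, 2^(seq_len(max(np, 1)) - 1)) > 0]
      out <- c(out, paste(c(mains, ints), collapse = " + "))
    }
  }
  unique(out)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k + 1)/(n - k - 1)`; converges to AIC as
#' n grows. Undefined (NA, with a warning) when `n <= k + 1`.
#'
#' @param logLik log-likelihood (numeric).
#' @param k number of estimated parameters.
#' @param n number of observations.
#' @return numeric scalar.
#' @export
aicc <- function(logLik, k, n) {
  if (n <= k + 1) {
    warning(sprintf("AICc undefined for n = %d, k = %d (need n > k + 1)", n, k))
    return(NA_real_)
  }
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights
#'
#' `w_i = exp(-d_i/2) / sum_j exp(-d_j/2)` with `d_i = AICc_i - min(AICc)`;
#' the weights sum to 1 over the candidate set.
#'
#' @param aicc_values numeric vector of AICc values (NAs get weight NA and
#'   are excluded from the normalization).
#' @return numeric vector of weights.
#' @export
akaike_weights <- function(aicc_values) {
  abort_if(length(aicc_values) < 1, "need at least one model")
  d <- aicc_values - min(aicc_values, na.rm = TRUE)
  w <- exp(-d / 2)
  w / sum(w, na.rm = TRUE)
}

#' Fit the candidate model set for one response
#'
#' Every candidate is `response ~ <fixed structure> + (1 | random)`, fitted
#' by maximum likelihood (gaussian: `lmer` with `REML = FALSE`; poisson:
#' `glmer` with a log link). Non-convergent candidates are retained with a
#' flag and excluded from model averaging.
#'
#' @param data data.frame containing the response, the atoms and the random
#'   grouping column.
#' @param response response column name.
#' @param family `"gaussian"` or `"poisson"`.
#' @param atoms main-effect terms for [candidate_formulas()].
#' @param random random-intercept grouping column (default `"site_id"`).
#' @param interactions include two-way interactions?
#' @return object of class `candidate_set`: list with `response`, `family`,
#'   `models` (list of `list(rhs, fit, k, logLik, converged)`), `n`.
#' @export
fit_candidates <- function(data, response, family = c("gaussian", "poisson"),
                           atoms = c("habitat", "month", "group_size"),
                           random = "site_id", interactions = TRUE) {
  family <- match.arg(family)
  abort_if(!response %in% names(data), "no column '%s' in data", response)
  abort_if(length(unique(data[[random]])) < 2,
           "need >= 2 levels of the random grouping factor")
  data <- data[stats::complete.cases(
    data[, c(response, atoms, random), drop = FALSE]), , drop = FALSE]
  rhss <- candidate_formulas(atoms, interactions)
  models <- lapply(rhss, function(rhs) {
    form <- stats::as.formula(
      sprintf("%s ~ %s + (1 | %s)", response, rhs, random))
    converged <- TRUE
    fit <- withCallingHandlers(
      tryCatch({
        if (family == "gaussian")
          lme4::lmer(form, data = data, REML = FALSE,
                     control = lme4::lmerControl(check.conv.singular = "ignore"))
        else
          lme4::glmer(form, data = data, family = stats::poisson(),
                      nAGQ = 0L,
                      control = lme4::glmerControl(check.conv.singular = "ignore"))
      }, error = function(e) { converged <<- FALSE; NULL }),
      warning = function(w) {
        if (grepl("converge", conditionMessage(w))) converged <<- FALSE
        invokeRestart("muffleWarning")
      },
      message = function(m) invokeRestart("muffleMessage"))
    ll <- if (is.null(fit)) NA_real_ else as.numeric(stats::logLik(fit))
    k <- if (is.null(fit)) NA_integer_ else attr(stats::logLik(fit), "df")
    list(rhs = rhs, fit = fit, k = k, logLik = ll,
         converged = converged && !is.null(fit))
  })
  structure(list(response = response, family = family, models = models,
                 n = nrow(data)), class = "candidate_set")
}

#' Rank a candidate set by AICc
#'
#' @param cs a `candidate_set` from [fit_candidates()].
#' @return data.frame `model, k, logLik, AICc, dAICc, weight, converged`,
#'   sorted by AICc; weights computed over converged candidates.
#' @export
rank_models <- function(cs) {
  stopifnot(inherits(cs, "candidate_set"))
  tab <- data.frame(
    model = vapply(cs$models, `[[`, "", "rhs"),
    k = vapply(cs$models, function(m) as.integer(m$k), 0L),
    logLik = vapply(cs$models, function(m) as.numeric(m$logLik), 0),
    converged = vapply(cs$models, `[[`, TRUE, "converged"),
    stringsAsFactors = FALSE)
  tab$AICc <- mapply(function(ll, k, conv)
    if (!conv || is.na(ll)) NA_real_ else aicc(ll, k, cs$n),
    tab$logLik, tab$k, tab$converged)
  tab$dAICc <- tab$AICc - min(tab$AICc, na.rm = TRUE)
  tab$weight <- akaike_weights(tab$AICc)
  tab <- tab[order(tab$AICc), c("model", "k", "logLik", "AICc", "dAICc",
                                "weight", "converged")]
  rownames(tab) <- NULL
  tab
}

#' Model-average the competitive set
#'
#' Takes the converged candidates with `dAICc < cutoff`, renormalizes their
#' Akaike weights, and averages fixed-effect coefficients conditionally
#' (each coefficient over the models that contain it, with weights
#' renormalized over those models — "natural" averaging). Unconditional
#' standard errors combine within-model variance and between-model spread:
#' `SE = sum_i w_i * sqrt(se_i^2 + (b_i - b_bar)^2)`.
#'
#' @param cs a `candidate_set`.
#' @param ranking optional precomputed [rank_models()] table.
#' @param cutoff dAICc inclusion threshold (default 2).
#' @return data.frame `term, estimate, se, weight_sum, n_models`.
#' @export
model_average <- function(cs, ranking = rank_models(cs), cutoff = 2) {
  keep_rhs <- ranking$model[!is.na(ranking$dAICc) & ranking$dAICc < cutoff &
                              ranking$converged]
  abort_if(length(keep_rhs) == 0, "no converged model within the cutoff")
  rhss <- vapply(cs$models, `[[`, "", "rhs")
  idx <- match(keep_rhs, rhss)
  w <- ranking$weight[match(keep_rhs, ranking$model)]
  w <- w / sum(w)
  coefs <- lapply(idx, function(i) lme4::fixef(cs$models[[i]]$fit))
  ses <- lapply(idx, function(i)
    sqrt(diag(as.matrix(stats::vcov(cs$models[[i]]$fit)))))
  terms <- unique(unlist(lapply(coefs, names)))
  out <- lapply(terms, function(tm) {
    has <- vapply(coefs, function(cf) tm %in% names(cf), TRUE)
    wi <- w[has] / sum(w[has])
    b <- vapply(coefs[has], `[[`, 0, tm)
    s <- vapply(ses[has], `[[`, 0, tm)
    bbar <- sum(wi * b)
    data.frame(term = tm, estimate = bbar,
               se = sum(wi * sqrt(s^2 + (b - bbar)^2)),
               weight_sum = sum(w[has]), n_models = sum(has),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
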
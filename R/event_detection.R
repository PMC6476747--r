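## Burst detection: a one-dimensional Gaussian mixture over visit timestamps
## segments each site-day into group foraging events (bursts of increased
## feeder activity). Components are selected by BIC, visits are hard-assigned
## to their maximum-responsibility component, and components whose assigned
## time ranges overlap are merged, so the returned events partition the day's
## visits and never overlap in time.

## ---- 1-D Gaussian mixture with EM -----------------------------------------

## k-means++ style seeding on the timestamp vector
kmeanspp_centres <- function(t, k) {
  centres <- numeric(k)
  centres[1] <- t[sample.int(length(t), 1)]
  d2 <- (t - centres[1])^2
  if (k > 1) for (j in 2:k) {
    centres[j] <- if (sum(d2) <= 0) t[sample.int(length(t), 1)]
    else t[sample.int(length(t), 1, prob = d2)]
    d2 <- pmin(d2, (t - centres[j])^2)
  }
  centres
}

## EM for a k-component univariate GMM. Variances are floored (default
## (10 s)^2, roughly the antenna read granularity) so duplicate or
## near-duplicate timestamps cannot produce singular components, and so BIC
## does not shred tight bursts into per-read singletons.
fit_gmm1 <- function(t, k, centres, max_iter = 50, tol = 1e-5,
                     var_floor = 100) {
  n <- length(t)
  mu <- sort(centres)
  # seed component variances and weights from a nearest-centre partition;
  # a shared global variance would swamp the centre separation and collapse
  # the means onto the grand mean
  near <- max.col(-abs(outer(t, mu, "-")), ties.method = "first")
  sigma2 <- vapply(seq_len(k), function(j) {
    tj <- t[near == j]
    if (length(tj) < 2) var_floor else max(stats::var(tj), var_floor)
  }, 0)
  pi_k <- pmax(tabulate(near, k), 0.5) / n
  pi_k <- pi_k / sum(pi_k)
  ll_old <- -Inf
  resp <- NULL
  t2 <- t * t
  for (iter in seq_len(max_iter)) {
    # dense E-step written with flat vector ops (no dnorm/sweep overhead)
    z <- outer(t, mu, "-")
    dens <- exp(z * z * rep(-0.5 / sigma2, each = n)) *
      rep(pi_k / sqrt(2 * pi * sigma2), each = n)
    rs <- rowSums(dens)
    rs[rs <= 0 | !is.finite(rs)] <- .Machine$double.xmin
    ll <- sum(log(rs))
    resp <- dens / rs
    nk <- colSums(resp)
    nk[nk < 1e-10] <- 1e-10
    pi_k <- nk / n
    mu <- colSums(resp * t) / nk
    sigma2 <- pmax(colSums(resp * t2) / nk - mu * mu, var_floor)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  list(loglik = ll, mu = mu, sigma2 = sigma2, pi = pi_k,
       assign = max.col(resp, ties.method = "first"), k = k)
}

## Deterministic 1-D seeding: cut the sorted timestamps at the k - 1 largest
## gaps and take segment means. Near-optimal when bursts are separated.
gap_split_centres <- function(t, k) {
  ts <- sort(t)
  if (k == 1) return(mean(ts))
  gaps <- diff(ts)
  cuts <- sort(order(gaps, decreasing = TRUE)[seq_len(k - 1)])
  seg <- findInterval(seq_along(ts), cuts + 0.5) + 1L
  as.numeric(tapply(ts, seg, mean))
}

## Best-of-`restarts` GMM fit at a fixed k (restart 1 seeds from the largest
## gaps, restart 2 from quantiles, the rest k-means++); highest log-likelihood
## wins.
best_gmm1 <- function(t, k, restarts = 5, prev = NULL, var_floor = 100) {
  best <- NULL
  inits <- list(gap_split_centres(t, k),
                stats::quantile(t, probs = (seq_len(k) - 0.5) / k,
                                names = FALSE))
  if (!is.null(prev) && prev$k == k - 1) {
    # incremental init: split the widest component of the (k-1)-fit in two
    j <- which.max(prev$sigma2)
    s <- sqrt(prev$sigma2[j])
    inits <- c(inits, list(sort(c(prev$mu[-j], prev$mu[j] - s,
                                  prev$mu[j] + s))))
  }
  while (length(inits) < restarts)
    inits <- c(inits, list(kmeanspp_centres(t, k)))
  for (centres in inits) {
    fit <- fit_gmm1(t, k, centres, var_floor = var_floor)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best
}

## ---- event detection -------------------------------------------------------

#' Detect group foraging events in one site-day of visits
#'
#' Fits univariate Gaussian mixtures with K = 1..`max_components` components
#' to the arrival timestamps, picks K by minimum BIC (free parameters
#' 3K - 1), hard-assigns every visit to its maximum-responsibility component,
#' and merges components whose assigned arrival-departure spans overlap.
#' Days with fewer than three visits skip the mixture and are segmented by
#' arrival gaps larger than `bridge_s` (BIC is meaningless at n < 3).
#'
#' Detection is invariant to a constant shift of all timestamps, and is
#' deterministic: the restart RNG is seeded from `(seed, site, day)`.
#'
#' @param visits data.frame with columns `site_id, tag_id, arrival_s,
#'   departure_s`, all rows from the same site and day.
#' @param max_components upper bound on the number of mixture components
#'   (capped at the number of visits).
#' @param bridge_s gap threshold (s) for the small-day fallback segmentation.
#' @param seed integer seed from which the per-day restart stream is derived.
#' @param restarts EM restarts per K (best log-likelihood kept).
#' @param patience stop expanding K after this many consecutive BIC
#'   increases (never before 10 components have been tried).
#' @param min_sd_s floor on a component's standard deviation, in seconds
#'   (default 10, about the antenna read granularity); keeps BIC from
#'   shredding tight bursts into per-read components.
#' @return an object of class `foraging_events`: a list with `site_id`,
#'   `day`, `events` (data.frame `event_idx, start_s, end_s, n_individuals,
#'   duration_s`), `membership` (data.frame `event_idx, tag_id,
#'   first_arrival_s`), and `assignment` (event index per input visit row).
#'   Events are ordered by start time; start is the earliest member arrival
#'   and end the latest member departure.
#' @export
detect_events <- function(visits, max_components = 20L, bridge_s = 600,
                          seed = 1L, restarts = 5L, patience = 3L,
                          min_sd_s = 10) {
  if (is.null(visits) || nrow(visits) == 0)
    return(empty_events(NA_character_, NA_integer_))
  abort_if(!all(is.finite(visits$arrival_s)) ||
             !all(is.finite(visits$departure_s)),
           "detect_events: non-finite timestamp")
  site <- unique(visits$site_id)
  abort_if(length(site) != 1, "detect_events: visits span multiple sites")
  day <- unique(visits$arrival_s %/% SECONDS_PER_DAY)
  abort_if(length(day) != 1, "detect_events: visits span multiple days")
  n <- nrow(visits)
  t <- as.numeric(visits$arrival_s)

  if (n < 3) {
    ord <- order(t)
    grp <- cumsum(c(1L, as.integer(diff(t[ord]) > bridge_s)))
    assign <- integer(n); assign[ord] <- grp
  } else {
    t0 <- mean(t)  # centre for numerical stability / shift invariance
    ts <- t - t0
    kmax <- min(max_components, n)
    day_seed <- derive_seed(seed, site, day)
    assign <- with_seed(day_seed, {
      best_bic <- Inf; best_fit <- NULL; worse <- 0L; prev <- NULL
      min_scan <- min(10L, kmax)   # BIC can be locally bumpy at small K
      vf <- min_sd_s^2
      for (k in seq_len(kmax)) {
        fit <- if (k == 1) fit_gmm1(ts, 1, mean(ts), var_floor = vf)
        else best_gmm1(ts, k, restarts, prev = prev, var_floor = vf)
        prev <- fit
        bic <- -2 * fit$loglik + (3 * k - 1) * log(n)
        if (bic < best_bic) { best_bic <- bic; best_fit <- fit; worse <- 0L }
        else { worse <- worse + 1L
               if (worse >= patience && k >= min_scan) break }
      }
      best_fit$assign
    })
  }
  events_from_assignment(visits, assign, site, day)
}

empty_events <- function(site, day) {
  structure(list(
    site_id = site, day = day,
    events = data.frame(event_idx = integer(0), start_s = integer(0),
                        end_s = integer(0), n_individuals = integer(0),
                        duration_s = integer(0)),
    membership = data.frame(event_idx = integer(0), tag_id = character(0),
                            first_arrival_s = integer(0)),
    assignment = integer(0)), class = "foraging_events")
}

## Merge components whose assigned [min arrival, max departure] spans overlap,
## then materialise the event and membership tables.
events_from_assignment <- function(visits, assign, site, day) {
  comp <- sort(unique(assign))
  spans <- t(vapply(comp, function(cid) {
    idx <- assign == cid
    c(min(visits$arrival_s[idx]), max(visits$departure_s[idx]))
  }, numeric(2)))
  ord <- order(spans[, 1], spans[, 2])
  comp <- comp[ord]; spans <- spans[ord, , drop = FALSE]
  event_of_comp <- integer(length(comp))
  cur <- 1L; cur_end <- spans[1, 2]; event_of_comp[1] <- 1L
  if (length(comp) > 1) for (i in 2:length(comp)) {
    if (spans[i, 1] <= cur_end) {            # overlapping spans -> same event
      event_of_comp[i] <- cur
      cur_end <- max(cur_end, spans[i, 2])
    } else {
      cur <- cur + 1L; event_of_comp[i] <- cur; cur_end <- spans[i, 2]
    }
  }
  ev_assign <- event_of_comp[match(assign, comp)]
  n_ev <- max(ev_assign)
  ev <- lapply(seq_len(n_ev), function(e) {
    idx <- which(ev_assign == e)
    first <- tapply(visits$arrival_s[idx], visits$tag_id[idx], min)
    list(start = min(visits$arrival_s[idx]),
         end = max(visits$departure_s[idx]),
         members = names(first), first = as.integer(first))
  })
  events <- data.frame(
    event_idx = seq_len(n_ev),
    start_s = vapply(ev, function(x) as.integer(x$start), 0L),
    end_s = vapply(ev, function(x) as.integer(x$end), 0L))
  events$n_individuals <- vapply(ev, function(x) length(x$members), 0L)
  events$duration_s <- events$end_s - events$start_s
  membership <- do.call(rbind, lapply(seq_len(n_ev), function(e)
    data.frame(event_idx = e, tag_id = ev[[e]]$members,
               first_arrival_s = ev[[e]]$first, stringsAsFactors = FALSE)))
  rownames(membership) <- NULL
  structure(list(site_id = site, day = day, events = events,
                 membership = membership, assignment = ev_assign),
            class = "foraging_events")
}

#' @export
print.foraging_events <- function(x, ...) {
  cat(sprintf("<foraging_events> site %s day %s: %d events, %d visits\n",
              x$site_id, x$day, nrow(x$events), length(x$assignment)))
  invisible(x)
}

#' Detect events for every site-day of a stream
#'
#' Convenience wrapper splitting a multi-site stream by site and calendar day
#' and running [detect_events()] on each block.
#'
#' @param stream visit stream data.frame.
#' @inheritParams detect_events
#' @return list of `foraging_events`, one per non-empty site-day.
#' @export
detect_events_stream <- function(stream, max_components = 20L,
                                 bridge_s = 600, seed = 1L) {
  if (nrow(stream) == 0) return(list())
  day <- stream$arrival_s %/% SECONDS_PER_DAY
  keys <- paste(stream$site_id, day, sep = "\r")
  blocks <- split(seq_len(nrow(stream)), keys)
  # split() orders keys lexicographically; restore site/day order
  ord <- order(vapply(blocks, function(i) stream$site_id[i[1]], ""),
               vapply(blocks, function(i) day[i[1]], 0))
  lapply(blocks[ord], function(idx)
    detect_events(stream[idx, , drop = FALSE], max_components = max_components,
                  bridge_s = bridge_s, seed = seed))
}

## ---- inclusion filters -----------------------------------------------------

#' Residency inclusion filters
#'
#' A bird counts as present in a sampling week only when it was recorded
#' strictly more than `min_weekly_records` times that week (very low visit
#' frequency suggests a non-resident); birds present in fewer than
#' `min_weeks` weeks are excluded from all downstream matrices. The strict
#' inequality can be relaxed to `>=` via `strict = FALSE`.
#'
#' @param stream visit stream data.frame (the record counts are antenna
#'   reads, not event memberships).
#' @param min_weeks minimum number of present weeks to keep a bird.
#' @param min_weekly_records weekly visit-count threshold for presence.
#' @param strict if `TRUE` (default) presence requires count
#'   `> min_weekly_records`; if `FALSE`, `>=`.
#' @return list with `roster` (named list: site id -> character vector of
#'   kept tag ids) and `presence` (data.frame `site_id, tag_id, week,
#'   n_records, present`).
#' @export
apply_inclusion_filters <- function(stream, min_weeks = 5L,
                                    min_weekly_records = 5L, strict = TRUE) {
  if (nrow(stream) == 0)
    return(list(roster = list(),
                presence = data.frame(site_id = character(0),
                                      tag_id = character(0), week = integer(0),
                                      n_records = integer(0),
                                      present = logical(0))))
  week <- stream$arrival_s %/% SECONDS_PER_DAY %/% DAYS_PER_WEEK + 1L
  counts <- stats::aggregate(
    list(n_records = rep(1L, nrow(stream))),
    by = list(site_id = stream$site_id, tag_id = stream$tag_id, week = week),
    FUN = sum)
  counts$present <- if (strict) counts$n_records > min_weekly_records
  else counts$n_records >= min_weekly_records
  counts <- counts[order(counts$site_id, counts$tag_id, counts$week), ]
  rownames(counts) <- NULL
  weeks_present <- stats::aggregate(
    list(n_weeks = counts$present),
    by = list(site_id = counts$site_id, tag_id = counts$tag_id), FUN = sum)
  kept <- weeks_present[weeks_present$n_weeks >= min_weeks, , drop = FALSE]
  roster <- lapply(split(kept$tag_id, kept$site_id), sort)
  list(roster = roster, presence = counts)
}

## ---- group-by-individual matrices ------------------------------------------

#' Build a group-by-individual matrix for one site-week
#'
#' Under the gambit of the group, every individual recorded in the same
#' foraging event is taken to be associating with every other member of that
#' event; the week's events become the rows of a binary incidence matrix.
#' Events emptied by restriction to the roster are dropped, so no all-zero
#' rows occur. Row day labels (needed by the day-restricted permutation
#' scheme) are carried in `attr(, "day")`.
#'
#' @param detections list of `foraging_events` objects from one site-week.
#' @param roster character vector of included individuals (fixed column
#'   order: the roster is sorted).
#' @param site_id,week_id identifiers stored on the result.
#' @return binary matrix of class `gbi` (events x individuals) with
#'   attributes `day` (integer per row), `site_id`, `week_id`.
#' @export
build_gbi <- function(detections, roster, site_id = NA_character_,
                      week_id = NA_integer_) {
  abort_if(length(roster) == 0, "build_gbi: roster must be nonempty")
  roster <- sort(roster)
  rows <- list(); days <- integer(0)
  for (det in detections) {
    if (nrow(det$events) == 0) next
    for (e in det$events$event_idx) {
      mem <- det$membership$tag_id[det$membership$event_idx == e]
      mem <- intersect(mem, roster)
      if (length(mem) == 0) next               # emptied by roster restriction
      rows[[length(rows) + 1L]] <- as.integer(roster %in% mem)
      days <- c(days, det$day)
    }
  }
  m <- if (length(rows)) do.call(rbind, rows) else
    matrix(0L, nrow = 0, ncol = length(roster))
  colnames(m) <- roster
  structure(m, day = days, site_id = site_id, week_id = week_id,
            class = c("gbi", class(m)))
}

## split detections into site-weeks and build one GBI per site-week
#' Build weekly group-by-individual matrices for all sites
#'
#' @param detections list of `foraging_events` (any sites/days).
#' @param roster named list from [apply_inclusion_filters()].
#' @return nested list: `gbis[[site_id]][[as.character(week)]]` -> `gbi`;
#'   site-weeks with no events after restriction yield zero-row matrices and
#'   are dropped.
#' @export
build_weekly_gbis <- function(detections, roster) {
  out <- list()
  for (det in detections) {
    site <- det$site_id
    if (is.null(roster[[site]]) || length(roster[[site]]) == 0) next
    week <- as.character(det$day %/% DAYS_PER_WEEK + 1L)
    out[[site]][[week]] <- c(out[[site]][[week]], list(det))
  }
  lapply(out, function(weeks) {
    site <- weeks[[1]][[1]]$site_id
    g <- lapply(names(weeks), function(w)
      build_gbi(weeks[[w]], roster[[site]], site_id = site,
                week_id = as.integer(w)))
    names(g) <- names(weeks)
    g <- g[vapply(g, nrow, 0L) > 0]
    g[order(as.integer(names(g)))]
  })
}
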
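## Temporal clumpiness and daily foraging summaries. Clumpiness is the
## entropy of the interval lengths separating items (arrival points or event
## spans) within a day's recording window, rescaled so that 0 means evenly
## spread and 1 means maximally clustered in time.

#' Raw interval entropy
#'
#' Normalizes a vector of interval lengths to proportions p and returns
#' `sum(p * log(p))` (natural log, with the `0 * log 0 = 0` convention).
#' Always <= 0; equals `-log(k)` for k equal intervals (the minimum, by
#' convexity) and 0 when a single interval carries all mass.
#'
#' @param x nonnegative interval lengths (any time unit; scale-invariant).
#' @return numeric scalar, or `NA` with a warning when `sum(x) == 0`.
#' @export
raw_entropy <- function(x) {
  abort_if(any(!is.finite(x)) || any(x < 0),
           "raw_entropy: intervals must be finite and nonnegative")
  s <- sum(x)
  if (s == 0) {
    warning("raw_entropy undefined: all intervals have zero length")
    return(NA_real_)
  }
  p <- x / s
  p <- p[p > 0]
  sum(p * log(p))
}

#' Rescaled clumpiness
#'
#' Maps a raw interval entropy onto \[0, 1\] via its theoretical bounds for
#' `n + 1` intervals: `1 + H_p / log(n + 1)`. Equals 0 for perfectly even
#' spacing and 1 in the fully clumped limit, and makes days with different
#' item counts comparable.
#'
#' @param H_p raw entropy from [raw_entropy()].
#' @param n number of items (so `n + 1` intervals); must be >= 1.
#' @return numeric scalar in \[0, 1\], or `NA` with a warning when `n < 1`
#'   or `H_p` is missing.
#' @export
rescaled_clumpiness <- function(H_p, n) {
  if (is.na(H_p)) return(NA_real_)
  if (n < 1) {
    warning("rescaled_clumpiness undefined for n < 1")
    return(NA_real_)
  }
  1 + H_p / log(n + 1)
}

## interval vector for a sorted set of time points within [ws, we]
point_intervals <- function(points, ws, we) {
  points <- sort(points)
  diff(c(ws, points, we))
}

#' Clumpiness of arrivals
#'
#' The item set is every individual's first arrival to every foraging event
#' (one point per individual per event, duplicates kept); the statistic is
#' the rescaled entropy of the intervals between consecutive sorted points,
#' including the two boundary intervals to the window edges.
#'
#' @param detections a `foraging_events` object, or a membership data.frame
#'   with a `first_arrival_s` column.
#' @param day_window length-2 numeric, absolute window \[start, end\] in
#'   seconds for that day.
#' @return rescaled clumpiness in \[0, 1\], or `NA` when there are no
#'   arrivals.
#' @export
clumpiness_of_arrivals <- function(detections, day_window) {
  mem <- if (inherits(detections, "foraging_events")) detections$membership
  else detections
  pts <- mem$first_arrival_s
  if (length(pts) == 0) return(NA_real_)
  pts <- pmin(pmax(pts, day_window[1]), day_window[2])
  x <- point_intervals(pts, day_window[1], day_window[2])
  rescaled_clumpiness(raw_entropy(x), length(pts))
}

#' Clumpiness of events
#'
#' Treats each foraging event as a span from the arrival of the individual
#' that starts it to the departure of the last to leave; the statistic is the
#' rescaled entropy of the gaps between consecutive spans (plus the two
#' boundary gaps), normalized over total gap time. Events straddling the
#' window are clipped to it.
#'
#' @param events data.frame with `start_s`, `end_s` (or a `foraging_events`
#'   object).
#' @param day_window length-2 numeric window.
#' @return rescaled clumpiness in \[0, 1\]; `NA` with a warning when the
#'   events fill the window (no gap time, degenerate).
#' @export
clumpiness_of_events <- function(events, day_window) {
  ev <- if (inherits(events, "foraging_events")) events$events else events
  if (nrow(ev) == 0) return(NA_real_)
  s <- pmin(pmax(ev$start_s, day_window[1]), day_window[2])
  e <- pmin(pmax(ev$end_s, day_window[1]), day_window[2])
  ord <- order(s, e)
  s <- s[ord]; e <- e[ord]
  gaps <- c(s[1] - day_window[1],
            if (length(s) > 1) s[-1] - e[-length(e)],
            day_window[2] - e[length(e)])
  gaps <- pmax(gaps, 0)  # overlap-free by construction; guard clipping ties
  rescaled_clumpiness(raw_entropy(gaps), nrow(ev))
}

#' Daily foraging summary
#'
#' @param detections a `foraging_events` object for one site-day.
#' @param day_window length-2 absolute window for that day.
#' @return list with `summary` (one-row data.frame: `site_id, day, n_events,
#'   n_visits, clump_arrivals, clump_events`) and `events` (per-event rows:
#'   `site_id, day, event_idx, n_individuals, duration_s`).
#' @export
summarize_day <- function(detections, day_window) {
  stopifnot(inherits(detections, "foraging_events"))
  n_ev <- nrow(detections$events)
  smry <- data.frame(
    site_id = detections$site_id, day = detections$day,
    n_events = n_ev, n_visits = length(detections$assignment),
    clump_arrivals = if (n_ev > 0)
      clumpiness_of_arrivals(detections, day_window) else NA_real_,
    clump_events = if (n_ev > 0)
      clumpiness_of_events(detections, day_window) else NA_real_,
    stringsAsFactors = FALSE)
  ev <- if (n_ev > 0) data.frame(
    site_id = detections$site_id, day = detections$day,
    event_idx = detections$events$event_idx,
    n_individuals = detections$events$n_individuals,
    duration_s = detections$events$duration_s, stringsAsFactors = FALSE)
  else data.frame(site_id = character(0), day = integer(0),
                  event_idx = integer(0), n_individuals = integer(0),
                  duration_s = integer(0))
  list(summary = smry, events = ev)
}

#' Daily and event-level foraging metrics for a set of detections
#'
#' @param detections list of `foraging_events`.
#' @param day_window length-2 window in seconds from midnight (converted to
#'   each day's absolute window).
#' @return list with `daily` and `events` data.frames (see
#'   [summarize_day()]), each carrying a `habitat` column.
#' @export
foraging_metrics <- function(detections, day_window = c(21600, 64800)) {
  res <- lapply(detections, function(det) {
    win <- det$day * SECONDS_PER_DAY + day_window
    summarize_day(det, win)
  })
  daily <- do.call(rbind, lapply(res, `[[`, "summary"))
  events <- do.call(rbind, lapply(res, `[[`, "events"))
  if (is.null(daily)) return(list(daily = NULL, events = NULL))
  daily$habitat <- site_habitat(daily$site_id)
  events$habitat <- site_habitat(events$site_id)
  rownames(daily) <- rownames(events) <- NULL
  list(daily = daily, events = events)
}
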
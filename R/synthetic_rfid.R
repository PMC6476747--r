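## Synthetic RFID feeder-visit generator.
##
## Emulates winter flocks visiting one RFID feeder per site: several sites of
## two habitat types, a fixed roster per site, weekly sampling, foraging
## events as temporal bursts of visits, a latent dominance rank driving
## per-event attendance, and a tunable temporal clumpiness of event starts.
## Every simulated visit is tagged with its generating event, so downstream
## detection / network / consistency stages have parameter-recovery oracles.

#' Simulation configuration for the synthetic RFID generator
#'
#' All arguments have defaults matching a field-realistic deployment: eight
#' sites (four urban, four rural), rosters of ten birds, thirteen 7-day
#' sampling weeks, a 06:00-18:00 diurnal recording window, and a handful of
#' group foraging events per day.
#'
#' @param n_sites_urban,n_sites_rural number of sites per habitat type.
#' @param birds_per_site roster size per site (winter flocks run ~8-12).
#' @param n_weeks number of sampling weeks; the study design floor is 13.
#' @param days_per_week recorded days per calendar week (1..7).
#' @param day_window length-2 vector, recording window in seconds from
#'   midnight; default `c(21600, 64800)` i.e. 06:00-18:00.
#' @param events_per_day_mean Poisson mean of group foraging events per
#'   site-day.
#' @param event_spacing_clumpiness target rescaled temporal clumpiness of
#'   event start times within a day, in \[0, 1\] (0 = evenly spread,
#'   1 = maximally clustered).
#' @param event_duration_mean_s mean scheduled event duration (exponential).
#' @param within_event_sd_s spread (s) of visit arrival times inside a burst.
#' @param attendance_slope how steeply per-event attendance probability
#'   declines with latent rank, on the logit scale; 0 = all birds equal.
#' @param attendance_base attendance probability of a mid-ranked bird in the
#'   rates-only regime (`n_subflocks = 1`); ignored otherwise.
#' @param n_subflocks number of stable foraging subflocks per site. Each
#'   week the flock is partitioned into `n_subflocks` contiguous blocks of
#'   the weekly latent rank order; each foraging event "belongs" to one
#'   subflock, drawn uniformly, and members of that subflock attend with
#'   probability `subflock_in` while the rest leak in with probability
#'   `subflock_out` (both then tilted by the slope, trend and activity
#'   terms on the logit scale). Rank-adjacent birds therefore forage
#'   together in consistent subgroups — pairwise association structure
#'   beyond what the margins of the group-by-individual matrix encode,
#'   which is exactly the signal the data-stream permutation test detects:
#'   attendance *rates* alone are margin-sufficient, so a rates-only
#'   stream is itself a draw from the permutation null. Because the
#'   subflock is drawn uniformly per event, every bird's *marginal*
#'   attendance law is identical at `attendance_slope = 0` regardless of
#'   block sizes. Set `n_subflocks = 1` for the structureless, rates-only
#'   regime.
#' @param subflock_in,subflock_out attendance probability of subflock
#'   members / non-members at a neutral logit tilt.
#' @param activity_sd per-bird, per-week sd of a logit-scale activity offset;
#'   makes weekly observation counts fluctuate the way field data do, while
#'   the affinity structure stays put.
#' @param rank_noise_sd week-to-week sd of the latent quality score
#'   (quality scores are spaced 1 apart, so 0 freezes the rank order and
#'   values >> 1 make weekly orders exchangeable).
#' @param visits_per_attendance_mean mean number of feeder visits an
#'   attending bird makes during one event (>= 1).
#' @param dwell_mean_s mean visit dwell (departure - arrival), exponential.
#' @param duration_trend_urban,duration_trend_rural fractional change of the
#'   event-duration mean from the first to the last week, per habitat.
#' @param size_trend_urban,size_trend_rural logit-scale change in attendance
#'   probability from first to last week, per habitat (negative shrinks
#'   late-season event sizes).
#' @param clump_jitter_sd_urban,clump_jitter_sd_rural day-to-day sd of the
#'   clumpiness target per habitat; a smaller urban value makes urban
#'   clumpiness more repeatable, mirroring the contrast the pipeline is
#'   designed to detect.
#' @param seed integer seed; identical configs give byte-identical streams.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_sites_urban = 4L, n_sites_rural = 4L,
                       birds_per_site = 10L, n_weeks = 13L,
                       days_per_week = 7L,
                       day_window = c(21600L, 64800L),
                       events_per_day_mean = 8,
                       event_spacing_clumpiness = 0.5,
                       event_duration_mean_s = 300,
                       within_event_sd_s = 60,
                       attendance_slope = 2,
                       attendance_base = 0.6,
                       n_subflocks = 3L,
                       subflock_in = 0.9,
                       subflock_out = 0.05,
                       activity_sd = 1,
                       rank_noise_sd = 0.5,
                       visits_per_attendance_mean = 3,
                       dwell_mean_s = 10,
                       duration_trend_urban = 0.5,
                       duration_trend_rural = 0,
                       size_trend_urban = -0.6,
                       size_trend_rural = 0.15,
                       clump_jitter_sd_urban = 0.05,
                       clump_jitter_sd_rural = 0.15,
                       seed = 1L) {
  cfg <- list(
    n_sites_urban = as.integer(n_sites_urban),
    n_sites_rural = as.integer(n_sites_rural),
    birds_per_site = as.integer(birds_per_site),
    n_weeks = as.integer(n_weeks),
    days_per_week = as.integer(days_per_week),
    day_window = as.integer(day_window),
    events_per_day_mean = events_per_day_mean,
    event_spacing_clumpiness = event_spacing_clumpiness,
    event_duration_mean_s = event_duration_mean_s,
    within_event_sd_s = within_event_sd_s,
    attendance_slope = attendance_slope,
    attendance_base = attendance_base,
    n_subflocks = as.integer(n_subflocks),
    subflock_in = subflock_in,
    subflock_out = subflock_out,
    activity_sd = activity_sd,
    rank_noise_sd = rank_noise_sd,
    visits_per_attendance_mean = visits_per_attendance_mean,
    dwell_mean_s = dwell_mean_s,
    duration_trend_urban = duration_trend_urban,
    duration_trend_rural = duration_trend_rural,
    size_trend_urban = size_trend_urban,
    size_trend_rural = size_trend_rural,
    clump_jitter_sd_urban = clump_jitter_sd_urban,
    clump_jitter_sd_rural = clump_jitter_sd_rural,
    seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  for (f in c("n_sites_urban", "n_sites_rural", "birds_per_site", "n_weeks",
              "days_per_week"))
    abort_if(!is_count(cfg[[f]]), "sim_config: %s must be a nonnegative count", f)
  abort_if(cfg$n_weeks < 1, "sim_config: n_weeks must be >= 1")
  abort_if(cfg$days_per_week < 1 || cfg$days_per_week > 7,
           "sim_config: days_per_week must be in 1..7")
  abort_if(length(cfg$day_window) != 2 || cfg$day_window[1] >= cfg$day_window[2],
           "sim_config: day_window must satisfy start < end")
  abort_if(cfg$day_window[1] < 0 || cfg$day_window[2] > SECONDS_PER_DAY,
           "sim_config: day_window must lie within 0..86400 seconds")
  for (f in c("events_per_day_mean", "event_duration_mean_s",
              "within_event_sd_s", "visits_per_attendance_mean",
              "dwell_mean_s"))
    abort_if(!is.numeric(cfg[[f]]) || cfg[[f]] <= 0,
             "sim_config: %s must be > 0", f)
  abort_if(cfg$event_spacing_clumpiness < 0 || cfg$event_spacing_clumpiness > 1,
           "sim_config: event_spacing_clumpiness must lie in [0, 1]")
  abort_if(cfg$attendance_base <= 0 || cfg$attendance_base >= 1,
           "sim_config: attendance_base must lie in (0, 1)")
  abort_if(cfg$rank_noise_sd < 0, "sim_config: rank_noise_sd must be >= 0")
  abort_if(!is_count(cfg$n_subflocks) || cfg$n_subflocks < 1,
           "sim_config: n_subflocks must be a count >= 1")
  for (f in c("subflock_in", "subflock_out"))
    abort_if(cfg[[f]] <= 0 || cfg[[f]] >= 1,
             "sim_config: %s must lie in (0, 1)", f)
  abort_if(cfg$activity_sd < 0, "sim_config: activity_sd must be >= 0")
  win <- diff(cfg$day_window)
  need <- 2 * cfg$events_per_day_mean * (cfg$event_duration_mean_s + 1)
  abort_if(win < need,
           paste0("sim_config: day_window (%d s) is too short to place an ",
                  "expected %.1f events of mean duration %.0f s; require ",
                  "window >= 2 * events_per_day_mean * (event_duration_mean_s + 1)",
                  " = %.0f s"),
           win, cfg$events_per_day_mean, cfg$event_duration_mean_s, need)
  invisible(cfg)
}

#' Expected rescaled clumpiness of symmetric-Dirichlet interval proportions
#'
#' If the `k` interval proportions of a day are drawn from a symmetric
#' Dirichlet with concentration `alpha`, the expected Shannon sum
#' `E[sum p_i log p_i]` equals `digamma(alpha + 1) - digamma(k * alpha + 1)`,
#' so the expected rescaled clumpiness is
#' `1 + (digamma(alpha + 1) - digamma(k * alpha + 1)) / log(k)`.
#' Monotone decreasing in `alpha`, with limits 1 (`alpha -> 0`, all mass in
#' one interval) and 0 (`alpha -> Inf`, even spacing).
#'
#' @param alpha Dirichlet concentration (> 0).
#' @param k number of intervals (>= 2).
#' @return expected rescaled clumpiness in (0, 1).
#' @export
expected_clumpiness <- function(alpha, k) {
  abort_if(any(alpha <= 0), "alpha must be > 0")
  abort_if(k < 2, "k must be >= 2")
  1 + (digamma(alpha + 1) - digamma(k * alpha + 1)) / log(k)
}

#' Dirichlet concentration achieving a target expected clumpiness
#'
#' Inverts [expected_clumpiness()] in `alpha` by bisection. This is the
#' generator's calibration from the clumpiness dial to the interval sampler.
#'
#' @param target desired expected rescaled clumpiness, in (0, 1).
#' @param k number of intervals (>= 2).
#' @return concentration `alpha` such that
#'   `expected_clumpiness(alpha, k) == target`.
#' @export
clumpiness_concentration <- function(target, k) {
  abort_if(target <= 0 || target >= 1,
           "target clumpiness must lie strictly in (0, 1)")
  abort_if(k < 2, "k must be >= 2")
  f <- function(la) expected_clumpiness(exp(la), k) - target
  # expected_clumpiness is decreasing in alpha; bracket on log scale
  uniroot(f, lower = log(1e-8), upper = log(1e8), tol = 1e-12)$root |> exp()
}

site_ids <- function(cfg) {
  c(if (cfg$n_sites_urban > 0) sprintf("U%d", seq_len(cfg$n_sites_urban)),
    if (cfg$n_sites_rural > 0) sprintf("R%d", seq_len(cfg$n_sites_rural)))
}

#' Habitat type of a site id
#'
#' Synthetic site ids encode habitat in their prefix (`U` = urban,
#' `R` = rural); real data should supply an explicit site metadata table.
#'
#' @param site_id character vector of site ids.
#' @return character vector, `"urban"` or `"rural"`.
#' @export
site_habitat <- function(site_id) {
  ifelse(substr(site_id, 1, 1) == "U", "urban", "rural")
}

## Event-start schedule for one day: m starts placed by k = m + 1 interval
## proportions from a symmetric Dirichlet calibrated to the clumpiness target.
schedule_day_events <- function(m, window, target_clump, dur_mean) {
  ws <- window[1]; we <- window[2]
  if (m == 0) return(NULL)
  alpha <- clumpiness_concentration(target_clump, m + 1)
  g <- rgamma(m + 1, shape = alpha, rate = 1)
  if (sum(g) <= 0) g <- rep(1, m + 1)  # numerically degenerate tiny alpha
  props <- g / sum(g)
  starts <- ws + round((we - ws) * cumsum(props)[seq_len(m)])
  # integer rounding can collide (or hit the window end) under heavy
  # clumping; clamp into the window, then restore strict increase with a
  # forward and a backward pass — never drop events, which would bias the
  # realized clumpiness of extreme days
  starts <- pmin(pmax(starts, ws), we - 1L)
  if (m > 1) {
    for (i in 2:m) if (starts[i] <= starts[i - 1])
      starts[i] <- starts[i - 1] + 1L
    starts[m] <- min(starts[m], we - 1L)   # forward pass may re-overshoot
    for (i in (m - 1):1) if (starts[i] >= starts[i + 1])
      starts[i] <- starts[i + 1] - 1L
  }
  dur <- round(rexp(m, rate = 1 / dur_mean))
  ends <- pmin(starts + dur, we)
  if (m > 1) ends[seq_len(m - 1)] <- pmin(ends[seq_len(m - 1)],
                                          starts[-1] - 1L)
  ends <- pmax(ends, starts)
  cbind(start = starts, end = ends)
}

#' Simulate an RFID visitation dataset with ground truth
#'
#' Draws, per site and week, latent quality-plus-noise rank orders; per day, a
#' Poisson number of non-overlapping foraging events whose start times follow
#' the calibrated clumpiness target; per event, Bernoulli attendance declining
#' with latent rank; and per attending bird, one or more visits with normal
#' within-burst arrival spread and exponential dwell. Deterministic given
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a list with components
#'   \describe{
#'     \item{stream}{data.frame `site_id, tag_id, arrival_s, departure_s`,
#'       one row per antenna read, ordered by site and arrival.}
#'     \item{truth}{list with `events` (site_id, day, event_idx, week,
#'       start_s, end_s — the scheduled bursts), `membership` (site_id, day,
#'       event_idx, tag_id), `ranks` (site_id, week, tag_id, quality, score,
#'       latent_rank; rank 1 = most dominant), and `visit_event` (integer row
#'       index into `events` for every stream row).}
#'   }
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    sites <- site_ids(cfg)
    acc <- list()        # per-site-day visit blocks
    ev_acc <- list()     # per-site-day event blocks
    mem_acc <- list()
    rank_acc <- list()
    ev_counter <- 0L
    for (site in sites) {
      habitat <- site_habitat(site)
      dur_trend <- if (habitat == "urban") cfg$duration_trend_urban else cfg$duration_trend_rural
      size_trend <- if (habitat == "urban") cfg$size_trend_urban else cfg$size_trend_rural
      clump_jit <- if (habitat == "urban") cfg$clump_jitter_sd_urban else cfg$clump_jitter_sd_rural
      nb <- cfg$birds_per_site
      tags <- if (nb > 0) sprintf("%s-B%02d", site, seq_len(nb)) else character(0)
      quality <- seq_len(nb)
      for (w in seq_len(cfg$n_weeks)) {
        frac <- if (cfg$n_weeks > 1) (w - 1) / (cfg$n_weeks - 1) else 0
        score <- quality + rnorm(nb, 0, cfg$rank_noise_sd)
        latent_rank <- if (nb > 0) rank(-score, ties.method = "first") else integer(0)
        if (nb > 0)
          rank_acc[[length(rank_acc) + 1L]] <- data.frame(
            site_id = site, week = w, tag_id = tags,
            quality = quality, score = score, latent_rank = latent_rank,
            stringsAsFactors = FALSE)
        # attendance logit tilt: declines with rank, shifted by the habitat
        # size trend over the season and a weekly per-bird activity offset;
        # the per-event subflock term is added below
        rank_norm <- (latent_rank - 0.5) / max(nb, 1L)
        act_w <- rnorm(nb, 0, cfg$activity_sd)
        tilt <- size_trend * frac +
          cfg$attendance_slope * (0.5 - rank_norm) + act_w
        # weekly subflocks: contiguous blocks of this week's rank order
        sub_w <- if (cfg$n_subflocks > 1 && nb > 0)
          pmin(ceiling(rank_norm * cfg$n_subflocks), cfg$n_subflocks)
        else rep(1L, nb)
        dur_mean_w <- cfg$event_duration_mean_s * (1 + dur_trend * frac)
        for (d in seq_len(cfg$days_per_week)) {
          day_abs <- (w - 1L) * DAYS_PER_WEEK + (d - 1L)
          win <- day_abs * SECONDS_PER_DAY + cfg$day_window
          m <- rpois(1, cfg$events_per_day_mean)
          c_day <- min(max(cfg$event_spacing_clumpiness +
                             rnorm(1, 0, clump_jit), 0.02), 0.98)
          sched <- schedule_day_events(m, win, c_day, dur_mean_w)
          if (is.null(sched)) next
          m <- nrow(sched)
          ev_rows <- data.frame(
            site_id = site, day = day_abs, event_idx = seq_len(m),
            week = w, start_s = as.integer(sched[, "start"]),
            end_s = as.integer(sched[, "end"]), stringsAsFactors = FALSE)
          ev_acc[[length(ev_acc) + 1L]] <- ev_rows
          if (nb == 0) { ev_counter <- ev_counter + m; next }
          for (e in seq_len(m)) {
            ev_counter <- ev_counter + 1L
            p_att <- if (cfg$n_subflocks > 1) {
              ge <- sample.int(cfg$n_subflocks, 1)
              plogis(ifelse(sub_w == ge, qlogis(cfg$subflock_in),
                            qlogis(cfg$subflock_out)) + tilt)
            } else {
              plogis(qlogis(cfg$attendance_base) + tilt)
            }
            attend <- runif(nb) < p_att
            if (!any(attend)) next
            who <- tags[attend]
            mem_acc[[length(mem_acc) + 1L]] <- data.frame(
              site_id = site, day = day_abs, event_idx = e, tag_id = who,
              stringsAsFactors = FALSE)
            s0 <- sched[e, "start"]; s1 <- sched[e, "end"]
            centre <- (s0 + s1) / 2
            nv <- 1L + rpois(length(who),
                             max(0, cfg$visits_per_attendance_mean - 1))
            arr <- round(rnorm(sum(nv), centre, cfg$within_event_sd_s))
            arr <- pmin(pmax(arr, s0), s1)
            dep <- pmin(arr + round(rexp(sum(nv), 1 / cfg$dwell_mean_s)),
                        win[2])
            acc[[length(acc) + 1L]] <- data.frame(
              site_id = site, tag_id = rep(who, nv),
              arrival_s = as.integer(arr), departure_s = as.integer(dep),
              event_row = ev_counter, stringsAsFactors = FALSE)
          }
        }
      }
    }
    events <- if (length(ev_acc)) do.call(rbind, ev_acc) else
      data.frame(site_id = character(0), day = integer(0),
                 event_idx = integer(0), week = integer(0),
                 start_s = integer(0), end_s = integer(0))
    membership <- if (length(mem_acc)) do.call(rbind, mem_acc) else
      data.frame(site_id = character(0), day = integer(0),
                 event_idx = integer(0), tag_id = character(0))
    ranks <- if (length(rank_acc)) do.call(rbind, rank_acc) else
      data.frame(site_id = character(0), week = integer(0),
                 tag_id = character(0), quality = numeric(0),
                 score = numeric(0), latent_rank = integer(0))
    stream <- if (length(acc)) do.call(rbind, acc) else
      data.frame(site_id = character(0), tag_id = character(0),
                 arrival_s = integer(0), departure_s = integer(0),
                 event_row = integer(0))
    ord <- order(stream$site_id, stream$arrival_s, stream$tag_id,
                 stream$departure_s)
    stream <- stream[ord, , drop = FALSE]
    visit_event <- stream$event_row
    stream$event_row <- NULL
    rownames(stream) <- NULL
    rownames(events) <- rownames(membership) <- rownames(ranks) <- NULL
    list(stream = stream,
         truth = list(events = events, membership = membership,
                      ranks = ranks, visit_event = visit_event))
  })
}

#' Write / read an RFID visit stream
#'
#' The on-disk dialect is a plain CSV with header
#' `site_id,tag_id,arrival_s,departure_s` and integer-second timestamps;
#' `read_stream(write_stream(x, p))` is the identity.
#'
#' @param stream data.frame as produced by [simulate_dataset()].
#' @param path file path.
#' @return `write_stream`: the path, invisibly. `read_stream`: the stream
#'   data.frame.
#' @export
write_stream <- function(stream, path) {
  cols <- c("site_id", "tag_id", "arrival_s", "departure_s")
  abort_if(!all(cols %in% names(stream)),
           "stream must have columns %s", paste(cols, collapse = ", "))
  utils::write.csv(stream[, cols, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stream
#' @export
read_stream <- function(path) {
  abort_if(!file.exists(path), "no such stream file: %s", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  cols <- c("site_id", "tag_id", "arrival_s", "departure_s")
  abort_if(!identical(names(raw), cols),
           "malformed stream header in %s: expected %s", path,
           paste(cols, collapse = ","))
  if (nrow(raw) == 0)
    return(data.frame(site_id = character(0), tag_id = character(0),
                      arrival_s = integer(0), departure_s = integer(0)))
  bad <- which(!grepl("^-?[0-9]+$", raw$arrival_s) |
                 !grepl("^-?[0-9]+$", raw$departure_s))
  abort_if(length(bad) > 0,
           "malformed timestamp in %s at line(s) %s (1-based, incl. header)",
           path, paste(bad + 1L, collapse = ", "))
  out <- data.frame(site_id = raw$site_id, tag_id = raw$tag_id,
                    arrival_s = as.integer(raw$arrival_s),
                    departure_s = as.integer(raw$departure_s),
                    stringsAsFactors = FALSE)
  bad <- which(out$departure_s < out$arrival_s)
  abort_if(length(bad) > 0,
           "departure before arrival in %s at line(s) %s",
           path, paste(bad + 1L, collapse = ", "))
  out
}

#' Attach calendar columns to a visit stream
#'
#' Derives the absolute study day, 7-day sampling week, calendar date and
#' month from integer-second timestamps. Day 0 maps to `epoch`.
#'
#' @param stream a visit stream data.frame.
#' @param epoch Date of study day 0 (default the start of a nonbreeding
#'   season, "2014-11-01").
#' @return the stream with extra columns `day`, `week`, `date`, `month`.
#' @export
add_calendar <- function(stream, epoch = as.Date("2014-11-01")) {
  stream$day <- stream$arrival_s %/% SECONDS_PER_DAY
  stream$week <- stream$day %/% DAYS_PER_WEEK + 1L
  stream$date <- epoch + stream$day
  stream$month <- format(stream$date, "%Y-%m")
  stream
}
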
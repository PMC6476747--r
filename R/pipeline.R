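## End-to-end pipeline: simulate (or ingest) an RFID stream, detect events,
## build weekly networks, run the consistency and repeatability analyses,
## compute foraging metrics and their repeatability, and perform model
## selection — writing plain-CSV stage outputs plus a YAML manifest so that
## reruns with the same config are byte-identical.

#' Pipeline run configuration
#'
#' Bundles every stage's knobs. Stage toggles allow rerunning the tail of
#' the pipeline from stage outputs already on disk.
#'
#' @param sim a [sim_config()] (used by the `simulate` stage).
#' @param stream_file optional path to an existing stream CSV (skips
#'   simulation even when the `simulate` stage is enabled).
#' @param filters list: `min_weeks`, `min_weekly_records`, `strict`.
#' @param detection list: `max_components`, `bridge_s`.
#' @param permutation list: `n_networks`, `swaps_between_saves`.
#' @param repeatability list: `n_boot` (bootstrap draws; the methodological
#'   default is 1,000 — the pipeline default of 100 is a desk-scale choice,
#'   see the vignette), `n_perm` (randomized-network repeatabilities for
#'   permutation p-values).
#' @param day_window recording window, seconds from midnight.
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "detect", "networks", "consistency", "repeatability",
#'   "foraging", "foraging_repeatability", "selection")`; disabled stages
#'   read their inputs from `out_dir`.
#' @param seed global seed; every stage derives its own stream from it.
#' @return object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), stream_file = NULL,
                       filters = list(), detection = list(),
                       permutation = list(), repeatability = list(),
                       day_window = c(21600, 64800),
                       stages = c("simulate", "detect", "networks",
                                  "consistency", "repeatability", "foraging",
                                  "foraging_repeatability", "selection"),
                       seed = 1L) {
  defaults <- list(
    filters = list(min_weeks = 5L, min_weekly_records = 5L, strict = TRUE),
    detection = list(max_components = 20L, bridge_s = 600),
    permutation = list(n_networks = 1000L, swaps_between_saves = 10L),
    repeatability = list(n_boot = 100L, n_perm = 100L))
  merge1 <- function(d, u) { d[names(u)] <- u; d }
  cfg <- list(sim = sim, stream_file = stream_file,
              filters = merge1(defaults$filters, filters),
              detection = merge1(defaults$detection, detection),
              permutation = merge1(defaults$permutation, permutation),
              repeatability = merge1(defaults$repeatability, repeatability),
              day_window = day_window,
              stages = match.arg(stages, several.ok = TRUE),
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; the `sim` block
#' mirrors [sim_config()] field names.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$sim)) do.call(sim_config, y$sim) else sim_config()
  args <- y[setdiff(names(y), "sim")]
  args$sim <- sim
  do.call(run_config, args)
}

write_csv0 <- function(df, dir, name) {
  utils::write.csv(df, file.path(dir, name), row.names = FALSE, quote = FALSE)
}

stage_log <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(paste0("[flocknet] ", fmt), ...))
}

## reconstruct foraging_events objects from the events/membership CSVs
detections_from_tables <- function(events, membership) {
  keys <- unique(events[, c("site_id", "day")])
  lapply(seq_len(nrow(keys)), function(i) {
    site <- keys$site_id[i]; day <- keys$day[i]
    ev <- events[events$site_id == site & events$day == day, , drop = FALSE]
    mem <- membership[membership$site_id == site & membership$day == day,
                      , drop = FALSE]
    counts <- table(factor(mem$event_idx, levels = ev$event_idx))
    structure(list(
      site_id = site, day = day,
      events = data.frame(event_idx = ev$event_idx, start_s = ev$start_s,
                          end_s = ev$end_s,
                          n_individuals = as.integer(counts),
                          duration_s = ev$end_s - ev$start_s),
      membership = data.frame(event_idx = mem$event_idx, tag_id = mem$tag_id,
                              first_arrival_s = mem$first_arrival_s),
      assignment = integer(0)), class = "foraging_events")
  })
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order, writing each stage's outputs as CSV
#' under `out_dir` plus a `manifest.yaml` (config, seed, package version,
#' row counts — no timestamps, so reruns are byte-identical). A stage
#' failure halts the run with the stage name; outputs of completed stages
#' remain on disk.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress per-stage progress messages?
#' @return `out_dir`, invisibly.
#' @export
run_all <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  on_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    stage_log(quiet, "stage %-22s %6.1f s", name,
              proc.time()[["elapsed"]] - t0)
    res
  }
  counts <- list()

  ## -- simulate --------------------------------------------------------------
  stream <- NULL
  if (!is.null(config$stream_file)) {
    stream <- read_stream(config$stream_file)
  } else if ("simulate" %in% stages) {
    sim <- on_stage("simulate", {
      cfg <- config$sim
      cfg$seed <- derive_seed(config$seed, "simulate")
      class(cfg) <- "sim_config"
      simulate_dataset(cfg)
    })
    stream <- sim$stream
    write_csv0(stream, out_dir, "stream.csv")
    write_csv0(sim$truth$events, out_dir, "truth_events.csv")
    write_csv0(sim$truth$membership, out_dir, "truth_membership.csv")
    write_csv0(sim$truth$ranks, out_dir, "truth_ranks.csv")
  } else {
    stream <- read_stream(file.path(out_dir, "stream.csv"))
  }
  counts$stream <- nrow(stream)

  ## -- detect ----------------------------------------------------------------
  if ("detect" %in% stages) {
    detections <- on_stage("detect",
      detect_events_stream(stream,
                           max_components = config$detection$max_components,
                           bridge_s = config$detection$bridge_s,
                           seed = derive_seed(config$seed, "detect")))
    events <- do.call(rbind, lapply(detections, function(d)
      if (nrow(d$events)) cbind(site_id = d$site_id, day = d$day,
                                d$events[c("event_idx", "start_s", "end_s")])))
    membership <- do.call(rbind, lapply(detections, function(d)
      if (nrow(d$membership)) cbind(site_id = d$site_id, day = d$day,
                                    d$membership)))
    write_csv0(events, out_dir, "events.csv")
    write_csv0(membership, out_dir, "membership.csv")
  } else {
    events <- utils::read.csv(file.path(out_dir, "events.csv"),
                              stringsAsFactors = FALSE)
    membership <- utils::read.csv(file.path(out_dir, "membership.csv"),
                                  stringsAsFactors = FALSE)
    detections <- detections_from_tables(events, membership)
  }
  counts$events <- length(unique(paste(events$site_id, events$day,
                                       events$event_idx)))

  filt <- apply_inclusion_filters(stream,
                                  min_weeks = config$filters$min_weeks,
                                  min_weekly_records = config$filters$min_weekly_records,
                                  strict = config$filters$strict)
  roster_df <- do.call(rbind, lapply(names(filt$roster), function(s)
    data.frame(site_id = s, tag_id = filt$roster[[s]],
               stringsAsFactors = FALSE)))
  write_csv0(filt$presence, out_dir, "presence.csv")
  write_csv0(roster_df, out_dir, "roster.csv")
  counts$individuals_kept <- if (is.null(roster_df)) 0L else nrow(roster_df)
  gbis <- build_weekly_gbis(detections, filt$roster)

  ## -- networks --------------------------------------------------------------
  if ("networks" %in% stages) {
    networks <- on_stage("networks",
      lapply(unlist(gbis, recursive = FALSE), weekly_network))
    metrics <- network_metrics(networks)
    write_csv0(metrics, out_dir, "network_metrics.csv")
    # one labelled square SRI matrix per site-week
    nw_dir <- file.path(out_dir, "networks")
    dir.create(nw_dir, showWarnings = FALSE)
    for (nw in networks)
      utils::write.csv(as.data.frame(nw$sri),
                       file.path(nw_dir, sprintf("sri_%s_week%02d.csv",
                                                 nw$site_id, nw$week_id)))
  } else {
    metrics <- utils::read.csv(file.path(out_dir, "network_metrics.csv"),
                               stringsAsFactors = FALSE)
  }
  counts$site_weeks <- length(unique(paste(metrics$site_id, metrics$week_id)))

  ## -- consistency -----------------------------------------------------------
  if ("consistency" %in% stages) {
    cons <- on_stage("consistency", {
      rows <- list()
      for (site in names(gbis)) {
        if (length(gbis[[site]]) < 5) next
        plan <- permutation_plan(
          n_networks = config$permutation$n_networks,
          swaps_between_saves = config$permutation$swaps_between_saves,
          seed = derive_seed(config$seed, "consistency", site))
        res <- suppressWarnings(consistency_test(gbis[[site]], plan))
        for (r in res)
          rows[[length(rows) + 1L]] <- data.frame(
            site_id = site, habitat = site_habitat(site),
            n_individuals = r$n_individuals, metric = r$metric,
            sv_obs = r$sv_obs, p = r$p, stringsAsFactors = FALSE)
      }
      do.call(rbind, rows)
    })
    write_csv0(cons, out_dir, "consistency.csv")
  }

  ## -- network repeatability -------------------------------------------------
  if ("repeatability" %in% stages) {
    nr <- on_stage("repeatability",
      network_repeatability(gbis, metrics, config))
    write_csv0(nr$table, out_dir, "network_repeatability.csv")
    write_csv0(nr$comparison, out_dir, "network_habitat_comparison.csv")
  }

  ## -- foraging metrics ------------------------------------------------------
  if ("foraging" %in% stages) {
    fm <- on_stage("foraging", {
      fm <- foraging_metrics(detections, config$day_window)
      # fill recorded days that produced no events with zero counts
      fm$daily <- complete_daily(fm$daily, stream, config)
      fm
    })
    write_csv0(fm$daily, out_dir, "daily_foraging.csv")
    write_csv0(fm$events, out_dir, "event_foraging.csv")
  } else {
    fm <- list(
      daily = utils::read.csv(file.path(out_dir, "daily_foraging.csv"),
                              stringsAsFactors = FALSE),
      events = utils::read.csv(file.path(out_dir, "event_foraging.csv"),
                               stringsAsFactors = FALSE))
  }
  counts$site_days <- nrow(fm$daily)

  ## covariates shared by the two modelling stages
  roster_size <- vapply(filt$roster, length, 0L)
  add_covars <- function(df) {
    df$group_size <- as.integer(roster_size[df$site_id])
    df$month <- format(as.Date("2014-11-01") + df$day, "%Y-%m")
    df$habitat <- site_habitat(df$site_id)
    df
  }
  daily <- add_covars(fm$daily)
  evdat <- add_covars(fm$events)
  responses <- list(
    list(name = "duration_s", data = "event", family = "gaussian"),
    list(name = "n_individuals", data = "event", family = "poisson"),
    list(name = "n_events", data = "daily", family = "poisson"),
    list(name = "n_visits", data = "daily", family = "poisson"),
    list(name = "clump_arrivals", data = "daily", family = "gaussian"),
    list(name = "clump_events", data = "daily", family = "gaussian"))

  ## -- foraging repeatability ------------------------------------------------
  if ("foraging_repeatability" %in% stages) {
    fr <- on_stage("foraging_repeatability", {
      rows <- list(); comps <- list()
      for (resp in responses) {
        dat <- if (resp$data == "event") evdat else daily
        subs <- list(all = dat, urban = dat[dat$habitat == "urban", ],
                     rural = dat[dat$habitat == "rural", ])
        fits <- list()
        for (sn in names(subs)) {
          d <- subs[[sn]]
          if (length(unique(d$site_id)) < 2) next
          lvl <- if (sn == "all") 0.95 else 0.84
          fits[[sn]] <- suppressWarnings(adjusted_repeatability(
            d, resp$name, group = "site_id",
            fixed = c("group_size", "month", "day"),
            family = resp$family,
            n_boot = config$repeatability$n_boot, ci_level = lvl,
            p_method = "lrt",
            seed = derive_seed(config$seed, "frep", resp$name, sn)))
          rows[[length(rows) + 1L]] <- data.frame(
            metric = resp$name, subset = sn, R = fits[[sn]]$R,
            ci_low = fits[[sn]]$ci[1], ci_high = fits[[sn]]$ci[2],
            ci_level = lvl, p = fits[[sn]]$p, p_method = "lrt",
            stringsAsFactors = FALSE)
        }
        if (!is.null(fits$urban) && !is.null(fits$rural)) {
          cmp <- compare_habitats(fits$urban, fits$rural)
          comps[[length(comps) + 1L]] <- data.frame(
            metric = resp$name, differs = cmp$differs,
            overlap = cmp$overlap, stringsAsFactors = FALSE)
        }
      }
      list(table = rbind_or_empty(rows, empty_rep_table()),
           comparison = rbind_or_empty(comps, empty_comparison_table()))
    })
    write_csv0(fr$table, out_dir, "foraging_repeatability.csv")
    write_csv0(fr$comparison, out_dir, "foraging_habitat_comparison.csv")
  }

  ## -- model selection -------------------------------------------------------
  if ("selection" %in% stages) {
    on_stage("selection", {
      for (resp in responses) {
        dat <- if (resp$data == "event") evdat else daily
        cs <- fit_candidates(dat, resp$name, family = resp$family,
                             atoms = c("habitat", "month", "group_size"),
                             random = "site_id")
        ranking <- rank_models(cs)
        write_csv0(ranking, out_dir,
                   sprintf("model_rank_%s.csv", resp$name))
        write_csv0(model_average(cs, ranking), out_dir,
                   sprintf("model_average_%s.csv", resp$name))
      }
      invisible(NULL)
    })
  }

  manifest <- list(
    package = "flocknet",
    version = as.character(utils::packageVersion("flocknet")),
    seed = config$seed,
    stages = stages,
    config = config_to_list(config),
    rows = counts)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  validate_outputs(out_dir)
  invisible(out_dir)
}

rbind_or_empty <- function(rows, empty) {
  out <- do.call(rbind, rows)
  if (is.null(out)) empty else out
}

empty_rep_table <- function() data.frame(
  metric = character(0), subset = character(0), R = numeric(0),
  ci_low = numeric(0), ci_high = numeric(0), ci_level = numeric(0),
  p = numeric(0), p_method = character(0), stringsAsFactors = FALSE)

empty_comparison_table <- function() data.frame(
  metric = character(0), differs = logical(0), overlap = numeric(0),
  stringsAsFactors = FALSE)

config_to_list <- function(config) {
  out <- unclass(config)
  out$sim <- unclass(out$sim)
  out
}

## Complete the daily table over every recorded site-day and take the visit
## counts from the stream itself, so runs that rebuild detections from the
## on-disk event tables (which carry no per-visit assignments) produce the
## same table as in-memory runs.
complete_daily <- function(daily, stream, config) {
  day <- stream$arrival_s %/% SECONDS_PER_DAY
  cnt <- stats::aggregate(list(n_visits = rep(1L, nrow(stream))),
                          by = list(site_id = stream$site_id, day = day),
                          FUN = sum)
  miss <- cnt[!paste(cnt$site_id, cnt$day) %in%
                paste(daily$site_id, daily$day), , drop = FALSE]
  if (nrow(miss) > 0) {
    add <- data.frame(site_id = miss$site_id, day = miss$day, n_events = 0L,
                      n_visits = 0L, clump_arrivals = NA_real_,
                      clump_events = NA_real_,
                      habitat = site_habitat(miss$site_id),
                      stringsAsFactors = FALSE)
    daily <- rbind(daily, add)
  }
  idx <- match(paste(daily$site_id, daily$day), paste(cnt$site_id, cnt$day))
  daily$n_visits <- ifelse(is.na(idx), 0L, cnt$n_visits[idx])
  daily <- daily[order(daily$site_id, daily$day), ]
  rownames(daily) <- NULL
  daily
}

## Repeatability of normalized network ranks: grouping factor = individual,
## fixed effects month + week number; site enters as an extra random effect
## for the pooled model and as a fixed effect within habitat subsets (too few
## sites per habitat for a variance estimate). Permutation p-values compare
## the observed R to R recomputed on ensembles of day-restricted swaps.
network_repeatability <- function(gbis, metrics, config) {
  prep <- function(df) {
    df$week_num <- as.numeric(df$week_id)
    df$month <- format(as.Date("2014-11-01") + (df$week_id - 1L) * 7L, "%Y-%m")
    df$habitat <- site_habitat(df$site_id)
    df
  }
  dat <- prep(metrics)
  specs <- list(degree = "rank_degree", eigen = "rank_eigen")
  subsets <- list(all = dat, urban = dat[dat$habitat == "urban", ],
                  rural = dat[dat$habitat == "rural", ])
  fits <- list(); rows <- list(); comps <- list()
  for (mt in names(specs)) {
    for (sn in names(subsets)) {
      d <- subsets[[sn]]
      if (nrow(d) == 0) next
      multi_site <- length(unique(d$site_id)) > 1
      fixed <- c("month", "week_num",
                 if (sn != "all" && multi_site) "site_id")
      fit <- suppressWarnings(adjusted_repeatability(
        d, specs[[mt]], group = "tag_id", fixed = fixed,
        random_extra = if (sn == "all") "site_id" else NULL,
        family = "gaussian", n_boot = config$repeatability$n_boot,
        ci_level = if (sn == "all") 0.95 else 0.84, p_method = "none",
        seed = derive_seed(config$seed, "nrep", mt, sn)))
      fits[[paste(mt, sn)]] <- fit
    }
  }
  ## permutation null: R on randomized networks, shared swap chains
  n_perm <- config$repeatability$n_perm
  null_R <- array(NA_real_, dim = c(n_perm, length(specs), length(subsets)),
                  dimnames = list(NULL, names(specs), names(subsets)))
  flat <- unlist(gbis, recursive = FALSE)
  pair_list <- lapply(flat, same_day_pairs)
  sbs <- config$permutation$swaps_between_saves
  with_seed(derive_seed(config$seed, "nrep-null"), {
    cur <- flat
    for (r in seq_len(n_perm)) {
      for (w in seq_along(cur))
        cur[[w]] <- advance_chain(cur[[w]], sbs, pair_list[[w]])
      pm <- prep(network_metrics(lapply(cur, weekly_network)))
      psub <- list(all = pm, urban = pm[pm$habitat == "urban", ],
                   rural = pm[pm$habitat == "rural", ])
      for (mt in names(specs)) for (sn in names(subsets)) {
        d <- psub[[sn]]
        if (nrow(d) == 0) next
        multi_site <- length(unique(d$site_id)) > 1
        fixed <- c("month", "week_num",
                   if (sn != "all" && multi_site) "site_id")
        null_R[r, mt, sn] <- tryCatch(suppressWarnings(adjusted_repeatability(
          d, specs[[mt]], group = "tag_id", fixed = fixed,
          random_extra = if (sn == "all") "site_id" else NULL,
          family = "gaussian", n_boot = 0L, p_method = "none")$R),
          error = function(e) NA_real_)
      }
    }
  })
  for (mt in names(specs)) for (sn in names(subsets)) {
    key <- paste(mt, sn)
    if (is.null(fits[[key]])) next
    fit <- fits[[key]]
    p <- tryCatch(repeatability_p_vs_null(fit, null_R[, mt, sn]),
                  error = function(e) NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      metric = mt, subset = sn, R = fit$R, ci_low = fit$ci[1],
      ci_high = fit$ci[2], ci_level = fit$ci_level, p = p,
      p_method = "permutation", stringsAsFactors = FALSE)
  }
  for (mt in names(specs)) {
    fu <- fits[[paste(mt, "urban")]]; fr <- fits[[paste(mt, "rural")]]
    if (is.null(fu) || is.null(fr)) next
    cmp <- compare_habitats(fu, fr)
    comps[[length(comps) + 1L]] <- data.frame(
      metric = mt, differs = cmp$differs, overlap = cmp$overlap,
      stringsAsFactors = FALSE)
  }
  list(table = rbind_or_empty(rows, empty_rep_table()),
       comparison = rbind_or_empty(comps, empty_comparison_table()))
}

#' Validate pipeline outputs against the shipped column schemas
#'
#' @param dir pipeline output directory.
#' @return invisibly `TRUE`; errors when a CSV's header deviates from the
#'   schema shipped at `inst/schemas/outputs.yaml`.
#' @export
validate_outputs <- function(dir) {
  schema <- yaml::read_yaml(system.file("schemas", "outputs.yaml",
                                        package = "flocknet"))
  for (name in names(schema)) {
    files <- Sys.glob(file.path(dir, name))
    for (f in files) {
      hdr <- names(utils::read.csv(f, nrows = 1, check.names = FALSE))
      abort_if(!identical(hdr, schema[[name]]),
               "schema mismatch in %s: got [%s], expected [%s]",
               f, paste(hdr, collapse = ","),
               paste(schema[[name]], collapse = ","))
    }
  }
  invisible(TRUE)
}
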
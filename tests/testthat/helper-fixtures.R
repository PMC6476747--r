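# Programmatic fixtures shared across the suite.

# random binary group-by-individual matrix with day labels; rows are
# guaranteed nonempty
random_gbi <- function(n_events, n_birds, n_days = 2, p = 0.4,
                       site = "S1", week = 1L) {
  m <- matrix(rbinom(n_events * n_birds, 1, p), nrow = n_events)
  empty <- rowSums(m) == 0
  if (any(empty)) m[cbind(which(empty), sample.int(n_birds, sum(empty),
                                                   replace = TRUE))] <- 1L
  colnames(m) <- sprintf("B%02d", seq_len(n_birds))
  structure(m, day = sort(sample.int(n_days, n_events, replace = TRUE)),
            site_id = site, week_id = week,
            class = c("gbi", class(m)))
}

# brute-force SRI: literal pairwise event counting, independent of the
# crossprod implementation
brute_sri <- function(gbi) {
  m <- matrix(as.numeric(gbi), nrow = nrow(gbi), dimnames = dimnames(gbi))
  keep <- colSums(m) > 0
  m <- m[, keep, drop = FALSE]
  nb <- ncol(m)
  out <- matrix(0, nb, nb, dimnames = list(colnames(m), colnames(m)))
  for (a in seq_len(nb)) for (b in seq_len(nb)) {
    if (a == b) next
    x <- 0; ya <- 0; yb <- 0
    for (e in seq_len(nrow(m))) {
      if (m[e, a] == 1 && m[e, b] == 1) x <- x + 1
      else if (m[e, a] == 1) ya <- ya + 1
      else if (m[e, b] == 1) yb <- yb + 1
    }
    out[a, b] <- if (x + ya + yb == 0) 0 else x / (x + ya + yb)
  }
  out
}

# weekly ground-truth GBIs straight from the generator's truth tables
# (bypasses detection and the inclusion filters)
truth_gbis <- function(sim, site = NULL) {
  ev <- sim$truth$events
  mem <- sim$truth$membership
  if (!is.null(site)) {
    ev <- ev[ev$site_id == site, , drop = FALSE]
    mem <- mem[mem$site_id == site, , drop = FALSE]
  }
  roster <- sort(unique(sim$truth$ranks$tag_id[
    sim$truth$ranks$site_id %in% ev$site_id]))
  out <- list()
  for (w in sort(unique(ev$week))) {
    evw <- ev[ev$week == w, , drop = FALSE]
    rows <- list(); days <- integer(0)
    for (i in seq_len(nrow(evw))) {
      who <- mem$tag_id[mem$site_id == evw$site_id[i] &
                          mem$day == evw$day[i] &
                          mem$event_idx == evw$event_idx[i]]
      if (length(who) == 0) next
      rows[[length(rows) + 1L]] <- as.integer(roster %in% who)
      days <- c(days, evw$day[i])
    }
    if (length(rows) == 0) next
    m <- do.call(rbind, rows)
    colnames(m) <- roster
    out[[as.character(w)]] <- structure(
      m, day = days, site_id = evw$site_id[1], week_id = w,
      class = c("gbi", class(m)))
  }
  out
}

# tiny one-day visit table
visits_df <- function(arrivals, departures = arrivals + 5,
                      tags = sprintf("B%02d", seq_along(arrivals)),
                      site = "S1") {
  data.frame(site_id = rep(site, length(arrivals)), tag_id = tags,
             arrival_s = as.integer(arrivals),
             departure_s = as.integer(departures),
             stringsAsFactors = FALSE)
}

# exhaustive enumeration of all binary matrices with the given row and
# column sums (the margin-preserving fiber); returns a list of matrices
enumerate_fiber <- function(row_sums, col_sums, n_cols = length(col_sums)) {
  res <- list()
  recurse <- function(rows_done, col_left) {
    if (rows_done == length(row_sums)) {
      if (all(col_left == 0))
        res[[length(res) + 1L]] <<- do.call(rbind, acc)
      return(invisible())
    }
    k <- row_sums[rows_done + 1]
    for (cols in utils::combn(n_cols, k, simplify = FALSE)) {
      row <- integer(n_cols); row[cols] <- 1L
      if (any(col_left - row < 0)) next
      acc[[rows_done + 1]] <<- row
      recurse(rows_done + 1, col_left - row)
    }
  }
  acc <- vector("list", length(row_sums))
  recurse(0, col_sums)
  res
}
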
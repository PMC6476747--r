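## Data-stream permutations. The null model randomizes a group-by-individual
## matrix by checkerboard swaps restricted to events (rows) with the same day
## label: picking events e1, e2 on one day and individuals a in e1 only and
## b in e2 only, and exchanging them. Swaps preserve every row sum (event
## size), every column sum (individual observation count) and the per-day
## event structure, so ensembles of cumulatively swapped matrices provide the
## null distribution for any network statistic.

#' Permutation plan
#'
#' @param n_networks number of randomized networks (checkpoints) to record;
#'   the field standard is 1,000.
#' @param swaps_between_saves swaps performed between successive checkpoints
#'   of the cumulative chain (default 10, so 1,000 checkpoints span 10,000
#'   swaps).
#' @param seed integer seed for the swap stream.
#' @return object of class `permutation_plan`.
#' @export
permutation_plan <- function(n_networks = 1000L, swaps_between_saves = 10L,
                             seed = 1L) {
  abort_if(!is_count(n_networks) || n_networks < 1,
           "n_networks must be a positive count")
  abort_if(!is_count(swaps_between_saves) || swaps_between_saves < 1,
           "swaps_between_saves must be a positive count")
  structure(list(n_networks = as.integer(n_networks),
                 swaps_between_saves = as.integer(swaps_between_saves),
                 seed = as.integer(seed)), class = "permutation_plan")
}

## All unordered pairs of rows sharing a day label, as a 2 x n matrix.
same_day_pairs <- function(gbi) {
  days <- attr(gbi, "day")
  abort_if(is.null(days), "gbi has no day labels")
  pairs <- lapply(split(seq_len(nrow(gbi)), days), function(idx)
    if (length(idx) >= 2) utils::combn(idx, 2) else NULL)
  pairs <- Filter(Negate(is.null), pairs)
  if (!length(pairs)) matrix(integer(0), nrow = 2) else do.call(cbind, pairs)
}

## Does any checkerboard exist among the given same-day row pairs?
any_checkerboard <- function(gbi, pairs) {
  if (ncol(pairs) == 0) return(FALSE)
  for (j in seq_len(ncol(pairs))) {
    d <- gbi[pairs[1, j], ] - gbi[pairs[2, j], ]
    if (any(d > 0) && any(d < 0)) return(TRUE)
  }
  FALSE
}

#' One day-restricted checkerboard swap
#'
#' Picks uniformly among the valid checkerboard quadruples (same-day event
#' pair e1/e2, individuals a in e1 only and b in e2 only) by rejection
#' sampling, and exchanges a and b between the two events. If no valid
#' quadruple exists the matrix is returned unchanged with
#' `attr(, "swapped") = FALSE`.
#'
#' Uses the caller's RNG stream; wrap in a seeded context for
#' reproducibility.
#'
#' @param gbi binary `gbi` matrix with per-row day labels.
#' @param pairs optional precomputed [same_day_pairs()] matrix (the day
#'   structure is swap-invariant, so it can be reused along a chain).
#' @param max_tries rejection-sampling attempts before falling back to an
#'   exhaustive existence check.
#' @return the swapped matrix, with attribute `swapped` (logical).
#' @export
single_swap <- function(gbi, pairs = NULL, max_tries = 2000L) {
  if (is.null(pairs)) pairs <- same_day_pairs(gbi)
  nc <- ncol(gbi)
  if (ncol(pairs) == 0 || nc < 2) {
    attr(gbi, "swapped") <- FALSE
    return(gbi)
  }
  for (try in seq_len(max_tries)) {
    p <- pairs[, sample.int(ncol(pairs), 1)]
    ab <- sample.int(nc, 2)
    if (gbi[p[1], ab[1]] == 1 && gbi[p[2], ab[1]] == 0 &&
        gbi[p[1], ab[2]] == 0 && gbi[p[2], ab[2]] == 1) {
      gbi[p[1], ab[1]] <- 0L; gbi[p[2], ab[1]] <- 1L
      gbi[p[1], ab[2]] <- 1L; gbi[p[2], ab[2]] <- 0L
      attr(gbi, "swapped") <- TRUE
      return(gbi)
    }
  }
  # rejection failed: either no checkerboard exists, or they are very rare —
  # enumerate explicitly and sample uniformly among quadruples
  counts <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    d <- gbi[pairs[1, j], ] - gbi[pairs[2, j], ]
    counts[j] <- sum(d > 0) * sum(d < 0)
  }
  if (sum(counts) == 0) {
    attr(gbi, "swapped") <- FALSE
    return(gbi)
  }
  j <- sample.int(ncol(pairs), 1, prob = counts)
  d <- gbi[pairs[1, j], ] - gbi[pairs[2, j], ]
  a <- which(d > 0); b <- which(d < 0)
  a <- a[sample.int(length(a), 1)]; b <- b[sample.int(length(b), 1)]
  gbi[pairs[1, j], a] <- 0L; gbi[pairs[2, j], a] <- 1L
  gbi[pairs[1, j], b] <- 1L; gbi[pairs[2, j], b] <- 0L
  attr(gbi, "swapped") <- TRUE
  gbi
}

#' Advance a swap chain by several swaps
#'
#' Compiled equivalent of repeated [single_swap()] calls (same proposal law,
#' same R RNG stream, so seed-determinism is preserved); used by the
#' ensemble generators where the chain is the hot loop.
#'
#' @inheritParams single_swap
#' @param nswaps number of swaps to perform.
#' @return the randomized matrix, with attribute `n_noop` (swaps that found
#'   no checkerboard).
#' @export
advance_chain <- function(gbi, nswaps, pairs = NULL, max_tries = 2000L) {
  if (is.null(pairs)) pairs <- same_day_pairs(gbi)
  res <- advance_chain_cpp(matrix(as.integer(gbi), nrow = nrow(gbi)),
                           pairs[1, ], pairs[2, ], as.integer(nswaps),
                           as.integer(max_tries))
  out <- res$gbi
  dimnames(out) <- dimnames(gbi)
  for (a in c("day", "site_id", "week_id", "class"))
    attr(out, a) <- attr(gbi, a, exact = TRUE)
  attr(out, "n_noop") <- res$n_noop
  out
}

#' Null ensemble of a statistic along a cumulative swap chain
#'
#' Performs sequential swaps on `gbi`; after every `plan$swaps_between_saves`
#' swaps the statistic is evaluated on the current (increasingly randomized)
#' matrix and recorded, until `plan$n_networks` values are collected.
#' Statistic failures on a randomized matrix are recorded as `NA`, counted
#' and warned about. Seed-deterministic via `plan$seed`.
#'
#' @param gbi binary `gbi` matrix with day labels.
#' @param plan a [permutation_plan()].
#' @param statistic function of the (randomized) matrix; may return a scalar
#'   or a vector (vectors are returned as rows of a matrix).
#' @return numeric vector (or matrix, one row per checkpoint) of statistic
#'   values, with attribute `n_failed`.
#' @export
null_ensemble <- function(gbi, plan, statistic) {
  stopifnot(inherits(plan, "permutation_plan"))
  pairs <- same_day_pairs(gbi)
  with_seed(plan$seed, {
    cur <- gbi
    vals <- vector("list", plan$n_networks)
    n_failed <- 0L
    for (i in seq_len(plan$n_networks)) {
      cur <- advance_chain(cur, plan$swaps_between_saves, pairs)
      vals[[i]] <- tryCatch(statistic(cur), error = function(e) {
        n_failed <<- n_failed + 1L
        NA_real_
      })
    }
    lens <- lengths(vals)
    out <- if (max(lens) > 1) {
      vals[lens == 1] <- lapply(vals[lens == 1], function(v)
        rep(NA_real_, max(lens)))
      do.call(rbind, vals)
    } else unlist(vals)
    if (n_failed > 0)
      warning(sprintf("statistic failed on %d of %d randomized matrices",
                      n_failed, plan$n_networks))
    attr(out, "n_failed") <- n_failed
    out
  })
}

#' Draw one approximately independent null matrix
#'
#' Convenience: applies `n_swaps` cumulative swaps (a long burn-in) and
#' returns the final matrix. Used to manufacture datasets that are
#' themselves draws from the margin-preserving null.
#'
#' @param gbi binary `gbi` matrix with day labels.
#' @param n_swaps number of swaps (default 500).
#' @param seed integer seed.
#' @return a randomized `gbi` with identical margins.
#' @export
null_draw <- function(gbi, n_swaps = 500L, seed = 1L) {
  pairs <- same_day_pairs(gbi)
  with_seed(seed, advance_chain(gbi, n_swaps, pairs))
}
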
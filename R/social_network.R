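## Weekly association networks. Edges are simple ratio indices (SRI) computed
## from a binary group-by-individual matrix; node metrics are weighted degree
## and eigenvector centrality, each also expressed as a normalized within-week
## rank so that weeks with different network sizes are comparable.

#' Simple ratio index matrix from a group-by-individual matrix
#'
#' For a pair (a, b), SRI = x / (x + y_a + y_b) where x is the number of
#' events containing both and y_a (y_b) the number containing only a (only
#' b); under gambit-of-the-group sampling there are no simultaneous separate
#' sightings, so the denominator is simply the number of events containing a
#' or b. Ranges from 0 (never associating) to 1 (never detected apart).
#' Individuals appearing in no event are dropped from the matrix (the index
#' is undefined for them).
#'
#' @param gbi binary events x individuals matrix (class `gbi` or plain).
#' @return symmetric SRI matrix with zero diagonal, entries in \[0, 1\],
#'   attributes `site_id` / `week_id` copied from the input.
#' @export
sri_matrix <- function(gbi) {
  abort_if(nrow(gbi) < 1, "sri_matrix: need at least one event")
  abort_if(ncol(gbi) < 2, "sri_matrix: need at least two individuals")
  m <- matrix(as.numeric(gbi), nrow = nrow(gbi),
              dimnames = dimnames(gbi))
  seen <- colSums(m) > 0
  m <- m[, seen, drop = FALSE]
  x <- crossprod(m)                       # co-occurrence counts
  n_i <- diag(x)                          # events containing each individual
  denom <- outer(n_i, n_i, "+") - x       # events containing a or b
  sri <- x / denom
  sri[denom == 0] <- 0                    # only possible off the kept set
  diag(sri) <- 0
  structure(sri, site_id = attr(gbi, "site_id"),
            week_id = attr(gbi, "week_id"))
}

#' Weighted degree centrality
#'
#' Sum of an individual's edge weights: its number and strength of direct
#' connections, a general gregariousness measure.
#'
#' @param sri symmetric association matrix.
#' @return named numeric vector.
#' @export
weighted_degree <- function(sri) rowSums(sri)

#' Eigenvector centrality of a weighted association matrix
#'
#' The principal eigenvector of the full SRI matrix, taken elementwise
#' nonnegative and rescaled to a maximum of 1. Disconnected weekly networks
#' are handled on the whole matrix (the dominant component carries the mass),
#' matching the limit of power iteration; set `componentwise = TRUE` to
#' rescale within each connected component instead.
#'
#' @param sri symmetric association matrix.
#' @param componentwise rescale per connected component?
#' @return named numeric vector in \[0, 1\]; all zeros for an empty matrix.
#' @export
eigenvector_centrality <- function(sri, componentwise = FALSE) {
  n <- nrow(sri)
  out <- stats::setNames(numeric(n), rownames(sri))
  if (n == 0 || all(sri == 0)) return(out)
  if (!componentwise) {
    v <- abs(eigen(sri, symmetric = TRUE)$vectors[, 1])
    return(stats::setNames(v / max(v), rownames(sri)))
  }
  comp <- connected_components(sri > 0)
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    if (length(idx) == 1 || all(sri[idx, idx] == 0)) { out[idx] <- 0; next }
    v <- abs(eigen(sri[idx, idx], symmetric = TRUE)$vectors[, 1])
    out[idx] <- v / max(v)
  }
  out
}

connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (comp[v] > 0) next
      comp[v] <- cur
      stack <- c(stack, which(adj[v, ] & comp == 0))
    }
  }
  comp
}

#' Normalized within-week ranks
#'
#' Ascending ranks with average ties, divided by the number of individuals
#' ranked that week, mapping any metric onto a size-free (0, 1] scale so that
#' rank variances are comparable across weeks and sites of different sizes.
#'
#' @param values numeric vector of a metric for one week.
#' @param n_present divisor; defaults to `length(values)`.
#' @return numeric vector in (0, 1].
#' @export
normalized_ranks <- function(values, n_present = length(values)) {
  abort_if(length(values) < 1, "normalized_ranks: need at least one value")
  rank(values, ties.method = "average") / n_present
}

#' Build a weekly network with node metrics
#'
#' @param gbi group-by-individual matrix for one site-week.
#' @return object of class `weekly_network`: list with `site_id`, `week_id`,
#'   `individuals`, `sri`, `weighted_degree`, `eigen_centrality`,
#'   `rank_degree`, `rank_eigen` (normalized ranks).
#' @export
weekly_network <- function(gbi) {
  sri <- sri_matrix(gbi)
  wd <- weighted_degree(sri)
  ec <- eigenvector_centrality(sri)
  structure(list(
    site_id = attr(gbi, "site_id"), week_id = attr(gbi, "week_id"),
    individuals = rownames(sri), sri = sri,
    weighted_degree = wd, eigen_centrality = ec,
    rank_degree = normalized_ranks(wd),
    rank_eigen = normalized_ranks(ec)), class = "weekly_network")
}

#' @export
print.weekly_network <- function(x, ...) {
  cat(sprintf("<weekly_network> site %s week %s: %d individuals, mean SRI %.3f\n",
              x$site_id, x$week_id, length(x$individuals),
              mean(x$sri[upper.tri(x$sri)])))
  invisible(x)
}

#' Long-format node metrics for a set of weekly networks
#'
#' @param networks list of `weekly_network` objects.
#' @return data.frame `site_id, week_id, tag_id, weighted_degree,
#'   eigen_centrality, rank_degree, rank_eigen`.
#' @export
network_metrics <- function(networks) {
  out <- lapply(networks, function(nw) data.frame(
    site_id = nw$site_id, week_id = nw$week_id, tag_id = nw$individuals,
    weighted_degree = unname(nw$weighted_degree),
    eigen_centrality = unname(nw$eigen_centrality),
    rank_degree = unname(nw$rank_degree),
    rank_eigen = unname(nw$rank_eigen), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
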
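#' @keywords internal
#' @import stats
#' @importFrom Rcpp evalCpp
#' @useDynLib flocknet, .registration = TRUE
"_PACKAGE"

## Seconds per day; the generator's calendar is integer seconds since an
## epoch date, so civil days are flat 86400-s blocks and weeks are 7 days.
SECONDS_PER_DAY <- 86400L
DAYS_PER_WEEK <- 7L

#' Run code with a private, restored RNG state
#'
#' Evaluates `expr` after seeding the Mersenne-Twister stream with `seed`,
#' then restores whatever `.Random.seed` held before (including "unset").
#' All stochastic entry points in the package route their randomness through
#' this helper so that callers' RNG streams are never disturbed.
#'
#' @param seed integer scalar seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

#' Derive a child seed from a parent seed and string labels
#'
#' Deterministic, order-sensitive hash of the parent seed plus any number of
#' labels (site ids, day indices, stage names), folded into [0, 2^31 - 2].
#' Used to give every site-day / stage its own reproducible stream.
#'
#' @param seed parent integer seed.
#' @param ... labels (coerced to character).
#' @return integer scalar in [0, 2147483646].
#' @keywords internal
derive_seed <- function(seed, ...) {
  m <- 2147483647  # 2^31 - 1, kept in double arithmetic to avoid overflow
  h <- as.numeric(seed) %% m
  for (lab in as.character(unlist(list(...)))) {
    for (code in utf8ToInt(lab)) h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

## stopifnot() with a formatted message
abort_if <- function(cond, fmt, ...) {
  if (cond) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x >= 0 && x == floor(x)

#' Adjusted Rand index between two partitions
#'
#' Agreement between two labelings of the same items, corrected for chance;
#' 1 means identical partitions, ~0 means unrelated. Used by the
#' event-detection recovery tests to compare recovered and true visit
#' partitions.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  abort_if(length(a) != length(b), "partitions must have equal length")
  if (length(a) == 0) return(NaN)
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}
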
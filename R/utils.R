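#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

stop_vt <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Derive independent substream seeds from a master seed
#'
#' One master seed governs all randomness; per-iteration substreams (bootstrap
#' replicates, permutations, repeated simulations) use seeds derived
#' deterministically from it so that iteration `i` is reproducible in
#' isolation.
#'
#' @param seed Master seed (single integer).
#' @param n Number of substream seeds to derive.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(n), n >= 0)
  if (n == 0) return(integer(0))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(2147483645L, as.integer(n), replace = FALSE)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items:
#' 1 for identical partitions (up to renaming), approximately 0 for
#' independent ones.
#'
#' @param a,b Vectors of cluster labels (any atomic type), same length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop_vt("label vectors differ in length (%d vs %d)", length(a), length(b))
  if (length(a) == 0L) stop_vt("empty label vectors")
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  expected <- sum_i * sum_j / comb2(n)
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(ifelse(sum_ij == max_index, 1, 0))
  (sum_ij - expected) / (max_index - expected)
}

## Minimal misassignment count between a predicted partition and reference
## labels: best matching over permutations of predicted cluster names
## (feasible for the small k used here).
misassignment_count <- function(predicted, reference) {
  ref <- as.character(reference)
  pl <- unique(predicted)
  rl <- unique(ref)
  k <- max(length(pl), length(rl))
  if (k > 7L) stop_vt("misassignment_count supports at most 7 clusters")
  ## pad so a bijection always exists, then minimise over assignments
  pl <- c(pl, paste0(".pad.p", seq_len(k - length(pl))))
  rl <- c(rl, paste0(".pad.r", seq_len(k - length(rl))))
  best <- length(predicted)
  for (p in permutations_of(seq_len(k))) {
    mapped <- rl[p][match(predicted, pl)]
    best <- min(best, sum(mapped != ref))
  }
  best
}

permutations_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    rest <- permutations_of(x[-i])
    out <- c(out, lapply(rest, function(r) c(x[i], r)))
  }
  out
}
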
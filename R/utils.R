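# Internal helpers shared across modules.

#' @importFrom stats setNames
NULL

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a per-stage seed from a global seed; kept below 2^31 (arithmetic in
# doubles to avoid 32-bit overflow).
derive_seed <- function(seed, stage_index) {
  as.integer((as.numeric(seed) * 101 + as.numeric(stage_index) * 7919) %%
               2147483629)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

check_prob <- function(x, field) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stopf("configuration error: '%s' must contain probabilities in [0, 1]", field)
  }
  invisible(x)
}

check_count <- function(x, field) {
  if (length(x) != 1L || !is.finite(x) || x <= 0 || x != round(x)) {
    stopf("configuration error: '%s' must be a positive integer count", field)
  }
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Thin wrapper around [mclust::adjustedRandIndex()] used for recovery
#' diagnostics in pipeline reports and tests.
#'
#' @param a,b partition label vectors of equal length.
#' @return Adjusted Rand index (1 = identical partitions, ~0 = random).
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}

# Jaccard overlap between the best-matching cluster and a reference set.
best_jaccard <- function(labels, truth_set) {
  sets <- split(seq_along(labels), labels)
  j <- vapply(sets, function(s) {
    length(intersect(s, truth_set)) / length(union(s, truth_set))
  }, numeric(1))
  max(j)
}
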
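# Internal helpers shared across modules.

#' Derive per-cohort child seeds from one master seed
#'
#' One global seed spawns independent child seeds by a fixed affine rule,
#' `(seed + 104729 * i) mod (2^31 - 1)`, so that multi-cohort simulations are
#' reproducible from a single integer while cohorts stay decorrelated.
#'
#' @param seed Integer master seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`.
#' @export
child_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  (as.integer(seed) %% 2147483647L + 104729L * seq_len(n)) %% 2147483647L
}

# Stop with a formatted message (no call in output).
abort <- function(...) stop(sprintf(...), call. = FALSE)

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    x == round(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Row standard deviations of a numeric matrix (denominator n - 1).
row_sds <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  sqrt(rowSums((x - m)^2) / (n - 1L))
}
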
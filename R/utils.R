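# Internal helpers shared across modules.

# Harmonic number a_k = sum_{i=1..k} 1/i, the Watterson denominator.
harmonic_number <- function(k) {
  vapply(k, function(x) if (x < 1) NA_real_ else sum(1 / seq_len(x)), 0)
}

#' Watterson's theta from a segregating-site count
#'
#' \eqn{\hat\theta_W = S / (a_{n-1} L)} with \eqn{a_k = \sum_{i=1}^{k} 1/i},
#' the standard estimator of the population mutation rate per site from the
#' number of segregating sites.
#'
#' @param S number of segregating sites.
#' @param L number of surveyed (callable) sites.
#' @param n number of sampled sequences (haploid-coded accessions).
#' @return Watterson's theta per site.
#' @examples
#' theta_w_from_counts(16, 1000, 10)
#' @export
theta_w_from_counts <- function(S, L, n) {
  stopifnot(S >= 0, L > 0, n >= 2)
  S / (harmonic_number(n - 1) * L)
}

# Deterministic derived seeds: one global seed expands into per-stage seeds.
# Kept below 2^31 so they are valid R integers.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((abs(seed) * 48271 + h * 16807 + 12345) %% 2147483647L)
}

# Validation shorthand
assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (strict_lower && x <= lower)
    stop(sprintf("'%s' must be > %g", name, lower), call. = FALSE)
  if (!strict_lower && x < lower)
    stop(sprintf("'%s' must be >= %g", name, lower), call. = FALSE)
  if (x > upper)
    stop(sprintf("'%s' must be <= %g", name, upper), call. = FALSE)
  invisible(x)
}

# Total overlap (bp) between one window [start, end) and a set of sorted,
# non-overlapping intervals.  Vectorized over windows.
interval_overlap_bp <- function(win_start, win_end, ivl_start, ivl_end) {
  if (length(ivl_start) == 0) return(numeric(length(win_start)))
  o <- order(ivl_start)
  ivl_start <- ivl_start[o]; ivl_end <- ivl_end[o]
  vapply(seq_along(win_start), function(i) {
    s <- pmax(ivl_start, win_start[i])
    e <- pmin(ivl_end, win_end[i])
    sum(pmax(0, e - s))
  }, 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
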
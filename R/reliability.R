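#' Interleaved split-half of a trial table
#'
#' Assigns every second trial, starting with the first, to an artificial
#' "test" session and the remaining trials to a "retest" session. The two
#' halves partition the input (sizes differ by at most one) and preserve
#' trial order, so within-session dynamics are matched between halves.
#'
#' @param trials Trial table with at least 2 rows.
#' @return A list with elements `test` (odd positions) and `retest` (even
#'   positions).
#' @export
split_half_interleaved <- function(trials) {
  n <- nrow(trials)
  if (n < 2) stop("need at least 2 trials to split")
  idx <- seq_len(n)
  list(test = trials[idx %% 2 == 1L, , drop = FALSE],
       retest = trials[idx %% 2 == 0L, , drop = FALSE])
}

#' Normalized mean absolute error between two sessions
#'
#' Absolute-error reliability statistic for paired per-subject measures
#' `x` (test) and `y` (retest). The numerator is the mean absolute
#' test-retest difference; the denominator is the mean absolute difference
#' between each value and the average of the *other* session:
#' `NMAE = mean(|x - y|) / (mean(|x - mean(y)|)/2 + mean(|y - mean(x)|)/2)`.
#' The denominator makes the statistic invariant to common positive affine
#' rescalings of both sessions, so it can be compared across measures. An
#' NMAE of 1 means a subject's test value is on average no closer to their
#' retest value than to the retest group mean.
#'
#' @param x,y Numeric vectors of equal length (missing pairs removed
#'   beforehand).
#' @return Non-negative NMAE; 0 iff `x == y` elementwise.
#' @export
nmae <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2,
            !anyNA(x), !anyNA(y))
  num <- mean(abs(x - y))
  den <- mean(abs(x - mean(y))) / 2 + mean(abs(y - mean(x))) / 2
  if (den == 0) stop("NMAE is undefined: all values identical across both sessions")
  num / den
}

#' Pearson test-retest correlation
#'
#' Standard sample correlation between paired test and retest values.
#'
#' @param x,y Numeric vectors of equal length `>= 3`, neither constant.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            !anyNA(x), !anyNA(y))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation is undefined for constant input")
  }
  stats::cor(x, y)
}

#' Test-retest reliability of a paired measure
#'
#' Applies the missing-value and extreme-value policies, then computes both
#' reliability statistics. Pairs are dropped when either entry is missing
#' or (optionally) when either entry exceeds `exclude_abs` in magnitude —
#' the guard used for the unregularized M_ratio, whose estimates can
#' explode when the denominator d' is close to zero. The NMAE is flagged
#' invalid for hierarchically estimated inputs: separate group priors
#' compress the test and retest values around their respective group means,
#' which deflates the NMAE artifactually.
#'
#' @param x,y Aligned per-subject measure vectors (test, retest).
#' @param exclude_abs Drop pairs where `|x|` or `|y|` exceeds this value
#'   (default `Inf`, no exclusion; use 10 for raw M_ratio).
#' @param hierarchical Set `TRUE` when `x`/`y` come from hierarchical
#'   estimation; the NMAE is then returned as `NA`.
#' @return A list with `pearson_r`, `nmae`, `n_used`, `n_dropped`.
#' @export
reliability <- function(x, y, exclude_abs = Inf, hierarchical = FALSE) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y) & abs(x) <= exclude_abs &
    abs(y) <= exclude_abs
  n_used <- sum(keep)
  if (n_used < 3) stop("fewer than 3 usable pairs")
  xr <- x[keep]
  yr <- y[keep]
  list(pearson_r = pearson(xr, yr),
       nmae = if (hierarchical) NA_real_ else nmae(xr, yr),
       n_used = n_used,
       n_dropped = length(x) - n_used)
}
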
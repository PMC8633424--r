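#' Discretize continuous confidence into percentile ratings
#'
#' Sorts trials into at most `k` confidence bins on a percentile basis,
#' aiming for a balanced number of trials per bin. Duplicate percentile
#' edges (which arise when many trials share a confidence value) are
#' collapsed and the surviving ratings renumbered consecutively, so the
#' result can have fewer than `k` distinct levels. The mapping is order
#' preserving: a higher confidence value never receives a lower rating.
#'
#' @param confidence Numeric vector of confidence values.
#' @param k Maximum number of rating levels (default 6, the cap used when
#'   harmonizing heterogeneous confidence scales).
#' @return Integer vector of ratings in `1..k`.
#' @export
discretize_confidence <- function(confidence, k = 6) {
  stopifnot(is.numeric(confidence), length(confidence) >= 1, k >= 2)
  edges <- unique(stats::quantile(confidence, probs = seq_len(k - 1) / k,
                                  names = FALSE, type = 7))
  r <- findInterval(confidence, sort(edges), left.open = TRUE) + 1L
  # renumber consecutively in case edge collapsing left gaps
  match(r, sort(unique(r)))
}

#' Floor negative confidence ratings at 1
#'
#' Some rating scales include negative values to indicate confidence in
#' being wrong; these are floored at 1, the lowest rating.
#'
#' @param ratings Integer vector of ratings.
#' @return Integer vector with every rating below 1 replaced by 1.
#' @export
floor_negative_ratings <- function(ratings) {
  pmax(as.integer(ratings), 1L)
}

#' Tabulate stimulus x response x rating counts
#'
#' Builds the 2 x 2 x K contingency array of trial counts consumed by the
#' type 1 statistics and the meta-d' fit.
#'
#' @param trials A trial table with columns `stimulus` (0/1), `choice`
#'   (0/1) and `rating` (integers in `1..k`); if `rating` is absent it is
#'   created by [discretize_confidence()] applied to `confidence`.
#' @param k Number of rating levels.
#' @return Integer array with `dim = c(2, 2, k)` indexed by
#'   `(stimulus + 1, choice + 1, rating)`, of class `rating_counts`.
#' @export
tabulate_counts <- function(trials, k = 6) {
  if (!"rating" %in% names(trials)) {
    trials$rating <- discretize_confidence(trials$confidence, k)
  }
  r <- as.integer(trials$rating)
  if (any(r < 1L | r > k)) stop("ratings must lie in 1..k")
  idx <- trials$stimulus + 2L * trials$choice + 4L * (r - 1L) + 1L
  counts <- array(tabulate(idx, nbins = 4L * k), dim = c(2L, 2L, k))
  structure(counts, class = c("rating_counts", "array"))
}

# Add 1/(2K) to every stimulus x response x rating cell. This is the
# conventional correction of the meta-d' literature: it removes hit and
# false-alarm rates of exactly 0 or 1 (infinite z-scores) at small counts
# while leaving large-count estimates essentially unchanged.
pad_counts <- function(counts) {
  k <- dim(counts)[3]
  counts + 1 / (2 * k)
}

#' Type 1 signal-detection statistics
#'
#' Equal-variance SDT sensitivity and criterion from a rating-count array.
#' Hit rate is the probability of responding category 1 given stimulus 1,
#' false-alarm rate the same given stimulus 0. Every cell is padded with
#' `1/(2K)` before the rates are formed, so degenerate rates of 0 or 1
#' cannot occur. `d' = z(H) - z(F)` and `c = -(z(H) + z(F)) / 2`.
#'
#' @param counts A `rating_counts` array from [tabulate_counts()].
#' @return A list with `d_prime`, `criterion`, `hit_rate`, `fa_rate`.
#' @export
type1_stats <- function(counts) {
  p <- pad_counts(counts)
  n_s0 <- sum(p[1, , ])
  n_s1 <- sum(p[2, , ])
  hit <- sum(p[2, 2, ]) / n_s1
  fa <- sum(p[1, 2, ]) / n_s0
  zh <- stats::qnorm(hit)
  zf <- stats::qnorm(fa)
  list(d_prime = zh - zf, criterion = -(zh + zf) / 2,
       hit_rate = hit, fa_rate = fa)
}

#' Area under the type 2 ROC curve
#'
#' Metacognitive sensitivity as the area under the ROC curve that contrasts
#' the confidence-rating distributions of correct and incorrect trials.
#' For each rating threshold the type 2 hit rate is the probability of a
#' rating at or above the threshold given a correct trial, the type 2
#' false-alarm rate the same given an incorrect trial; the area is computed
#' by trapezoidal integration over the thresholds plus the (0,0) and (1,1)
#' endpoints.
#'
#' @param correct Logical vector, trial correctness.
#' @param ratings Integer vector of confidence ratings.
#' @return AUROC2 in `[0, 1]`; 0.5 means confidence carries no information
#'   about correctness.
#' @export
auroc2 <- function(correct, ratings) {
  stopifnot(length(correct) == length(ratings))
  correct <- as.logical(correct)
  n_c <- sum(correct)
  n_i <- sum(!correct)
  if (n_c == 0L || n_i == 0L) {
    stop("AUROC2 is undefined without both correct and incorrect trials")
  }
  lev <- sort(unique(ratings))
  # P(rating >= threshold | correct / incorrect), thresholds descending
  tab_c <- vapply(lev, function(l) sum(ratings[correct] == l), numeric(1))
  tab_i <- vapply(lev, function(l) sum(ratings[!correct] == l), numeric(1))
  h2 <- c(0, cumsum(rev(tab_c)) / n_c)
  f2 <- c(0, cumsum(rev(tab_i)) / n_i)
  sum(diff(f2) * (h2[-1] + h2[-length(h2)]) / 2)
}

# Negative multinomial log-likelihood of the rating counts under the
# meta-level SDT model. theta = c(meta_d, log-gaps below the criterion,
# log-gaps above), counts is the (possibly padded) 2 x 2 x K array,
# c_rel = c / d' is the fixed relative type 1 criterion.
meta_d_nll <- function(theta, counts, c_rel) {
  k <- dim(counts)[3]
  if (any(!is.finite(theta)) || any(abs(theta) > 50)) return(1e10)
  meta_d <- theta[1]
  meta_c <- c_rel * meta_d
  g1 <- exp(theta[2:k])
  g2 <- exp(theta[(k + 1):(2 * k - 1)])
  c_s1 <- meta_c - rev(cumsum(g1)) # ascending, all < meta_c
  c_s2 <- meta_c + cumsum(g2)      # ascending, all > meta_c
  b0 <- c(-Inf, c_s1, meta_c)      # response 0 boundaries
  b1 <- c(meta_c, c_s2, Inf)       # response 1 boundaries
  nll <- 0
  for (s in 1:2) {
    mu_s <- (2 * s - 3) * meta_d / 2 # -meta_d/2 for stim 0, + for stim 1
    p0 <- diff(stats::pnorm(b0 - mu_s)) # response 0, interval masses
    p1 <- diff(stats::pnorm(b1 - mu_s))
    # rating order: extreme percept = high rating; the response masses are
    # floored so a degenerate parameter probe (criterion far in a tail)
    # yields a finite penalty instead of 0/0
    pr0 <- rev(p0) / max(sum(p0), 1e-300)
    pr1 <- p1 / max(sum(p1), 1e-300)
    nll <- nll - sum(counts[s, 1, ] * log(pmax(pr0, 1e-12))) -
      sum(counts[s, 2, ] * log(pmax(pr1, 1e-12)))
  }
  nll
}

# Data-driven starting values: meta-d' at the type 1 d', type 2 criteria
# placed at the normal quantiles matching the observed conditional rating
# proportions in each response cell.
meta_d_start <- function(counts, d1, c_rel) {
  k <- dim(counts)[3]
  meta_c0 <- c_rel * d1
  init_gaps <- function(cell_counts, side) {
    tot <- sum(cell_counts)
    cum <- cumsum(cell_counts)[seq_len(k - 1)] / tot # P(rating <= j)
    cum <- pmin(pmax(cum, 0.025), 0.975)
    if (side == "low") {
      # response 0: rating <= j <-> percept in (c_s1[k-j], meta_c)
      resp_mass <- stats::pnorm(meta_c0)
      b <- stats::qnorm(pmax(resp_mass * (1 - cum), 1e-6))
      b <- rev(b) # ascending criteria below meta_c0
      b <- pmin(b, meta_c0 - 0.01)
      gaps <- diff(c(b, meta_c0))
    } else {
      resp_mass <- 1 - stats::pnorm(meta_c0)
      b <- stats::qnorm(pmin(1 - resp_mass * (1 - cum), 1 - 1e-6))
      b <- pmax(b, meta_c0 + 0.01)
      gaps <- diff(c(meta_c0, b))
    }
    gaps <- pmax(gaps, 0.01)
    # log-gaps ordered from nearest the criterion outward
    log(if (side == "low") rev(gaps) else gaps)
  }
  low <- init_gaps(counts[1, 1, ] + counts[2, 1, ], "low")
  high <- init_gaps(counts[1, 2, ] + counts[2, 2, ], "high")
  c(d1, low, high)
}

#' Maximum likelihood meta-d'
#'
#' Fits the meta-level equal-variance SDT model of Maniscalco and Lau to a
#' stimulus x response x rating count array. The model asks what type 1
#' sensitivity an ideal metacognitive observer would need in order to
#' produce the observed type 2 (confidence) data: category means sit at
#' `+/- meta_d/2`, the type 1 criterion is held at the same relative
#' position `c' = c / d'` as in the observed type 1 data, and `K - 1`
#' type 2 criteria on each side of it carve percept space into rating
#' regions. The multinomial log-likelihood of the rating counts,
#' conditional on each (stimulus, response) cell, is maximized over
#' `meta_d` and the type 2 criteria; criteria are parameterized by ordered
#' positive increments away from the type 1 criterion so monotonicity holds
#' by construction. All cells are padded with `1/(2K)` beforehand.
#'
#' @param counts A `rating_counts` array from [tabulate_counts()].
#' @return A list of class `meta_d_fit` with elements `meta_d`,
#'   `t2_criteria_resp0` and `t2_criteria_resp1` (each ascending, length
#'   `K - 1`), `meta_c`, `d_prime`, `criterion`, `log_likelihood` and
#'   `converged`.
#' @export
fit_meta_d <- function(counts) {
  k <- dim(counts)[3]
  if (k < 2) stop("meta-d' requires at least 2 rating levels")
  padded <- pad_counts(counts)
  t1 <- type1_stats(counts)
  if (t1$d_prime == 0) {
    stop("d' = 0: the relative type 1 criterion of the meta-level model ",
         "is undefined")
  }
  c_rel <- t1$criterion / t1$d_prime
  theta0 <- meta_d_start(padded, t1$d_prime, c_rel)
  fit <- stats::nlminb(theta0, meta_d_nll, counts = padded, c_rel = c_rel,
                       control = list(rel.tol = 1e-10, iter.max = 500L,
                                      eval.max = 1000L))
  meta_d <- fit$par[1]
  meta_c <- c_rel * meta_d
  g1 <- exp(fit$par[2:k])
  g2 <- exp(fit$par[(k + 1):(2 * k - 1)])
  structure(list(
    meta_d = meta_d,
    meta_c = meta_c,
    t2_criteria_resp0 = meta_c - rev(cumsum(g1)),
    t2_criteria_resp1 = meta_c + cumsum(g2),
    d_prime = t1$d_prime,
    criterion = t1$criterion,
    log_likelihood = -fit$objective,
    converged = fit$convergence == 0L
  ), class = "meta_d_fit")
}

#' @export
print.meta_d_fit <- function(x, ...) {
  cat(sprintf("meta-d' fit: meta-d' = %.4f (d' = %.4f, M_ratio = %.4f)\n",
              x$meta_d, x$d_prime, x$meta_d / x$d_prime))
  cat(sprintf("  logL = %.4f, converged: %s\n", x$log_likelihood,
              x$converged))
  invisible(x)
}

#' Metacognitive efficiency from d' and meta-d'
#'
#' `M_diff = meta_d - d'` and `M_ratio = meta_d / d'`. When `d' = 0` the
#' ratio is undefined and returned as `NA` (not an error), so missing
#' values can be handled pairwise downstream.
#'
#' @param d_prime Type 1 sensitivity.
#' @param meta_d Meta-level sensitivity.
#' @return A list with `m_diff` and `m_ratio`.
#' @export
efficiency_measures <- function(d_prime, meta_d) {
  list(m_diff = meta_d - d_prime,
       m_ratio = ifelse(d_prime != 0, meta_d / d_prime, NA_real_))
}

#' Regularize M_ratio values
#'
#' Three remedies against the extreme M_ratio estimates that arise at low
#' trial numbers or near-chance performance:
#' \describe{
#'   \item{exclude}{values outside `[lb, ub]` become `NA`;}
#'   \item{bound}{values are clipped into `[lb, ub]`;}
#'   \item{log}{values are floored at `lb > 0` and log-transformed.}
#' }
#' Default bounds are `lb = 0` (a metacognitively blind observer) and
#' `ub = 1.6` (symmetric around a typical empirical median of 0.8); the
#' logarithmic floor defaults to 0.1.
#'
#' @param m_ratio Numeric vector of M_ratio values.
#' @param method One of `"exclude"`, `"bound"`, `"log"`.
#' @param lb,ub Bounds; `ub` is ignored for `"log"`.
#' @return Numeric vector of regularized values (possibly `NA`).
#' @export
regularize_mratio <- function(m_ratio, method = c("exclude", "bound", "log"),
                              lb = if (method == "log") 0.1 else 0,
                              ub = 1.6) {
  method <- match.arg(method)
  if (method %in% c("exclude", "bound") && lb >= ub) {
    stop("`lb` must be smaller than `ub`")
  }
  switch(method,
    exclude = ifelse(m_ratio >= lb & m_ratio <= ub, m_ratio, NA_real_),
    bound = pmax(lb, pmin(ub, m_ratio)),
    log = {
      if (lb <= 0) stop("`lb` must be > 0 for the log transform")
      log(pmax(lb, m_ratio))
    }
  )
}

#' All performance measures for one subject-session
#'
#' Full pipeline from a trial table to the measure set: percentile
#' discretization of confidence, count tabulation, type 1 statistics,
#' AUROC2, the meta-d' fit and the efficiency measures with their
#' regularized variants (the hierarchical variant is cohort-level; see
#' [hierarchical_mratio()]).
#'
#' @param trials Trial table with `stimulus`, `choice`, `correct` and
#'   either `rating` or `confidence` columns.
#' @param k Number of rating levels for discretization (default 6).
#' @param bounds Lower/upper bound for the excluded and bounded variants.
#' @param log_lb Floor for the logarithmic variant.
#' @return A one-row tibble with `n_trials`, `d_prime`, `criterion`,
#'   `auroc2`, `meta_d`, `m_diff`, `m_ratio`, `m_ratio_excl`,
#'   `m_ratio_bounded`, `m_ratio_log` and `converged`.
#' @export
compute_measures <- function(trials, k = 6, bounds = c(0, 1.6),
                             log_lb = 0.1) {
  if (!"rating" %in% names(trials)) {
    trials$rating <- discretize_confidence(trials$confidence, k)
  }
  counts <- tabulate_counts(trials, k)
  t1 <- type1_stats(counts)
  a2 <- tryCatch(auroc2(trials$correct, trials$rating),
                 error = function(e) NA_real_)
  fit <- tryCatch(fit_meta_d(counts), error = function(e) NULL)
  if (is.null(fit)) {
    meta_d <- NA_real_
    converged <- FALSE
  } else {
    meta_d <- fit$meta_d
    converged <- fit$converged
  }
  eff <- efficiency_measures(t1$d_prime, meta_d)
  tibble::tibble(
    n_trials = nrow(trials),
    d_prime = t1$d_prime,
    criterion = t1$criterion,
    auroc2 = a2,
    meta_d = meta_d,
    m_diff = eff$m_diff,
    m_ratio = eff$m_ratio,
    m_ratio_excl = regularize_mratio(eff$m_ratio, "exclude",
                                     bounds[1], bounds[2]),
    m_ratio_bounded = regularize_mratio(eff$m_ratio, "bound",
                                        bounds[1], bounds[2]),
    m_ratio_log = regularize_mratio(eff$m_ratio, "log", log_lb),
    converged = converged
  )
}

#' Per-subject (and per-session) measures for a cohort
#'
#' Applies [compute_measures()] to every subject-session of a tidy cohort
#' table (as produced by [simulate_cohort()]).
#'
#' @param cohort Tibble with `subject`, optional `session`, and the trial
#'   columns required by [compute_measures()].
#' @inheritParams compute_measures
#' @return A tibble with one row per subject-session, keyed by `subject`
#'   and `session`.
#' @export
compute_measures_cohort <- function(cohort, k = 6, bounds = c(0, 1.6),
                                    log_lb = 0.1) {
  if (!"session" %in% names(cohort)) cohort$session <- 1L
  cohort |>
    dplyr::group_by(.data$subject, .data$session) |>
    dplyr::group_modify(~ compute_measures(.x, k = k, bounds = bounds,
                                           log_lb = log_lb)) |>
    dplyr::ungroup()
}
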
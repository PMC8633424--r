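#' Type 1 performance dependency grid
#'
#' Simulation experiment characterizing how each metacognitive performance
#' measure depends on type 1 performance. For every combination of sensory
#' noise (`sigma_s_grid`) and metacognitive noise (`sigma_m_grid`), a
#' cohort of independent single-session observers is simulated and all
#' measures are computed per observer; the grid cell is summarized by the
#' mean and asymmetric standard deviations (computed separately from the
#' observations above and below the mean, since several measures have
#' skewed sampling distributions).
#'
#' The default sensory-noise grid is chosen so the implied sensitivity
#' `d' = mu / sigma_s` covers 0.2 to 3 roughly evenly.
#'
#' @param sigma_s_grid Sensory noise levels.
#' @param sigma_m_grid Metacognitive noise levels (default 0 to 0.5 in
#'   steps of 0.1).
#' @param n_subjects Observers per grid cell.
#' @param n_trials Trials per observer.
#' @param k Rating levels for discretization.
#' @param mu Stimulus mean separation.
#' @param seed Optional integer seed.
#' @return A tidy tibble with one row per grid cell and measure:
#'   `sigma_s`, `sigma_m`, `d_prime_mean`, `measure`, `mean`, `sd_lower`,
#'   `sd_upper`, `n`.
#' @export
run_dependency_grid <- function(sigma_s_grid = 1 / seq(0.2, 3, length.out = 10),
                                sigma_m_grid = seq(0, 0.5, by = 0.1),
                                n_subjects = 200, n_trials = 2000, k = 6,
                                mu = 1, seed = NULL) {
  stopifnot(length(sigma_s_grid) >= 1, length(sigma_m_grid) >= 1,
            all(sigma_m_grid >= 0 & sigma_m_grid <= 0.5))
  if (!is.null(seed)) set.seed(seed)
  cells <- expand.grid(sigma_s = sigma_s_grid, sigma_m = sigma_m_grid)
  cell_seeds <- sample.int(.Machine$integer.max, nrow(cells))
  measure_cols <- c("d_prime", "auroc2", "meta_d", "m_diff", "m_ratio",
                    "m_ratio_excl", "m_ratio_bounded", "m_ratio_log")
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cohort <- simulate_cohort(n_subjects, n_trials, n_sessions = 1,
                              sigma_m = cells$sigma_m[i],
                              sigma_s = cells$sigma_s[i], mu = mu,
                              seed = cell_seeds[i])
    ms <- compute_measures_cohort(cohort, k = k)
    d_mean <- mean(ms$d_prime, na.rm = TRUE)
    rows <- lapply(measure_cols, function(m) {
      x <- ms[[m]][!is.na(ms[[m]])]
      mn <- mean(x)
      up <- x[x >= mn] - mn
      lo <- x[x < mn] - mn
      tibble::tibble(
        sigma_s = cells$sigma_s[i], sigma_m = cells$sigma_m[i],
        d_prime_mean = d_mean, measure = m, mean = mn,
        sd_lower = if (length(lo)) sqrt(mean(lo^2)) else 0,
        sd_upper = if (length(up)) sqrt(mean(up^2)) else 0,
        n = length(x)
      )
    })
    out[[i]] <- dplyr::bind_rows(rows)
  }
  dplyr::bind_rows(out)
}

#' Test-retest reliability grid
#'
#' Simulation experiment mapping the test-retest reliability of
#' metacognitive efficiency measures over a (type 1 accuracy x trials per
#' session) lattice. Per iteration and grid cell, a cohort of subjects is
#' simulated (metacognitive noise drawn uniformly on `[0, 0.5]` per subject
#' and shared between the two sessions), two independent sessions are
#' generated, each measure is computed per subject and session, and the
#' Pearson correlation and NMAE between sessions are recorded. Statistics
#' are averaged over iterations. Pairs with raw `|M_ratio| > exclude_abs`
#' are dropped for the unregularized M_ratio.
#'
#' @param accuracy_grid Expected proportions correct in (0.5, 1).
#' @param trials_grid Trials per session.
#' @param n_subjects Subjects per cohort (default 100).
#' @param n_iterations Repetitions with fresh cohorts (default 20).
#' @param measures Measure columns to evaluate.
#' @param exclude_abs Extreme-value guard applied to raw `m_ratio`.
#' @param k Rating levels.
#' @param mu Stimulus mean separation.
#' @param fisher_z Average per-iteration correlations on the Fisher-z scale
#'   instead of the raw r scale (default `FALSE`).
#' @param seed Optional integer seed.
#' @return A tibble with one row per (accuracy, n_trials, measure):
#'   mean `pearson_r` and `nmae` across iterations, mean `n_used`, and the
#'   number of iterations that produced a usable statistic.
#' @export
run_reliability_grid <- function(accuracy_grid, trials_grid,
                                 n_subjects = 100, n_iterations = 20,
                                 measures = c("m_ratio", "m_ratio_excl",
                                              "m_ratio_bounded",
                                              "m_ratio_log"),
                                 exclude_abs = 10, k = 6, mu = 1,
                                 fisher_z = FALSE, seed = NULL) {
  stopifnot(all(accuracy_grid > 0.5 & accuracy_grid < 1),
            all(trials_grid >= 2), n_iterations >= 1)
  if (!is.null(seed)) set.seed(seed)
  cells <- expand.grid(accuracy = accuracy_grid, n_trials = trials_grid)
  iter_seeds <- matrix(sample.int(.Machine$integer.max,
                                  nrow(cells) * n_iterations),
                       nrow = nrow(cells))
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    acc <- vector("list", n_iterations)
    for (it in seq_len(n_iterations)) {
      cohort <- simulate_cohort(n_subjects, cells$n_trials[i],
                                n_sessions = 2, sigma_m = "uniform",
                                target_accuracy = cells$accuracy[i],
                                mu = mu, seed = iter_seeds[i, it])
      ms <- compute_measures_cohort(cohort, k = k)
      s1 <- ms[ms$session == 1, ]
      s2 <- ms[ms$session == 2, ]
      acc[[it]] <- dplyr::bind_rows(lapply(measures, function(m) {
        rel <- tryCatch(
          reliability(s1[[m]], s2[[m]],
                      exclude_abs = if (m == "m_ratio") exclude_abs
                                    else Inf),
          error = function(e) NULL)
        if (is.null(rel)) {
          tibble::tibble(measure = m, pearson_r = NA_real_,
                         nmae = NA_real_, n_used = NA_real_)
        } else {
          tibble::tibble(measure = m, pearson_r = rel$pearson_r,
                         nmae = rel$nmae, n_used = rel$n_used)
        }
      }))
    }
    iter_tab <- dplyr::bind_rows(acc)
    avg_r <- function(r) {
      r <- r[!is.na(r)]
      if (!length(r)) return(NA_real_)
      if (fisher_z) tanh(mean(atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))))
      else mean(r)
    }
    out[[i]] <- iter_tab |>
      dplyr::group_by(.data$measure) |>
      dplyr::summarise(
        n_iterations = sum(!is.na(.data$pearson_r)),
        pearson_r = avg_r(.data$pearson_r),
        nmae = mean(.data$nmae, na.rm = TRUE),
        n_used = mean(.data$n_used, na.rm = TRUE),
        .groups = "drop") |>
      dplyr::mutate(accuracy = cells$accuracy[i],
                    n_trials = cells$n_trials[i], .before = 1)
  }
  dplyr::bind_rows(out)
}

#' Sliding d'-window summary of a per-subject measure
#'
#' Summarizes a measure as a function of type 1 performance using
#' overlapping d' windows: each window includes the subjects whose d' lies
#' within `halfwidth` of the window center, and is summarized by the mean
#' and standard error of the measure. Subjects outside `d_range` are
#' discarded first.
#'
#' @param d_prime Per-subject d' values.
#' @param value Per-subject measure values, aligned with `d_prime`.
#' @param centers Window centers (default 0.3 to 2.9 in steps of 0.2).
#' @param halfwidth Half window width (default 0.2).
#' @param d_range Admissible d' range (default `c(0.1, 3.1)`).
#' @return A tibble with `bin_center`, `mean`, `sem` (`NA` for windows with
#'   fewer than 2 subjects) and `count`.
#' @export
bin_by_dprime <- function(d_prime, value,
                          centers = seq(0.3, 2.9, by = 0.2),
                          halfwidth = 0.2, d_range = c(0.1, 3.1)) {
  stopifnot(length(d_prime) == length(value), length(d_prime) >= 1)
  keep <- !is.na(d_prime) & !is.na(value) &
    d_prime >= d_range[1] & d_prime <= d_range[2]
  d <- d_prime[keep]
  v <- value[keep]
  rows <- lapply(centers, function(ct) {
    inwin <- abs(d - ct) <= halfwidth
    n <- sum(inwin)
    tibble::tibble(
      bin_center = ct,
      mean = if (n) mean(v[inwin]) else NA_real_,
      sem = if (n >= 2) stats::sd(v[inwin]) / sqrt(n) else NA_real_,
      count = n
    )
  })
  dplyr::bind_rows(rows)
}
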
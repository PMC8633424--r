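#' Generative observer parameters
#'
#' Bundle of the three parameters of the noisy-metacognition observer model:
#' the separation `mu` between the two stimulus category means (percept means
#' sit at `-mu/2` and `+mu/2`), the sensory noise standard deviation
#' `sigma_s`, and the metacognitive noise spread `sigma_m` of the Beta
#' distribution that corrupts reported confidence.
#'
#' `sigma_m` lives in `[0, 0.5]`: at 0 the observer reports the internal
#' confidence exactly; at 0.5 the Beta noise distribution is uniform on
#' `[0, 1]`, i.e. confidence reports are random. `sigma_s = 0` is permitted
#' and denotes a noiseless (perfectly performing) observer. Only the ratio
#' `mu / sigma_s` is identified, so `mu` defaults to 1 throughout the
#' package; type 1 sensitivity d' then equals `1 / sigma_s`.
#'
#' @param mu Positive real, separation of the stimulus means.
#' @param sigma_s Non-negative real, sensory noise SD.
#' @param sigma_m Real in `[0, 0.5]`, metacognitive noise spread.
#' @return An object of class `generative_params`.
#' @examples
#' generative_params(mu = 1, sigma_s = 1.5, sigma_m = 0.2)
#' @export
generative_params <- function(mu = 1, sigma_s = 1, sigma_m = 0) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(sigma_s), length(sigma_s) == 1L, is.finite(sigma_s),
            is.numeric(sigma_m), length(sigma_m) == 1L, is.finite(sigma_m))
  if (mu <= 0) stop("`mu` must be > 0")
  if (sigma_s < 0) stop("`sigma_s` must be >= 0")
  if (sigma_m < 0 || sigma_m > 0.5) stop("`sigma_m` must lie in [0, 0.5]")
  structure(list(mu = mu, sigma_s = sigma_s, sigma_m = sigma_m),
            class = "generative_params")
}

#' @export
print.generative_params <- function(x, ...) {
  cat(sprintf("Generative observer: mu = %g, sigma_s = %g, sigma_m = %g\n",
              x$mu, x$sigma_s, x$sigma_m))
  if (x$sigma_s > 0) {
    cat(sprintf("  implied d' = %.4g, expected accuracy = %.4g\n",
                x$mu / x$sigma_s, stats::pnorm(x$mu / (2 * x$sigma_s))))
  } else {
    cat("  noiseless observer (perfect accuracy)\n")
  }
  invisible(x)
}

#' Bayesian choice probability from a percept
#'
#' Posterior probability that the stimulus belongs to category 1 (the
#' category with percept mean `+mu/2`) given the percept, under equal
#' category priors and Gaussian sensory noise:
#' `p = 1 / (1 + exp(-mu * percept / sigma_s^2))`.
#'
#' @param percept Numeric vector of percepts.
#' @param params A [generative_params()] object with `sigma_s > 0`.
#' @return Numeric vector of choice probabilities in (0, 1), monotone
#'   increasing in `percept`.
#' @export
choice_probability <- function(percept, params) {
  stopifnot(inherits(params, "generative_params"), is.numeric(percept))
  if (params$sigma_s == 0) {
    stop("choice_probability is undefined at sigma_s = 0; ",
         "the noiseless observer decides by the sign of the percept")
  }
  stats::plogis(params$mu * percept / params$sigma_s^2)
}

#' Internal confidence from the choice probability
#'
#' Choice-independent confidence variable: the choice probability folded
#' around 0.5 and rescaled to `[0, 1]`, `c = 2 * |p - 0.5|`. Confidence is
#' symmetric, `c(p) = c(1 - p)`, so relabeling the stimulus categories does
#' not change it.
#'
#' @param p Numeric vector of probabilities in `[0, 1]`.
#' @return Numeric vector of confidence values in `[0, 1]`.
#' @export
confidence_from_p <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1, na.rm = TRUE))
  2 * abs(p - 0.5)
}

#' Beta shape parameters of the metacognitive noise distribution
#'
#' Mode-parameterized Beta shapes for confidence noise:
#' `alpha = c * (1/sigma_m - 2) + 1`, `beta = (1 - c) * (1/sigma_m - 2) + 1`.
#' The resulting Beta distribution has mode `c`; at `sigma_m = 0.5` both
#' shapes equal 1 and the distribution is uniform on `[0, 1]`.
#'
#' @param c Numeric vector of mode values in `[0, 1]`.
#' @param sigma_m Spread in `(0, 0.5]` (`sigma_m` is not a standard
#'   deviation).
#' @return A list with numeric components `alpha` and `beta` (each `>= 1`).
#' @export
beta_shape_params <- function(c, sigma_m) {
  stopifnot(is.numeric(c), all(c >= 0 & c <= 1),
            is.numeric(sigma_m), length(sigma_m) == 1L)
  if (sigma_m <= 0 || sigma_m > 0.5) {
    stop("`sigma_m` must lie in (0, 0.5]")
  }
  nu <- 1 / sigma_m - 2
  list(alpha = c * nu + 1, beta = (1 - c) * nu + 1)
}

#' Sample reported confidence
#'
#' Draw reported confidence from the metacognitive noise distribution: a
#' Beta distribution with mode equal to the internal confidence `c` and
#' spread `sigma_m`. `sigma_m = 0` is the noiseless limit and returns `c`
#' unchanged (without consuming random numbers).
#'
#' @param c Numeric vector of internal confidence values in `[0, 1]`.
#' @param sigma_m Spread in `[0, 0.5]`.
#' @return Numeric vector of reported confidence values in `[0, 1]`.
#' @export
sample_confidence <- function(c, sigma_m) {
  stopifnot(is.numeric(c), all(c >= 0 & c <= 1))
  if (sigma_m == 0) return(c)
  sh <- beta_shape_params(c, sigma_m)
  stats::rbeta(length(c), sh$alpha, sh$beta)
}

#' Sensory noise level for a target accuracy
#'
#' Inverts the closed-form expected accuracy `Phi(mu / (2 sigma_s))` of the
#' unbiased observer: `sigma_s = mu / (2 * qnorm(target_accuracy))`.
#'
#' @param target_accuracy Proportion correct, strictly between 0.5 and 1.
#' @param mu Stimulus mean separation (default 1).
#' @return Positive sensory noise SD attaining the target accuracy in
#'   expectation.
#' @examples
#' sigma_for_accuracy(0.75) # ~0.7413
#' @export
sigma_for_accuracy <- function(target_accuracy, mu = 1) {
  stopifnot(is.numeric(target_accuracy), is.numeric(mu), all(mu > 0))
  if (any(target_accuracy <= 0.5) || any(target_accuracy >= 1)) {
    stop("`target_accuracy` must lie strictly between 0.5 and 1")
  }
  mu / (2 * stats::qnorm(target_accuracy))
}

#' Simulate one experimental session
#'
#' Generates `n_trials` of the binary choice task. Stimulus categories are
#' equiprobable; percepts are Gaussian around `+/- mu/2`; the observer
#' responds category 1 whenever the choice probability is `>= 0.5` (ties go
#' to category 1); internal confidence is the folded choice probability and
#' reported confidence is a Beta draw around it.
#'
#' The percept is generated as `(2 * stimulus - 1) * (mu/2 + sigma_s * z)`
#' with `z` standard normal, which is distributionally identical to
#' `N(+/- mu/2, sigma_s)` but additionally makes the simulation exactly
#' symmetric under category relabeling: with the same RNG state, flipping
#' the stimulus labels flips percepts and choices while leaving correctness
#' and the confidence stream unchanged.
#'
#' At `sigma_s = 0` the observer is noiseless: every choice is correct and
#' internal confidence is 1 on every trial.
#'
#' @param params A [generative_params()] object.
#' @param n_trials Number of trials (>= 1).
#' @param stimuli Optional integer vector of stimulus categories (0/1) to
#'   use instead of random equiprobable draws; must have length `n_trials`.
#' @return A tibble (one row per trial) with columns `stimulus` (0/1),
#'   `percept`, `choice` (0/1), `correct` (logical), `confidence` in
#'   `[0, 1]`.
#' @export
simulate_session <- function(params, n_trials, stimuli = NULL) {
  stopifnot(inherits(params, "generative_params"),
            is.numeric(n_trials), length(n_trials) == 1L, n_trials >= 1)
  n_trials <- as.integer(n_trials)
  if (is.null(stimuli)) {
    stimuli <- sample(c(0L, 1L), n_trials, replace = TRUE)
  } else {
    stopifnot(length(stimuli) == n_trials, all(stimuli %in% c(0L, 1L)))
    stimuli <- as.integer(stimuli)
  }
  sgn <- 2 * stimuli - 1
  if (params$sigma_s == 0) {
    percept <- sgn * params$mu / 2
    choice <- stimuli
    conf_internal <- rep(1, n_trials)
  } else {
    evidence <- params$mu / 2 + params$sigma_s * stats::rnorm(n_trials)
    percept <- sgn * evidence
    p <- choice_probability(percept, params)
    choice <- as.integer(p >= 0.5)
    # evaluate the fold at |percept| so the confidence stream is exactly
    # (bitwise) invariant under category relabeling
    conf_internal <- confidence_from_p(choice_probability(abs(percept),
                                                          params))
  }
  confidence <- sample_confidence(conf_internal, params$sigma_m)
  tibble::tibble(
    stimulus = stimuli,
    percept = percept,
    choice = choice,
    correct = choice == stimuli,
    confidence = confidence
  )
}

#' Simulate a cohort of subjects over one or more sessions
#'
#' Simulates `n_subjects` observers, each completing `n_sessions`
#' independent sessions of `n_trials` trials. The metacognitive noise
#' `sigma_m` of a subject is drawn once (when `sigma_m = "uniform"`,
#' uniformly on `[0, 0.5]`) and shared across that subject's sessions, so
#' that between-session agreement reflects measurement noise only. Sensory
#' noise is set either directly through `sigma_s` or through
#' `target_accuracy` via [sigma_for_accuracy()].
#'
#' A single cohort `seed` determines everything; per-subject seeds are
#' derived from it so each subject's data are reproducible in isolation.
#'
#' @param n_subjects Number of subjects.
#' @param n_trials Trials per session.
#' @param n_sessions Sessions per subject (default 2).
#' @param sigma_m Either a single numeric value in `[0, 0.5]` used for all
#'   subjects, or `"uniform"` to draw one value per subject uniformly on
#'   `[0, 0.5]`.
#' @param target_accuracy Expected proportion correct in (0.5, 1); used to
#'   set `sigma_s` unless `sigma_s` is given directly.
#' @param sigma_s Sensory noise SD (overrides `target_accuracy`).
#' @param mu Stimulus mean separation (default 1).
#' @param seed Optional integer cohort seed.
#' @return A tibble with columns `subject`, `session`, `trial`, `sigma_m`,
#'   `stimulus`, `percept`, `choice`, `correct`, `confidence`.
#' @export
simulate_cohort <- function(n_subjects, n_trials, n_sessions = 2,
                            sigma_m = "uniform", target_accuracy = NULL,
                            sigma_s = NULL, mu = 1, seed = NULL) {
  stopifnot(n_subjects >= 1, n_trials >= 1, n_sessions >= 1)
  if (is.null(sigma_s)) {
    if (is.null(target_accuracy)) {
      stop("give either `sigma_s` or `target_accuracy`")
    }
    sigma_s <- sigma_for_accuracy(target_accuracy, mu)
  }
  if (!is.null(seed)) set.seed(seed)
  subject_seeds <- sample.int(.Machine$integer.max, n_subjects)
  if (identical(sigma_m, "uniform")) {
    sigma_m_sub <- stats::runif(n_subjects, 0, 0.5)
  } else {
    stopifnot(is.numeric(sigma_m), length(sigma_m) == 1L,
              sigma_m >= 0, sigma_m <= 0.5)
    sigma_m_sub <- rep(sigma_m, n_subjects)
  }
  out <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    set.seed(subject_seeds[i])
    pars <- generative_params(mu = mu, sigma_s = sigma_s,
                              sigma_m = sigma_m_sub[i])
    sess <- lapply(seq_len(n_sessions), function(s) {
      tt <- simulate_session(pars, n_trials)
      tt$session <- s
      tt$trial <- seq_len(n_trials)
      tt
    })
    sub <- dplyr::bind_rows(sess)
    sub$subject <- i
    sub$sigma_m <- sigma_m_sub[i]
    out[[i]] <- sub
  }
  dplyr::bind_rows(out)[, c("subject", "session", "trial", "sigma_m",
                            "stimulus", "percept", "choice", "correct",
                            "confidence")]
}

#' Write a simulated cohort to CSV
#'
#' Writes the flat per-trial format used by trial-level confidence
#' repositories: columns `Subj_idx`, `Session`, `Trial`, `Stimulus`,
#' `Response`, `Correct`, `Confidence`.
#'
#' @param cohort A tibble from [simulate_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- data.frame(
    Subj_idx = cohort$subject,
    Session = cohort$session,
    Trial = cohort$trial,
    Stimulus = cohort$stimulus,
    Response = cohort$choice,
    Correct = as.integer(cohort$correct),
    Confidence = cohort$confidence
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
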
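#' Read a trial-level confidence CSV into a study dataset
#'
#' Reads per-trial confidence data in the Confidence Database convention
#' (one row per trial, columns for subject id, stimulus, response and
#' confidence) and harmonizes it for the measure pipeline. Rows are grouped
#' by subject with trial order preserved. Stimulus and response must be
#' binary; their two levels are mapped to 0/1 by sorted order. Verbal
#' confidence labels are converted through a user-supplied mapping (any
#' unmapped label is an error, never silently dropped); fractional ratings
#' are kept as numeric confidence and handled by the downstream percentile
#' discretization. Scales that use negative ratings to signal confidence
#' in being wrong should be passed through [floor_negative_ratings()]
#' after discretization (not done automatically, since some scales start
#' legitimately at 0).
#'
#' @param path CSV file path (UTF-8, header row).
#' @param column_map Named character vector mapping the canonical names
#'   `subject`, `stimulus`, `response`, `confidence` (and optionally
#'   `session`) to the file's column names. Defaults to the Confidence
#'   Database names `Subj_idx`, `Stimulus`, `Response`, `Confidence`.
#' @param verbal_map Optional named numeric vector converting verbal
#'   confidence labels to numeric ratings, e.g.
#'   `c(difficult = 1, easy = 2)`.
#' @param study_id Study identifier stored with the dataset.
#' @param modality One of `"cognitive"`, `"memory"`, `"motor"`,
#'   `"perception"`, `"mixed"`.
#' @param metadata Optional named list of task characteristics (feedback,
#'   staircase, simultaneous report, scale type, number of rating levels).
#' @return An object of class `study_dataset`: a list with `study_id`,
#'   `modality`, `metadata` and `trials` (a tibble with `subject`,
#'   `stimulus`, `choice`, `correct`, `confidence`).
#' @export
read_trial_csv <- function(path,
                           column_map = c(subject = "Subj_idx",
                                          stimulus = "Stimulus",
                                          response = "Response",
                                          confidence = "Confidence"),
                           verbal_map = NULL, study_id = basename(path),
                           modality = c("perception", "cognitive", "memory",
                                        "motor", "mixed"),
                           metadata = list()) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject", "stimulus", "response", "confidence")
  if (!all(needed %in% names(column_map))) {
    stop("`column_map` must name columns for: ",
         paste(needed, collapse = ", "))
  }
  missing_cols <- setdiff(unname(column_map[needed]), names(raw))
  if (length(missing_cols)) {
    stop("missing columns in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  stim <- raw[[column_map[["stimulus"]]]]
  resp <- raw[[column_map[["response"]]]]
  to_binary <- function(x, what) {
    lev <- sort(unique(x))
    if (length(lev) > 2) {
      stop("non-binary ", what, ": found ", length(lev),
           " distinct values; only two-alternative tasks are supported")
    }
    as.integer(match(x, lev) - 1L)
  }
  stim <- to_binary(stim, "stimulus")
  resp <- to_binary(resp, "response")
  conf <- raw[[column_map[["confidence"]]]]
  if (!is.numeric(conf)) {
    if (is.null(verbal_map)) {
      suppressWarnings(num <- as.numeric(conf))
      if (anyNA(num) && !anyNA(conf)) {
        stop("verbal confidence labels found but no `verbal_map` given: ",
             paste(utils::head(unique(conf[is.na(num)])), collapse = ", "))
      }
      conf <- num
    } else {
      unmapped <- setdiff(unique(conf), names(verbal_map))
      if (length(unmapped)) {
        stop("unmapped verbal confidence labels: ",
             paste(unmapped, collapse = ", "))
      }
      conf <- unname(verbal_map[conf])
    }
  }
  trials <- tibble::tibble(
    subject = raw[[column_map[["subject"]]]],
    stimulus = stim,
    choice = resp,
    correct = stim == resp,
    confidence = conf
  )
  if ("session" %in% names(column_map) &&
      column_map[["session"]] %in% names(raw)) {
    trials$session <- raw[[column_map[["session"]]]]
  }
  structure(list(study_id = study_id, modality = modality,
                 metadata = metadata, trials = trials),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("Study '%s' (%s): %d subjects, %d trials\n", x$study_id,
              x$modality, length(unique(x$trials$subject)),
              nrow(x$trials)))
  invisible(x)
}

#' Write a study dataset back to CSV
#'
#' Inverse of [read_trial_csv()] with canonical column names; a written
#' dataset re-reads to identical trial tables.
#'
#' @param study A `study_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_study_csv <- function(study, path) {
  tr <- study$trials
  out <- data.frame(Subj_idx = tr$subject, Stimulus = tr$stimulus,
                    Response = tr$choice, Confidence = tr$confidence)
  if ("session" %in% names(tr)) out$Session <- tr$session
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Apply subject inclusion rules
#'
#' Retains subjects with at least `min_trials` trials and `d' > min_dprime`
#' (d' computed from the padded stimulus x response table with `k` rating
#' levels). The counts of retained and excluded subjects are attached as
#' attributes and reported via `message()`.
#'
#' @param study A `study_dataset`.
#' @param min_trials Minimum trials per subject (default 400).
#' @param min_dprime Minimum d' (exclusive, default 0.5).
#' @param k Rating levels used when tabulating counts for d'.
#' @return The filtered `study_dataset` with attributes `n_retained` and
#'   `n_excluded`.
#' @export
apply_inclusion <- function(study, min_trials = 400, min_dprime = 0.5,
                            k = 6) {
  stopifnot(inherits(study, "study_dataset"), min_trials >= 1)
  keep_subject <- function(tr) {
    if (nrow(tr) < min_trials) return(FALSE)
    d <- type1_stats(tabulate_counts(tr, k))$d_prime
    d > min_dprime
  }
  by_sub <- split(study$trials, study$trials$subject)
  keep <- vapply(by_sub, keep_subject, logical(1))
  out <- study
  out$trials <- dplyr::bind_rows(by_sub[keep])
  attr(out, "n_retained") <- sum(keep)
  attr(out, "n_excluded") <- sum(!keep)
  message(sprintf("apply_inclusion: retained %d of %d subjects",
                  sum(keep), length(keep)))
  out
}

#' Assign studies to split-half trial-number bins
#'
#' Bins studies by their typical split-half trial count (the median over
#' subjects of the test-half size), using intervals `(0, w]`, `(w, 2w]`,
#' ... with `w = bin_width`. Subjects whose own split-half count falls
#' outside their study's bin are flagged for exclusion.
#'
#' @param studies List of `study_dataset` objects.
#' @param bin_width Bin width on split-half counts (default 200).
#' @return A tibble with one row per subject: `study_id`, `subject`,
#'   `split_half_trials`, `study_bin`, `excluded`.
#' @export
assign_trial_bins <- function(studies, bin_width = 200) {
  stopifnot(bin_width > 0)
  rows <- lapply(studies, function(st) {
    by_sub <- split(st$trials, st$trials$subject)
    half <- vapply(by_sub, function(tr) ceiling(nrow(tr) / 2), 0)
    study_bin <- ceiling(stats::median(half) / bin_width)
    tibble::tibble(
      study_id = st$study_id,
      subject = names(by_sub),
      split_half_trials = unname(half),
      study_bin = study_bin,
      excluded = ceiling(half / bin_width) != study_bin
    )
  })
  dplyr::bind_rows(rows)
}

#' Cross-validated d' and measure table
#'
#' Splits each subject's trials into two interleaved halves and computes
#' type 1 d' on one half and the metacognitive measures on the other, so
#' that the measurement noise of the d' used as a predictor is independent
#' of the d' folded into the efficiency measures. This prevents spurious
#' correlations when regressing metacognitive efficiency on type 1
#' performance.
#'
#' @param study A `study_dataset` (typically after [apply_inclusion()]).
#' @param k Rating levels.
#' @param swap If `TRUE`, use the even half for d' and the odd half for the
#'   measures (statistically equivalent; useful for checking robustness).
#' @return A tibble with one row per subject: `subject`, `d_prime_cv`
#'   (from one half) plus all columns of [compute_measures()] (from the
#'   other half).
#' @export
crossvalidated_dprime_table <- function(study, k = 6, swap = FALSE) {
  stopifnot(inherits(study, "study_dataset"))
  by_sub <- split(study$trials, study$trials$subject)
  rows <- lapply(names(by_sub), function(id) {
    halves <- split_half_interleaved(by_sub[[id]])
    a <- if (swap) halves$retest else halves$test
    b <- if (swap) halves$test else halves$retest
    d_cv <- type1_stats(tabulate_counts(a, k))$d_prime
    ms <- compute_measures(b, k = k)
    dplyr::bind_cols(tibble::tibble(subject = id, d_prime_cv = d_cv), ms)
  })
  dplyr::bind_rows(rows)
}
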
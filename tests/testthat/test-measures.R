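test_that("percentile discretization balances bins and preserves order", {
  x <- seq(0, 1, length.out = 12)
  expect_equal(discretize_confidence(x, 6),
               c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5, 6, 6))
  # degenerate scale: everything in one bin
  expect_equal(discretize_confidence(rep(0.4, 10), 6), rep(1, 10))
  # k distinct equally frequent values map bijectively onto 1..k
  v <- rep(c(0.1, 0.3, 0.5, 0.8), each = 25)
  expect_equal(discretize_confidence(v, 4), rep(1:4, each = 25))
  # order preservation on arbitrary continuous input
  set.seed(2)
  z <- runif(500)
  r <- discretize_confidence(z, 6)
  expect_true(all(r[order(z)] == cummax(r[order(z)])))
  # never more than k levels, however fine the input scale
  expect_lte(length(unique(discretize_confidence(runif(1000) * 100, 6))), 6)
})

test_that("negative ratings are floored at the lowest rating", {
  expect_equal(floor_negative_ratings(c(-2, 1, 3)), c(1, 1, 3))
  expect_equal(floor_negative_ratings(1:5), 1:5)
  expect_equal(floor_negative_ratings(c(-3, -1, 0)), c(1, 1, 1))
})

test_that("count tabulation is a lossless order-invariant tally", {
  tt <- tibble::tibble(stimulus = c(0L, 0L, 1L, 1L),
                       choice = c(0L, 1L, 0L, 1L),
                       rating = c(1L, 1L, 1L, 1L))
  cnt <- tabulate_counts(tt, 2)
  expect_equal(sum(cnt), 4)
  expect_equal(cnt[, , 1], matrix(1L, 2, 2), ignore_attr = TRUE)
  # order invariance
  set.seed(1)
  tt2 <- make_rated_session(0.2, n = 300, seed = 10)
  perm <- sample(nrow(tt2))
  expect_equal(unclass(tabulate_counts(tt2, 6)),
               unclass(tabulate_counts(tt2[perm, ], 6)))
  # round trip: counts rebuild the trial multiset
  cnt2 <- tabulate_counts(tt2, 6)
  rebuilt <- expand.grid(stimulus = 0:1, choice = 0:1, rating = 1:6)
  rebuilt <- rebuilt[rep(seq_len(nrow(rebuilt)), as.vector(cnt2)), ]
  orig <- table(tt2$stimulus, tt2$choice, tt2$rating)
  expect_equal(as.vector(orig),
               as.vector(table(rebuilt$stimulus, rebuilt$choice,
                               rebuilt$rating)))
  expect_error(tabulate_counts(tibble::tibble(stimulus = 0L, choice = 0L,
                                              rating = 7L), 6), "1..k")
})

test_that("type 1 statistics follow the z-transform formulas", {
  mk <- function(h, f, n = 10000) {
    cnt <- array(0L, dim = c(2, 2, 2))
    cnt[2, 2, 1] <- round(n * h); cnt[2, 1, 1] <- round(n * (1 - h))
    cnt[1, 2, 1] <- round(n * f); cnt[1, 1, 1] <- round(n * (1 - f))
    structure(cnt, class = c("rating_counts", "array"))
  }
  t1 <- type1_stats(mk(0.84, 0.16))
  expect_equal(t1$d_prime, 1.989, tolerance = 0.005)
  expect_equal(t1$criterion, 0, tolerance = 0.005)
  # symmetric counts give a centered criterion, chance counts d' ~ 0
  expect_equal(type1_stats(mk(0.7, 0.3))$criterion, 0, tolerance = 0.005)
  expect_equal(type1_stats(mk(0.5, 0.5))$d_prime, 0, tolerance = 0.005)
  # padding keeps extreme rates finite
  t1x <- type1_stats(mk(1, 0, n = 100))
  expect_true(is.finite(t1x$d_prime))
})

test_that("AUROC2 matches hand-built ROC geometry and its limits", {
  # uninformative confidence: identical rating distributions
  correct <- rep(c(TRUE, FALSE), each = 30)
  ratings <- rep(rep(1:3, each = 10), 2)
  expect_equal(auroc2(correct, ratings), 0.5)
  # perfect type 2 separation
  expect_equal(auroc2(c(TRUE, TRUE, FALSE, FALSE), c(3, 3, 1, 1)), 1)
  # worked small case against the hand-built trapezoid
  cor3 <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  rat3 <- c(2, 2, 3, 1, 2)
  expect_equal(auroc2(cor3, rat3), 5 / 6)
  expect_equal(auroc2(cor3, rat3), oracle_auroc2(cor3, rat3))
  # random instances against the oracle, exactly
  for (s in 1:30) {
    set.seed(s)
    n <- sample(20:80, 1)
    co <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(co)) < 2) co[1:2] <- c(TRUE, FALSE)
    ra <- sample(1:6, n, replace = TRUE)
    expect_equal(auroc2(co, ra), oracle_auroc2(co, ra))
  }
  # invariance under strictly monotone relabeling
  relab <- c(2L, 3L, 10L, 11L, 50L, 60L)
  tt <- make_rated_session(0.2, n = 500, seed = 3)
  expect_equal(auroc2(tt$correct, tt$rating),
               auroc2(tt$correct, relab[tt$rating]))
  expect_error(auroc2(c(TRUE, TRUE), c(1, 2)), "undefined")
})

test_that("efficiency measures implement subtraction and division", {
  e <- efficiency_measures(1.5, 1.5)
  expect_equal(e$m_diff, 0)
  expect_equal(e$m_ratio, 1)
  e2 <- efficiency_measures(1.6, 0.8)
  expect_equal(e2$m_diff, -0.8)
  expect_equal(e2$m_ratio, 0.5)
  e3 <- efficiency_measures(0, 0.5)
  expect_true(is.na(e3$m_ratio))
  expect_equal(e3$m_diff, 0.5)
})

test_that("M_ratio regularization follows the exclusion/bound/log rules", {
  expect_equal(regularize_mratio(2.0, "bound"), 1.6)
  expect_equal(regularize_mratio(-0.5, "bound"), 0)
  expect_true(is.na(regularize_mratio(-0.5, "exclude")))
  expect_true(is.na(regularize_mratio(1.7, "exclude")))
  expect_equal(regularize_mratio(0.9, "exclude"), 0.9)
  expect_equal(regularize_mratio(0.05, "log"), log(0.1))
  expect_equal(regularize_mratio(0.05, "log"), -2.3026, tolerance = 1e-4)
  expect_equal(regularize_mratio(2, "log"), log(2))
  # bounding is idempotent and order-preserving
  set.seed(4)
  x <- rnorm(200, 0.8, 1.5)
  b <- regularize_mratio(x, "bound")
  expect_equal(regularize_mratio(b, "bound"), b)
  expect_true(all(diff(b[order(x)]) >= 0))
  expect_error(regularize_mratio(1, "bound", lb = 2, ub = 1), "smaller")
  expect_error(regularize_mratio(1, "log", lb = 0), "> 0")
})

test_that("the measure pipeline returns a coherent per-session row", {
  tt <- make_rated_session(0.15, accuracy = 0.8, n = 2000, seed = 21)
  ms <- compute_measures(tt)
  expect_equal(ms$m_diff, ms$meta_d - ms$d_prime)
  expect_equal(ms$m_ratio, ms$meta_d / ms$d_prime)
  expect_equal(ms$m_ratio_bounded,
               max(0, min(1.6, ms$m_ratio)))
  expect_true(ms$converged)
  expect_equal(ms$n_trials, 2000)
  # cohort wrapper keys rows by subject and session
  ch <- simulate_cohort(4, 400, n_sessions = 2, sigma_m = 0.2,
                        target_accuracy = 0.75, seed = 31)
  mc <- compute_measures_cohort(ch)
  expect_equal(nrow(mc), 8)
  expect_equal(sort(unique(mc$subject)), 1:4)
})
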
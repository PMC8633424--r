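test_that("parameter validation enforces the model's domain", {
  expect_error(generative_params(mu = 0), "mu")
  expect_error(generative_params(sigma_s = -1), "sigma_s")
  expect_error(generative_params(sigma_m = 0.51), "sigma_m")
  expect_silent(generative_params(mu = 1, sigma_s = 0, sigma_m = 0.5))
})

test_that("choice probability is the logistic posterior and is symmetric", {
  p1 <- generative_params(mu = 1, sigma_s = 1)
  expect_equal(choice_probability(0, p1), 0.5)
  expect_equal(choice_probability(0.5, p1), 1 / (1 + exp(-0.5)),
               tolerance = 1e-10)
  expect_equal(choice_probability(0.5, p1), 0.62246, tolerance = 1e-5)
  expect_equal(choice_probability(50, p1), 1, tolerance = 1e-10)
  # monotone increasing in the percept
  x <- seq(-3, 3, by = 0.1)
  expect_true(all(diff(choice_probability(x, p1)) > 0))
  # degenerate-noise observers have no defined choice probability
  expect_error(choice_probability(0.1, generative_params(sigma_s = 0)),
               "sigma_s = 0")
})

test_that("internal confidence folds the choice probability", {
  expect_equal(confidence_from_p(0.5), 0)
  expect_equal(confidence_from_p(1), 1)
  expect_equal(confidence_from_p(0.25), 0.5)
  p <- runif(50)
  expect_equal(confidence_from_p(p), confidence_from_p(1 - p))
})

test_that("Beta parameterization has mode c and the uniform limit", {
  sh <- beta_shape_params(0.7, 0.1)
  expect_equal(sh$alpha, 6.6)
  expect_equal(sh$beta, 3.4)
  sh0 <- beta_shape_params(0, 0.1)
  expect_equal(sh0$alpha, 1)
  expect_equal(sh0$beta, 9)
  # sigma_m = 0.5 gives Beta(1, 1) for any mode
  for (cc in c(0, 0.3, 1)) {
    shu <- beta_shape_params(cc, 0.5)
    expect_equal(shu$alpha, 1)
    expect_equal(shu$beta, 1)
  }
  # mode identity to machine precision over a (c, sigma_m) lattice
  for (cc in seq(0, 1, by = 0.05)) {
    for (sm in seq(0.01, 0.49, by = 0.04)) {
      sh <- beta_shape_params(cc, sm)
      expect_equal((sh$alpha - 1) / (sh$alpha + sh$beta - 2), cc,
                   tolerance = 1e-12)
    }
  }
  expect_error(beta_shape_params(0.5, 0), "sigma_m")
  expect_error(beta_shape_params(0.5, 0.6), "sigma_m")
})

test_that("confidence sampling honors the noiseless and uniform limits", {
  expect_identical(sample_confidence(c(0.3, 0.9), 0), c(0.3, 0.9))
  set.seed(42)
  u <- sample_confidence(rep(0.7, 1e5), 0.5)
  expect_gt(stats::ks.test(u, "punif")$p.value, 0.01)
  # empirical mode near c for small spread
  set.seed(43)
  x <- sample_confidence(rep(0.7, 2e5), 0.1)
  d <- stats::density(x)
  expect_equal(d$x[which.max(d$y)], 0.7, tolerance = 0.02)
  # spread increases confidence variance around a fixed mode
  v <- vapply(seq(0.05, 0.45, by = 0.1), function(sm) {
    sh <- beta_shape_params(0.6, sm)
    sh$alpha * sh$beta / ((sh$alpha + sh$beta)^2 * (sh$alpha + sh$beta + 1))
  }, numeric(1))
  expect_true(all(diff(v) > 0))
})

test_that("sigma_for_accuracy inverts the accuracy closed form", {
  expect_equal(sigma_for_accuracy(0.6), 1.9737, tolerance = 1e-4)
  expect_equal(sigma_for_accuracy(0.9), 0.39015, tolerance = 1e-4)
  expect_lt(sigma_for_accuracy(0.999), 0.17)
  expect_error(sigma_for_accuracy(0.5), "strictly")
  expect_error(sigma_for_accuracy(1), "strictly")
  # Monte-Carlo confirmation at two levels
  set.seed(7)
  for (acc in c(0.6, 0.9)) {
    pars <- generative_params(1, sigma_for_accuracy(acc), 0)
    expect_equal(mean(simulate_session(pars, 1e5)$correct), acc,
                 tolerance = 0.005)
  }
})

test_that("simulated sessions match the model's closed forms", {
  # noiseless observer: always correct, full confidence
  tt0 <- simulate_session(generative_params(1, 0, 0), 100)
  expect_true(all(tt0$correct))
  expect_true(all(tt0$confidence == 1))
  # accuracy matches Phi(mu / (2 sigma_s)) across noise levels
  set.seed(11)
  for (ss in c(0.5, 1, 2, 4)) {
    tt <- simulate_session(generative_params(1, ss, 0.2), 1e5)
    expect_equal(mean(tt$correct), pnorm(1 / (2 * ss)), tolerance = 0.01)
  }
  # determinism under a fixed seed
  set.seed(99)
  a <- simulate_session(generative_params(1, 1, 0.2), 500)
  set.seed(99)
  b <- simulate_session(generative_params(1, 1, 0.2), 500)
  expect_identical(a, b)
})

test_that("confidence is invariant under stimulus category relabeling", {
  pars <- generative_params(1, 1.5, 0.25)
  stim <- rep(c(0L, 1L), 100)
  set.seed(123)
  a <- simulate_session(pars, 200, stimuli = stim)
  set.seed(123)
  b <- simulate_session(pars, 200, stimuli = 1L - stim)
  expect_identical(a$confidence, b$confidence)
  expect_identical(a$correct, b$correct)
  expect_identical(b$choice, 1L - a$choice)
  expect_equal(b$percept, -a$percept)
})

test_that("cohorts fix sigma_m per subject and honor the seeding contract", {
  ch <- simulate_cohort(20, 50, n_sessions = 2, sigma_m = "uniform",
                        target_accuracy = 0.75, seed = 5)
  expect_equal(nrow(ch), 20 * 2 * 50)
  per_sub <- tapply(ch$sigma_m, ch$subject, function(x) length(unique(x)))
  expect_true(all(per_sub == 1))
  expect_equal(unname(table(ch$subject, ch$session)[1, ]), c(50, 50),
               ignore_attr = TRUE)
  ch2 <- simulate_cohort(20, 50, n_sessions = 2, sigma_m = "uniform",
                         target_accuracy = 0.75, seed = 5)
  expect_identical(ch, ch2)
  ch3 <- simulate_cohort(20, 50, n_sessions = 2, sigma_m = "uniform",
                         target_accuracy = 0.75, seed = 6)
  expect_false(identical(ch$confidence, ch3$confidence))
  # uniform sampling spans most of [0, 0.5]
  ch4 <- simulate_cohort(100, 2, sigma_m = "uniform",
                         target_accuracy = 0.75, seed = 8)
  sm <- unique(ch4$sigma_m)
  expect_length(sm, 100)
  expect_lt(min(sm), 0.05)
  expect_gt(max(sm), 0.45)
})

test_that("cohort CSV export uses the flat per-trial convention", {
  ch <- simulate_cohort(3, 10, n_sessions = 2, sigma_m = 0.2,
                        target_accuracy = 0.8, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(ch, path)
  re <- utils::read.csv(path)
  expect_named(re, c("Subj_idx", "Session", "Trial", "Stimulus",
                     "Response", "Correct", "Confidence"))
  expect_equal(nrow(re), 60)
  expect_equal(re$Confidence, ch$confidence)
})
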
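# Shared fixtures and independent oracles for the test suite. Everything
# is generated in code; no data files.

# One rated session from the generative model.
make_rated_session <- function(sigma_m, accuracy = 0.75, n = 1000, k = 6,
                               seed = NULL, sigma_s = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sigma_s)) sigma_s <- sigma_for_accuracy(accuracy)
  pars <- generative_params(mu = 1, sigma_s = sigma_s, sigma_m = sigma_m)
  tt <- simulate_session(pars, n)
  tt$rating <- discretize_confidence(tt$confidence, k)
  tt
}

make_counts <- function(...) tabulate_counts(make_rated_session(...))

# Brute-force AUROC2: builds the type 2 ROC point by point with explicit
# loops and accumulates the trapezoid area segment by segment.
oracle_auroc2 <- function(correct, ratings) {
  correct <- as.logical(correct)
  thresholds <- sort(unique(ratings), decreasing = TRUE)
  fa <- 0
  hit <- 0
  area <- 0
  prev_fa <- 0
  prev_hit <- 0
  for (th in thresholds) {
    hit <- sum(correct & ratings >= th) / sum(correct)
    fa <- sum(!correct & ratings >= th) / sum(!correct)
    area <- area + (fa - prev_fa) * (hit + prev_hit) / 2
    prev_fa <- fa
    prev_hit <- hit
  }
  area + (1 - prev_fa) * (1 + prev_hit) / 2
}

# Exhaustive grid-search maximizer of the meta-level likelihood for K = 2
# rating levels. Written from the model definition, independently of the
# package optimizer: for each candidate meta-d' the single type 2
# criterion on each side of the (fixed, relative) type 1 criterion is
# profiled over a fine grid, then polished with a 1-D golden-section
# search inside the winning grid bracket (so the profile is exact and the
# only quantization left is the meta-d' grid itself). Returns the grid
# argmax and its logL.
oracle_grid_metad <- function(counts, metad_grid = seq(-3, 3, by = 0.01),
                              crit_offsets = seq(0.005, 5, by = 0.005)) {
  stopifnot(dim(counts)[3] == 2)
  padded <- counts + 1 / 4
  t1 <- type1_stats(counts)
  c_rel <- t1$criterion / t1$d_prime
  best_nll <- Inf
  best_md <- NA_real_
  clog <- function(p) log(pmax(p, 1e-12))
  step <- crit_offsets[2] - crit_offsets[1]
  for (md in metad_grid) {
    mc <- c_rel * md
    # response 0: rating 2 below cutpoint mc - off, rating 1 up to mc
    f0 <- function(off) {
      nll <- 0
      for (s in 1:2) {
        mu_s <- c(-1, 1)[s] * md / 2
        p2 <- pnorm(mc - off - mu_s) / pnorm(mc - mu_s)
        nll <- nll -
          (padded[s, 1, 2] * clog(p2) + padded[s, 1, 1] * clog(1 - p2))
      }
      nll
    }
    # response 1: rating 1 up to cutpoint mc + off, rating 2 above
    f1 <- function(off) {
      nll <- 0
      for (s in 1:2) {
        mu_s <- c(-1, 1)[s] * md / 2
        p2 <- (1 - pnorm(mc + off - mu_s)) / (1 - pnorm(mc - mu_s))
        nll <- nll -
          (padded[s, 2, 2] * clog(p2) + padded[s, 2, 1] * clog(1 - p2))
      }
      nll
    }
    polish <- function(f) {
      coarse <- f(crit_offsets)
      at <- crit_offsets[which.min(coarse)]
      stats::optimize(f, c(max(at - step, 1e-9), at + step))$objective
    }
    nll <- polish(f0) + polish(f1)
    if (nll < best_nll) {
      best_nll <- nll
      best_md <- md
    }
  }
  list(meta_d = best_md, log_likelihood = -best_nll)
}

# Random small K = 2 count tables of ~200 trials with heterogeneous
# observers, for oracle comparisons.
random_small_counts <- function(seed) {
  set.seed(seed)
  sm <- runif(1, 0, 0.5)
  acc <- runif(1, 0.6, 0.9)
  tt <- make_rated_session(sm, accuracy = acc, n = 200, k = 2)
  tabulate_counts(tt, 2)
}
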
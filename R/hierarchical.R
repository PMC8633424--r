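# Build the JAGS model string for the hierarchical M_ratio model. The
# middle interval loops only exist for K > 2, and JAGS loops over
# decreasing ranges instead of skipping them, so the string is assembled
# conditionally.
hmeta_model_string <- function(k) {
  mid0 <- if (k > 2) "
      for (i in 2:(K-1)) {
        q0[n,s,i] <- phi(cS1[n,i] - mus[n,s]) - phi(cS1[n,i-1] - mus[n,s])
        q1[n,s,i] <- phi(cS2[n,i] - mus[n,s]) - phi(cS2[n,i-1] - mus[n,s])
      }" else ""
  paste0("
model {
  mu_logMratio ~ dnorm(0, 1)
  sigma_logMratio ~ dt(0, 1, 5) T(0.001,)
  lambda_logMratio <- pow(sigma_logMratio, -2)
  for (n in 1:N) {
    logMratio[n] ~ dnorm(mu_logMratio, lambda_logMratio)
    Mratio[n] <- exp(logMratio[n])
    metad[n] <- Mratio[n] * d1[n]
    metac[n] <- crel[n] * metad[n]
    for (j in 1:(K-1)) {
      g1[n,j] ~ dgamma(2, 2)
      g2[n,j] ~ dgamma(2, 2)
    }
    for (j in 1:(K-1)) {
      cS1[n,j] <- metac[n] - sum(g1[n, 1:(K-j)])
      cS2[n,j] <- metac[n] + sum(g2[n, 1:j])
    }
    mus[n,1] <- -metad[n] / 2
    mus[n,2] <-  metad[n] / 2
    for (s in 1:2) {
      q0[n,s,1] <- phi(cS1[n,1] - mus[n,s])
      q0[n,s,K] <- phi(metac[n] - mus[n,s]) - phi(cS1[n,K-1] - mus[n,s])
      q1[n,s,1] <- phi(cS2[n,1] - mus[n,s]) - phi(metac[n] - mus[n,s])
      q1[n,s,K] <- 1 - phi(cS2[n,K-1] - mus[n,s])", mid0, "
      for (r in 1:K) {
        p0[n,s,r] <- max(q0[n,s,K+1-r], 1.0E-8)
        p1[n,s,r] <- max(q1[n,s,r], 1.0E-8)
      }
      n0[n,s,1:K] ~ dmulti(p0[n,s,1:K], N0[n,s])
      n1[n,s,1:K] ~ dmulti(p1[n,s,1:K], N1[n,s])
    }
  }
}
")
}

#' Hierarchical Bayesian estimation of M_ratio
#'
#' Group-level regularization of metacognitive efficiency in the spirit of
#' Fleming's HMeta-d: each subject's log M_ratio is drawn from a group
#' Normal distribution, the subject's meta-d' is `M_ratio * d'` with `d'`
#' (and the relative type 1 criterion) fixed at the subject's
#' signal-detection point estimates, and the confidence-rating counts in
#' each (stimulus, response) cell follow the same meta-level multinomial
#' likelihood as [fit_meta_d()]. The group prior shrinks noisy per-subject
#' estimates toward the group mean; because M_ratio is modeled on the log
#' scale, hierarchical estimates are strictly positive.
#'
#' Requires the `rjags` package (and a JAGS installation); posterior
#' sampling uses `n_chains` parallel chains and convergence is assessed
#' with the Gelman-Rubin statistic over the monitored `Mratio` nodes.
#'
#' @param counts_list List of `rating_counts` arrays (one per subject, same
#'   K), at least 2 subjects; every subject must have `d' > 0`.
#' @param n_chains,n_adapt,n_burnin,n_iter MCMC settings (total sampled
#'   iterations per chain is `n_iter`).
#' @param seed Optional integer seed (drives the JAGS RNGs).
#' @return A list of class `hierarchical_mratio_fit` with `m_ratio`
#'   (posterior mean per subject), `m_ratio_mle` (per-subject maximum
#'   likelihood values for reference), `group_logmratio_mean`,
#'   `group_logmratio_sd`, `psrf` (max point estimate), `converged`.
#' @export
hierarchical_mratio <- function(counts_list, n_chains = 3, n_adapt = 500,
                                n_burnin = 500, n_iter = 2000,
                                seed = NULL) {
  if (!requireNamespace("rjags", quietly = TRUE)) {
    stop("hierarchical_mratio requires the `rjags` package")
  }
  stopifnot(is.list(counts_list), length(counts_list) >= 2)
  n <- length(counts_list)
  k <- dim(counts_list[[1]])[3]
  stopifnot(all(vapply(counts_list, function(x) dim(x)[3], 0L) == k))
  t1 <- lapply(counts_list, type1_stats)
  d1 <- vapply(t1, `[[`, 0, "d_prime")
  if (any(d1 <= 0)) {
    stop("all subjects must have d' > 0 for hierarchical estimation")
  }
  crel <- vapply(t1, `[[`, 0, "criterion") / d1
  mle <- vapply(counts_list, function(cc) {
    tryCatch(fit_meta_d(cc)$meta_d, error = function(e) NA_real_)
  }, 0) / d1
  n0 <- array(0L, dim = c(n, 2, k))
  n1 <- array(0L, dim = c(n, 2, k))
  for (i in seq_len(n)) {
    n0[i, , ] <- counts_list[[i]][, 1, ]
    n1[i, , ] <- counts_list[[i]][, 2, ]
  }
  # dmulti needs a positive total in every cell; uniform-pad cells that
  # are entirely empty (possible at very small trial counts)
  for (i in seq_len(n)) for (s in 1:2) {
    if (sum(n0[i, s, ]) == 0L) n0[i, s, ] <- 1L
    if (sum(n1[i, s, ]) == 0L) n1[i, s, ] <- 1L
  }
  data <- list(N = n, K = k, d1 = d1, crel = crel, n0 = n0, n1 = n1,
               N0 = apply(n0, c(1, 2), sum), N1 = apply(n1, c(1, 2), sum))
  if (!is.null(seed)) set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max, n_chains)
  inits <- lapply(seq_len(n_chains), function(ch) {
    list(logMratio = log(pmin(pmax(ifelse(is.na(mle), 1, mle), 0.1), 3)),
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = chain_seeds[ch])
  })
  model <- rjags::jags.model(textConnection(hmeta_model_string(k)),
                             data = data, inits = inits,
                             n.chains = n_chains, n.adapt = n_adapt,
                             quiet = TRUE)
  stats::update(model, n_burnin, progress.bar = "none")
  samp <- rjags::coda.samples(model,
                              c("Mratio", "mu_logMratio", "sigma_logMratio"),
                              n.iter = n_iter, progress.bar = "none")
  mat <- do.call(rbind, lapply(samp, as.matrix))
  m_cols <- if (n == 1) "Mratio" else paste0("Mratio[", seq_len(n), "]")
  psrf <- tryCatch({
    gd <- coda::gelman.diag(samp[, m_cols, drop = FALSE],
                            autoburnin = FALSE, multivariate = FALSE)
    max(gd$psrf[, 1])
  }, error = function(e) NA_real_)
  structure(list(
    m_ratio = unname(colMeans(mat[, m_cols, drop = FALSE])),
    m_ratio_mle = mle,
    group_logmratio_mean = mean(mat[, "mu_logMratio"]),
    group_logmratio_sd = mean(mat[, "sigma_logMratio"]),
    psrf = psrf,
    converged = is.finite(psrf) && psrf < 1.1,
    n_subjects = n
  ), class = "hierarchical_mratio_fit")
}

#' @export
print.hierarchical_mratio_fit <- function(x, ...) {
  cat(sprintf(
    "Hierarchical M_ratio fit: %d subjects, group mean M_ratio = %.3f\n",
    x$n_subjects, exp(x$group_logmratio_mean)))
  cat(sprintf("  max PSRF = %.3f (converged: %s)\n", x$psrf, x$converged))
  invisible(x)
}
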
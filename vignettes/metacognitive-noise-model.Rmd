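---
title: "A noisy-metacognition observer model and the measurement of metacognitive performance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A noisy-metacognition observer model and the measurement of metacognitive performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metacogsim)
```

## The generative model

`metacogsim` simulates an observer performing a two-alternative
categorization task with confidence ratings. The model has three
parameters, bundled in `generative_params()`:

* `mu` — the separation of the two stimulus category means. Percept means
  sit at $-\mu/2$ and $+\mu/2$. Only the ratio $\mu/\sigma_s$ is
  identified, so `mu` is fixed at 1 by convention throughout the package;
  type 1 sensitivity is then $d' = 1/\sigma_s$, which keeps simulated
  $d'$ values directly interpretable.
* `sigma_s` — the standard deviation of Gaussian sensory noise on the
  percept, $x \sim N(\pm\mu/2, \sigma_s)$. The expected proportion correct
  of the unbiased observer is $\Phi(\mu/(2\sigma_s))$;
  `sigma_for_accuracy()` inverts this closed form, which is how the grid
  experiments target accuracy levels. $\sigma_s = 0$ is the noiseless
  limit: every response is correct and internal confidence is 1.
* `sigma_m` — the metacognitive noise spread, in $[0, 0.5]$.

Given a percept, the observer computes the Bayesian probability of
category 1 under equal priors,
$p = 1/(1 + \exp(-\mu x / \sigma_s^2))$, responds category 1 whenever
$p \ge 0.5$ (the tie at exactly 0.5 goes to category 1), and forms the
choice-independent internal confidence $c = 2\,|p - 0.5| \in [0, 1]$.
Reported confidence is then a draw from a Beta distribution
parameterized by its mode:

$$\alpha = c\,(1/\sigma_m - 2) + 1, \qquad
  \beta = (1 - c)\,(1/\sigma_m - 2) + 1 .$$

This distribution always has mode $c$ (an identity the test suite checks
to machine precision), is supported on $[0,1]$ so no clipping is ever
needed, and interpolates between two interpretable limits: at
$\sigma_m \to 0$ reports equal $c$ (the package treats $\sigma_m = 0$ as a
deterministic pass-through, since the parameterization itself is undefined
there), and at $\sigma_m = 0.5$ the shapes are $(1, 1)$ — confidence is a
uniform random number carrying no information. Note $\sigma_m$ is a spread
parameter, not a standard deviation. Alternative noise kernels can be
studied by replacing `sample_confidence()`, which is the single point
where noise enters.

Two implementation details are worth stating. First, the percept is
generated as $(2s - 1)(\mu/2 + \sigma_s z)$ with $z \sim N(0,1)$, which
has exactly the distribution above but makes a session *bitwise* symmetric
under relabeling of the categories: with the same seed, flipping the
stimulus labels flips percepts and choices while leaving correctness and
the confidence stream unchanged. Internal confidence is likewise evaluated
at $|x|$ so the symmetry holds in floating point, not just in
distribution. Second, the observer has no type 1 bias parameter: the model
criterion is at percept 0.

Cohorts (`simulate_cohort()`) draw each subject's $\sigma_m$ once —
uniformly on $[0, 0.5]$ under the `"uniform"` rule, spanning ideal to
metacognitively blind observers — and share it across that subject's
sessions. Sharing is what makes test-retest correlations meaningful: the
subject's *trait* is fixed and only measurement noise differs between
sessions. A single cohort seed derives per-subject seeds, so any subject
can be regenerated in isolation.

## From trials to measures

Continuous confidence is discretized per subject-session into at most
`k = 6` percentile bins (`discretize_confidence()`), mirroring the cap of
6 rating levels used when harmonizing heterogeneous empirical confidence
scales. Duplicate percentile edges are collapsed and ratings renumbered,
so degenerate confidence distributions simply yield fewer levels. Six bins
retain enough of the confidence ordering that an ideal observer's
meta-$d'$ still converges to $d'$; the choice is configurable.

All counts pass through a $1/(2K)$ padding of every
stimulus-by-response-by-rating cell before rates are formed — the
convention of the original meta-$d'$ code — which removes infinite
$z$-scores at small counts at the cost of a negligible large-sample bias.

`fit_meta_d()` maximizes the multinomial likelihood of the rating counts,
conditional on each (stimulus, response) cell, under an equal-variance
SDT model with sensitivity meta-$d'$ and the type 1 criterion fixed at
the observed *relative* position $c' = c/d'$. The $K-1$ type 2 criteria on
each side are parameterized as ordered positive increments away from the
criterion (log-gaps), so monotonicity is enforced by construction rather
than by constraints; optimization uses `nlminb` started from
quantile-matched criteria and meta-$d' = d'$. The fit is validated two
ways: an exhaustive grid search over (meta-$d'$, profiled criteria) on
small 2-rating tables must agree within one 0.01 grid step and never find
a higher likelihood, and simulated ideal observers must recover
meta-$d' = d'$. Exactly chance-level counts ($d' = 0$) are rejected: the
relative criterion, and M_ratio itself, are undefined there, and the
missing value propagates pairwise into downstream reliability
computations.

The efficiency measures are $M_{\mathrm{diff}} = \text{meta-}d' - d'$ and
$M_{\mathrm{ratio}} = \text{meta-}d'/d'$. Because $M_{\mathrm{ratio}}$
explodes when $d'$ is small, four remedies are provided
(`regularize_mratio()`, `hierarchical_mratio()`):

| variant | rule | defaults |
|---|---|---|
| excluded | drop values outside $[lb, ub]$ | $lb = 0$, $ub = 1.6$ |
| bounded | clip into $[lb, ub]$ | $lb = 0$, $ub = 1.6$ |
| logarithmic | $\log\max(lb, M_{\mathrm{ratio}})$ | $lb = 0.1$ |
| hierarchical | group-prior shrinkage | see below |

The bounds 0 and 1.6 correspond to a metacognitively blind observer and to
a value symmetric, around a typical empirical median of 0.8, with that
floor. In reliability experiments an additional guard drops raw
$|M_{\mathrm{ratio}}| > 10$ pairs, which otherwise destabilize the
statistics at low accuracy and few trials.

The hierarchical variant places a Normal group prior on subject-level
$\log M_{\mathrm{ratio}}$ and evaluates the same conditional type 2
likelihood per subject, with $d'$ and $c'$ fixed at their point estimates;
it is fit by MCMC (JAGS via `rjags`, three chains, Gelman–Rubin PSRF
reported, criterion gaps given weakly informative Gamma(2, 2) priors and
the group SD a half-$t$). Modeling on the log scale constrains
hierarchical estimates to be positive and shrinks noisy extremes toward
the group mean — which also means estimates from different cohorts are not
comparable (they depend on the cohort's group posterior), and the NMAE is
invalid for this variant because separate test and retest group priors
compress each session's values around its own mean. `reliability()`
therefore flags NMAE as missing for hierarchical inputs.

## Reliability statistics

For aligned per-subject test/retest vectors $x, y$ the package computes
the Pearson correlation and the normalized mean absolute error

$$\mathrm{NMAE}(x,y) = \frac{\tfrac1N \sum_i |x_i - y_i|}
  {\tfrac{1}{2N}\sum_i |x_i - \bar y| + \tfrac{1}{2N}\sum_i |y_i - \bar x|},$$

whose denominator (each value's mean distance to the *other* session's
average) makes it invariant to common positive affine rescalings, so
absolute errors are comparable across measures on different scales. An
NMAE of 1 means test values are no closer to the same subject's retest
value than to the retest group mean. Missing pairs are removed pairwise
per measure, maximizing usable pairs; counts of dropped pairs are
reported. Interleaved split-half sessions (`split_half_interleaved()`)
assign odd positions to "test" and even to "retest" (1-based on stored
trial order), so slow drifts within a session load equally on both halves.

## The simulation experiments and their scales

`run_dependency_grid()` maps every measure over a sensory-noise by
metacognitive-noise lattice; `run_reliability_grid()` maps Pearson/NMAE
reliability over an accuracy-by-trial-count lattice with fresh cohorts per
iteration, averaging per-iteration correlations on the $r$ scale (a
Fisher-$z$ option exists; with $r$ values well inside $(-1,1)$ and many
iterations the difference is negligible).

Default scales are desk scales, chosen so the full test suite and the
reproduction script run in minutes on a single core while Monte-Carlo
error stays well inside the tolerances checked: dependency grids use 10
sensory-noise levels covering mean $d' \approx 0.2$–$3$ (taken as
$1/\sigma_s$ over an even $d'$ grid; $\sigma_s = 0$ is excluded because
$d'$ is unbounded and the relative criterion undefined there), 6
metacognitive-noise levels from 0 to 0.5, 200 subjects and 2000 trials
per cell; reliability grids use 100-subject cohorts with 10–20
iterations. Full-scale runs (100 noise levels, 1000 subjects, 10,000
trials; 300 iterations) are available through the CLI `--full` flag or by
passing the grids explicitly.

Characteristic results, each recomputed by the acceptance tests: at fixed
metacognitive noise, AUROC2 and meta-$d'$ rise with $d'$ (so neither
isolates metacognition from task performance); $M_{\mathrm{diff}}$ falls
with $d'$ at every noise level and falls faster the noisier metacognition
is; $M_{\mathrm{ratio}}$ is flat at 1 for near-ideal and flat at 0 for
blind metacognition but at intermediate noise rises steeply from 0 near
chance and declines gently beyond $d' \approx 2$ — stable only in a
middling performance band. Test-retest reliability of $M_{\mathrm{ratio}}$
depends jointly on accuracy and trial count: roughly $r \approx 0.2$ at
60% correct with 250 trials per session, $0.4$ at 500, $0.6$ only near
1000 trials, versus $r \approx 0.8$ at 80% correct with 500 trials.

## What the generator does and does not emulate

The simulator produces equiprobable categories, a bias-free observer,
independent identically distributed trials, and confidence corrupted only
at report by a single Beta kernel. It does not emulate response times,
post-decisional evidence accumulation, learning or staircase dynamics
within a session, type 1 criterion shifts, serial dependencies in
confidence, or mixtures of stimulus difficulties — all present in real
datasets. Passing tests therefore demonstrate properties of the measures
under a clean, well-specified observer, not that empirical data meet
these assumptions; the `read_trial_csv()` pipeline applies the same
measure machinery to real trial tables, where those caveats apply.

## Numerical choices and degenerate inputs

* Optimizer: `nlminb`, relative tolerance $10^{-10}$, convergence flag
  surfaced as `converged`; probabilities floored at $10^{-12}$ inside the
  likelihood.
* Percentile ties: duplicate bin edges collapse; values equal to an edge
  go to the lower bin; all-constant confidence yields a single rating.
* AUROC2 needs at least one correct and one incorrect trial; otherwise it
  is undefined and signalled as an error (propagated as `NA` by
  `compute_measures()`).
* `nmae()` with identical constant sessions, and `pearson()` with any
  constant vector, are undefined and error; `reliability()` requires at
  least 3 usable pairs.
* Negative $d'$ subjects are admissible in the MLE pipeline (the criteria
  construction holds for either sign of meta-$d'$) but rejected by the
  positive-ratio hierarchical model.
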
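---
title: "Censored Gaussian process regression: model, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Censored Gaussian process regression: model, algorithms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(censgp)
```

## The problem

Longitudinal and functional measurements are often *value-censored*: an
assay reports "below 50 copies/mL" rather than a number, a glucose sensor
saturates at its upper limit, a survey top-codes an answer. Dropping such
records biases any smooth-curve estimate away from the censored region, and
treating the detection limit as if it were the measured value biases it
toward the limit. `censgp` does Gaussian process (GP) regression that treats
a censored record as what it is: the event that the latent response lies in
a known interval.

## Single-curve model

A latent function $f \sim \mathrm{GP}(0, K_\theta)$ is observed with iid
Gaussian noise, $Y(t_j) \mid f \sim N(f(t_j), \sigma^2)$. At $J_o$ times we
see the value $y_o$; at $J_c$ times we only learn that $Y_c$ lies in a box
$(\ell, u)$ — $(L, \infty)$ for right-censoring at limit $L$,
$(-\infty, L)$ for left-censoring, a finite interval for interval-censoring.
The kernel is the exponentiated quadratic
$K(s,t) = m^2 \exp\{-(s-t)^2 / (2\lambda^2)\}$, where the magnitude $m$ is
on the **standard-deviation scale** (prior SD of $f$; at $m = 1$ the SD and
variance conventions coincide, which is why the package states its
convention prominently).

Because $(Y_o, Y_c, f(\tilde t))$ is jointly Gaussian, everything has a
closed form built from normal box probabilities:

* **Likelihood.**
  $L(\Theta) = \phi(y_o; 0, \Sigma_o)\, P(\ell < Y_c < u \mid Y_o = y_o)$,
  with the second factor a multivariate normal box probability under the
  conditional law of $Y_c$ given $Y_o$. With no censored points this is the
  standard GP marginal likelihood; the box factor can only lower it.
* **Conditional posterior density** of $f(\tilde t)$: the no-censoring
  Gaussian posterior density times a ratio of two box probabilities, the
  numerator additionally conditioning on the proposed function values. The
  ratio up-weights functions that push the censored responses deep into
  their boxes.
* **Exact sampling.** A draw from the posterior is
  $\xi_{f|o} + \Sigma_{fc|o}\Sigma_{c|o}^{-1} P + Q$ where $P$ is a
  box-truncated multivariate normal draw on the censored block and $Q$ an
  independent Gaussian residual. No MCMC over function values is needed;
  the draws are exact (conditionally on $\Theta$). Left- and
  interval-censoring only change the truncation box, so all three censoring
  types are first-class throughout (a pure right-censoring problem
  reproduces the textbook one-sided formulas exactly).

## Multi-level model

For $n \ge 2$ curves measured around a common mean, $f_i = \mu + \eta_i$
with $\mu \sim \mathrm{GP}(0, K_{\theta_\mu})$ and the deviations
$(\eta_1,\dots,\eta_n)$ given a joint *sum-to-zero* GP prior: marginal
kernel $K_{\theta_\eta}$ and cross-covariance $-K_{\theta_\eta}/(n-1)$, so
that $\sum_i \eta_i \equiv 0$ and the mean/deviation split is identified.
The stacked covariance over subjects has $K_\mu + K_\eta$ diagonal blocks
and $K_\mu - K_\eta/(n-1)$ off-diagonal blocks; likelihood, posterior and
sampler carry over with the reduced vector
$\eta' = (\eta_1,\dots,\eta_{n-1})$, the last subject's deviation being
reconstructed as $\eta_n = -\sum_{i<n}\eta_i$ (exactly, in every draw; the
"dropped" subject is the **last in input order** and exchangeability over
subject order is a tested property). Subjects may have unequal, irregular
time grids and subject- or time-specific censoring limits; predictions are
made on one shared grid.

Two implementation notes:

* The Gaussian residual $Q$ of the multi-level sampler lives on an
  $nJ_p$-dimensional grid stack ($2010$ dimensions in the benchmark
  study). Rather than factorizing its covariance, the sampler draws $Q$
  *pathwise*: it simulates a joint prior replicate of
  $(\mu, \eta, Y_o, Y_c)$ and subtracts the fitted conditional mean of the
  replicate. The result has exactly the required law (conditioning on the
  data jointly equals conditioning sequentially) at a fraction of the cost.
* When no observation is censored and all subjects share one time grid,
  the marginal likelihood is computed by rotating the subject dimension:
  the scaled subject average has covariance $nK_\mu + \sigma^2 I$ and the
  $n-1$ orthogonal contrasts are iid with covariance
  $\tfrac{n}{n-1}K_\eta + \sigma^2 I$. This is an exact identity (tested
  against the generic stacked computation), used by the benchmark's
  uncensored comparison methods.

## The numerical kernel

Both likelihood and sampler reduce to two primitives, implemented in
compiled code:

* **`log_mvn_cdf`** evaluates $\log P(\ell < Z < u)$ for
  $Z \sim N(\mu, \Sigma)$ by separation-of-variables quasi-Monte Carlo: a
  variable-reordered Cholesky factorization (Gibson–Glasbey–Elston
  pivoting, least-probable intervals first) followed by a randomized
  Richtmyer lattice rule over the unit cube. All tail quantities use
  `pnorm`/`qnorm` in log space, so boxes with probabilities far below the
  smallest double (e.g. $e^{-600}$) retain full relative accuracy — which
  matters because hyperparameter search routinely visits such regions.
  Dimension 0 returns $\log 1$; dimension 1 is exact. The returned Monte
  Carlo error estimate comes from the spread across random shifts, and the
  point count doubles until a requested tolerance is met. Tested against
  `mvtnorm::pmvnorm` (an independent implementation of the same integral),
  against exact factorizations, and against plain Monte Carlo.
* **`sample_tmvn`** draws from a box-truncated multivariate normal. When
  the box probability (estimated by `log_mvn_cdf`) exceeds about $0.02$ it
  uses exact accept–reject from the untruncated normal; otherwise a
  parallel-chain Gibbs sampler — one independent chain per requested draw,
  started from the componentwise truncated marginals and swept `burn_in =
  100` times with univariate truncated-normal conditionals drawn by
  log-scale inverse-CDF. We chose accept–reject plus Gibbs over a minimax
  exponential-tilting sampler because the two regimes it covers (easy
  boxes, hard boxes) are exactly the regimes the study designs produce, and
  the agreement of the two routes on overlapping instances is itself a
  useful internal check (tested). Every draw is checked to lie strictly
  inside its box.

All linear algebra goes through Cholesky solves; explicit inverses are
never formed. Noise-free covariance blocks get a nugget of
$10^{-8} m^2$ on the diagonal because they are repeatedly factorized.
Covariances that are indefinite at floating-point level (large Schur
complements) are eigenvalue-clipped at zero with a warning above $10^{-6}$
relative mass; stacks too large to eigendecompose cheaply try Cholesky with
escalating jitter first.

## Empirical Bayes fitting

$\hat\Theta$ maximizes the observed-data log-likelihood over the log
parameters (3 in the single-curve model, 5 in the multi-level model).
Choices, since the procedure itself leaves them open:

* **Optimizer**: Nelder–Mead on log-parameters, followed by a restart with
  a fresh simplex at the endpoint. The restart matters: on the 5-parameter
  surface the first simplex occasionally collapses along a ridge (typical
  symptom: the mean-process magnitude wandering while the likelihood is
  flat), and a restart recovers the optimum at modest extra cost. A
  quasi-Newton option (`optimizer = "lbfgsb"`) is provided but the default
  is derivative-free: finite-difference gradients proved fragile near the
  boundary of the feasible box.
* **Starts**: the first start is data-driven (magnitude from the SD of the
  values with censored records represented by their finite bound, length
  scale from the time span, noise at 15% of the SD); additional starts are
  log-uniform perturbations of it. `fit_opts(n_starts = )` controls the
  count (default 5); the study harnesses use 1–3 (with the restart) after
  verifying recovery, to keep their runtimes proportionate.
* **Determinism**: the quasi-Monte Carlo CDF uses one fixed seed for the
  whole fit, so the objective is deterministic and smooth in the
  parameters, and two identical calls agree bit-wise. During optimization
  the CDF runs at a lean fixed point count (the objective error this
  induces, well under 0.1 log-likelihood units, is far below the curvature
  scale of the surface); reported final likelihoods use the same control,
  and `log_mvn_cdf` can always be called at tighter tolerance afterwards.
* **Bounds**: log-parameters are confined to $[-10, 10]$ to keep the CDF
  away from degenerate covariances.

## What the synthetic-data generator emulates

`sim_scenario()`/`simulate_dataset()` reproduce the two study conditions
used throughout:

* **Multi-curve benchmark**: $n = 10$ curves, $\mu$ from an exponentiated
  quadratic GP with magnitude 1 and length scale 1, deviations from a
  sum-to-zero GP with magnitude 0.5 and length scale 0.5, $n_{obs} = 26$
  (recovery checks use 51) equidistant points on $[-10, 10]$, iid
  $N(0, 0.2^2)$ noise, truth stored on a 201-point grid.
* **Single-curve coverage**: one curve per dataset from the magnitude-1,
  length-scale-1 kernel, $N_{obs}$ equidistant noisy observations.

Censoring is right-sided (left-sided is available) above a cut-off chosen
per dataset (empirical quantile, so each dataset censors exactly the target
fraction — we read "the 0.75 quantile" as the empirical one, consistent
with every dataset attaining 25%), or as one population-wide cut-off pooled
across all datasets, or as a fixed threshold. The oracle/include/exclude
comparison methods reuse the *same* noisy realizations (the generator
returns pre-censoring values), so methods differ only in censoring
handling; this pairing is a variance-reduction choice. Each method is
re-fitted by empirical Bayes on the data it sees, because each sees
different effective data.

What the generator does **not** emulate: irregular visit times,
subject-specific censoring limits varying over time (supported by the
model and the CSV reader, but not exercised by the generator), non-zero
prior means, non-Gaussian noise, and model misspecification. Passing tests
therefore demonstrate correctness of the inferential machinery under the
model, not robustness to violations of it.

## Evaluation choices

* Error metrics: ISE and IAE by the trapezoid rule on the 201-point grid;
  sup-norm over grid points ($f$-metrics summed, and sup maximized, over
  the $n$ curves).
* The censored-GP method's posterior means average 100 exact draws in the
  multi-level benchmark and 1000 in single-curve studies; methods whose
  posterior is exactly Gaussian use the closed-form mean.
* Credible intervals are equal-tailed sample quantiles of the draws (the
  interval construction is otherwise unspecified).
* Coverage is the proportion of intervals containing the true latent value
  at observation times, pooled over datasets and split by censoring status.
* Problem sizes: the shipped coverage study uses 200 datasets of
  $N_{obs} = 200$ (1000-draw posteriors), the benchmark 100 datasets, and
  the recovery check 20 replicates at $n_{obs} = 51$ — sizes at which the
  Monte Carlo spread of each summary is comfortably below the margins the
  tests assert, while a full suite run stays proportionate.

## Degenerate inputs and edge behavior

Empty observed or censored blocks are fully supported (likelihood terms
drop out; conditioning on nothing returns the prior). Duplicate times, and
grids overlapping data times, are permitted — the nugget keeps factors
positive definite. A truncation box whose probability is numerically zero
(below $e^{-690}$) raises an error rather than returning garbage draws.
The multi-level model refuses $n = 1$ (the univariate model *is* that
case). The density can be evaluated on grids that do not contain the
censored times; the box-probability ratio then marginalizes over the
censored-time function values implicitly, exactly as the closed form
prescribes.

## Known limitations

Hyperparameter uncertainty is ignored (empirical Bayes), so credible
intervals are slightly narrower than a full Bayes treatment would give —
visible as coverage a shade below nominal in the coverage study. Cost
grows cubically with the number of observations and the QMC dimension
equals the number of censored points, so problems with more than a few
hundred censored observations per likelihood evaluation are outside the
intended envelope. Only stationary exponentiated-quadratic kernels ship,
though the kernel interface accepts registered replacements.
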
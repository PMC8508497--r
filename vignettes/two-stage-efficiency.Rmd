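---
title: "Two-stage hospital efficiency analysis: BCC efficiency scores and multilevel zero-one inflated beta regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage hospital efficiency analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deazoib)
```

## The problem

Health-economics studies of hospital efficiency typically proceed in two
stages. First, each hospital (a *decision-making unit*, DMU) is scored by
data envelopment analysis (DEA): its observed conversion of inputs (beds,
personnel, purchases) into outputs (discharges, outpatient activity) is
compared with the best convex combination of its peers. Second, the
resulting efficiency scores are regressed on exogenous hospital and
regional characteristics to ask *which* features travel with efficiency.

The second stage is statistically awkward: pure technical efficiency (PTE)
lives in (0, 1], a noticeable fraction of units sits exactly at 1 (the
efficiency frontier), and hospitals are nested in regions. A Gaussian
linear model is misspecified on all three counts. This package implements
the combination that addresses them directly: an output-oriented
variable-returns-to-scale DEA for stage one, and a Bayesian **multilevel
zero-one inflated beta (ZOIB) regression** for stage two.

## Stage one: the output-oriented BCC program

For unit $0$ with inputs $x_{i0}$ and outputs $y_{r0}$, the program is

$$\max \varphi \quad \text{s.t.}\quad
\sum_j \lambda_j x_{ij} \le x_{i0},\;
\sum_j \lambda_j y_{rj} \ge \varphi\, y_{r0},\;
\sum_j \lambda_j = 1,\; \lambda_j \ge 0 .$$

The convexity constraint $\sum_j \lambda_j = 1$ imposes variable returns to
scale (the BCC technology). $\varphi \ge 1$ is the largest proportional
output expansion attainable at the unit's inputs; $\mathrm{PTE} =
1/\varphi \in (0, 1]$, with $\mathrm{PTE} = 1$ defining the frontier.

Numerical choices:

* The program is solved by a dense two-phase primal simplex with Bland's
  anti-cycling rule, written for exactly this problem shape (a handful of
  constraints, a few hundred variables). Tests cross-check it against an
  exhaustive vertex-enumeration oracle on small random instances.
* Solver feasibility tolerance is `1e-8`; the optimum is clipped to
  $\varphi \ge 1$ before inversion so PTE never exceeds 1 by round-off.
* Frontier membership uses `frontier_tol = 1e-6` (`pte >= 1 - 1e-6`),
  configurable; the underlying definition ("the value is 1") does not fix
  a tolerance, so ties at the frontier within LP noise count as efficient.
* Inputs and outputs must be strictly positive — they are counts, staffed
  beds and euros. Zero or negative entries are rejected at construction
  rather than patched by translation tricks.
* Degenerate optima are possible; only $\varphi$ is guaranteed unique.
  Intensity weights $\lambda$ are reported as found.
* Any normalisation of the raw columns (e.g. expenditure per bed) is the
  caller's responsibility; the DEA consumes final matrices.

## Stage two: the multilevel ZOIB model

PTE for unit $i$ in group $j$ has the mixed density

$$f(y) = \begin{cases}
\omega_{01}(1 - \theta) & y = 0\\
\omega_{01}\,\theta & y = 1\\
(1 - \omega_{01})\,\mathrm{Beta}(y;\ \mu\phi_B,\ (1-\mu)\phi_B) & 0 < y < 1
\end{cases}$$

where $\omega_{01}$ is the probability of an endpoint, $\theta$ the
conditional probability the endpoint is 1, $\mu$ the beta mean and
$\phi_B$ the beta precision (shapes $\alpha_1 = \mu\phi_B$, $\alpha_2 =
(1-\mu)\phi_B$). Two linear predictors carry the covariates:

$$\operatorname{logit}\mu_{ij} = \beta_0 + u_{0j}
  + \textstyle\sum_r \beta^{(1)}_r x^{(1)}_{rij}
  + \sum_r \beta^{(2)}_r x^{(2)}_{rj}, \qquad
  u_{0j} \sim N(0, \sigma_{u0}^2)$$

$$\operatorname{logit}\omega_{01,ij} = \gamma_0
  + \textstyle\sum_r \gamma^{(1)}_r x^{(1)}_{rij}
  + \sum_r \gamma^{(2)}_r x^{(2)}_{rj}$$

with $\theta$ and $\phi_B$ constant. Two structural choices deserve
emphasis:

* **No random intercept in the $\omega_{01}$ submodel.** The frontier
  submodel is written without a group effect, and we implement it exactly
  that way as a fidelity choice. One could argue for symmetry with the
  $\mu$ submodel; with typically $\sim$30 frontier units spread over 17
  groups there is very little information to estimate such an effect, and
  adding one would change the interpretation of the published layout this
  package mirrors.
* **Endpoint classification.** Observed responses within `endpoint_tol =
  1e-6` of 0 or 1 are snapped to the exact endpoint before the likelihood
  is evaluated. The discrete mass is defined on exact endpoints; stage-one
  LP round-off must not leak a frontier hospital into the continuous beta
  component. Zeros are supported by the density even though DEA cannot
  produce them (generators may emit them; real PTE data will not).

Effect measures are reported on the ratio scale: $I = \mu/(1-\mu)$ is the
*mean efficiency index* (MEI), $\exp\beta^{(k)}_r$ is the **ratio of mean
efficiency indices** (RMEI) for a one-standard-deviation increase (or
versus the reference category), and $\exp\gamma^{(k)}_r$ is the **odds
ratio** of frontier membership.

### Priors

The estimation convention this package follows uses improper flat priors
for all fixed effects. The remaining priors are stated only loosely in
that convention ("normal distribution for the variance of the random
error"), which cannot be meant literally — a normal prior on a variance
has negative support. We read it as a **half-normal prior on the standard
deviation** $\sigma_{u0}$ (scale 2.5 by default), the standard
weakly-informative choice. $\theta$ gets a uniform(0, 1) prior and the
beta precision a half-normal with scale 50; both are wide relative to the
plausible regime ($\theta$ near 1, precision near 14). Two sensitivity
configurations (`zoib_priors("gamma_sensitivity")`,
`"normal_sensitivity"`) swap the $\sigma_{u0}$/precision priors for gamma
or positive-truncated normal forms, mirroring the kind of sensitivity
analysis such studies report; the exact published alternatives are not
recoverable, so the shapes here are documented defaults
(Gamma(2, 1)/Gamma(2, 0.1); N(1, 1)/N(10, 10) truncated at zero).

### Posterior computation

Sampling is blocked adaptive Metropolis-within-Gibbs
(`sample_zoib()`), with defaults matching the reporting convention: 4
chains, 1000 warmup iterations, 5000 retained updates.

* Scalar random-walk updates for each fixed effect, each random
  intercept, $\log\sigma_{u0}$ and $\log\phi_B$, with proposal scales
  adapted toward 44% acceptance during warmup only (Robbins–Monro),
  then frozen, so retained draws come from a valid Markov chain.
* $\theta$ is drawn exactly: given the endpoint counts $(n_1, n_0)$ its
  conditional is Beta$(n_1 + 1, n_0 + 1)$ under the uniform prior. On
  zero-free data the posterior piles up near 1, as it should.
* Two remedies for the strong posterior coupling between the
  $\mu$-submodel intercept (and level-2 effects) and the random
  intercepts: *translation moves* that shift $\beta_0 \to \beta_0 + d$,
  $u_{0j} \to u_{0j} - d$ (and the analogous move along each level-2
  column), leaving the likelihood exactly unchanged and accepted on the
  $u$-prior ratio; and *joint block proposals* for the full $\beta$ and
  $\gamma$ vectors after warmup, scaled by the empirical covariance of
  the second half of warmup. Without these, the intercept's effective
  sample size is an order of magnitude smaller.
* Initialization: fixed effects at 0, $\sigma_{u0}$ at 1, $\theta$ at
  0.9, precision at 10, $u$ at 0, all jittered per chain; values sit in
  the plausible regime of published fits. A non-finite log posterior
  after 100 re-draws is an initialization failure.
* Per-chain seeds are derived deterministically from the master seed, so
  a run is reproducible bitwise from `(seed, config)`.

Convergence is assessed with rank-normalized split-chain $\widehat R$
(taking the larger of the bulk and folded statistics) and bulk/tail
effective sample sizes, with the acceptance thresholds $\widehat R <
1.01$ and ESS $> 400$. Posterior summaries use pooled post-warmup draws:
mean, sd, 2.5/97.5 percentiles with linear interpolation, and the
positive/negative coefficient probabilities. PCP counts draws strictly
greater than zero and ties at zero count as negative, so PCP + NCP = 1
exactly.

## Synthetic data: what is emulated and what is not

The real hospital dataset behind the published study is not publicly
deposited, so every stage here is validated on synthetic data with known
parameters.

* `simulate_hierarchy()` draws standard-normal covariates at both levels
  and a three-level ownership factor (public reference) with configurable
  prevalences; groups may be unbalanced, as real regions are.
* `simulate_zoib()` is the generative reading of the mixture, given any
  `zoib_params`.
* `simulate_production()` plants a known technology: a latent hospital
  scale drives all inputs (log-scale spread 0.15 around the scale, so
  inputs are strongly correlated, as beds, staff and spending are),
  frontier outputs are Cobb–Douglas in the inputs with exponents summing
  to 0.8 (decreasing returns — the VRS hull is the correct model class),
  and outputs are shrunk by a planted inefficiency factor: 1 with
  probability 0.14, otherwise Beta(7, 3). Planted frontier units lie on
  the concave technology, so the BCC stage provably scores them at
  PTE = 1. The measured frontier share exceeds the planted rate by a few
  points (near-frontier units land on the sampled hull) and measured
  interior PTE sits slightly above the planted factor, so these planted
  constants are calibrated such that the *measured* distribution centres
  on a mean PTE of 0.78 and a frontier share near 18.5% — the regime of
  the published system.
* `scenario_table3()` fixes a benchmark: 173 units in 17 unbalanced
  groups, ownership counts 147/12/14, and true parameters at
  published-regime posterior means, with $\theta = 0.97$, precision
  14.27, $\sigma_{u0} = 0.57$. We deliberately use a reduced covariate
  set (the ownership factor plus two level-1 and two level-2 standardized
  covariates carrying the published effect magnitudes 0.22/−0.01,
  0.10/0.00 in the mean submodel and −0.38/0.41, 1.86/−0.98 in the
  frontier submodel) rather than all fifteen published covariates: with
  173 units and ~30 frontier members, a fifteen-covariate frontier
  submodel is so weakly identified that recovery replicates measure
  little beyond prior tail behaviour, and the replicated fits would
  dominate the test budget.

What the generators do **not** emulate: the real sampling frame, case-mix
adjustment of discharges, monetary deflators, spatial correlation between
neighbouring regions, or measurement error in the inputs. Passing
recovery tests therefore show the estimator recovers parameters *of this
generative process* — they do not validate the substantive published
coefficient values, which depend on confidential data.

## Known limitations

* **Flat-prior small-sample behaviour of the frontier submodel.** With
  ~30 frontier units among 173, a logistic-type submodel under improper
  flat priors exhibits the classic rare-event finite-sample bias: the
  likelihood peak (and hence the posterior mass) sits further from zero
  than the generating values, and equal-tailed credible intervals can
  undercover fixed true values — particularly for level-2 effects, which
  see only 17 group-level contrasts, and for rare ownership categories.
  This is a property of the estimation convention itself, reproduced by
  an independent maximum-likelihood fit of the endpoint indicator, not of
  this implementation (whose posterior matches an independent JAGS
  implementation of the same model within Monte Carlo error; see the test
  suite). Weakly-informative priors on the fixed effects would remove it,
  at the cost of departing from the convention this package mirrors.
* The posterior mean of $\sigma_{u0}$ carries the usual upward shift of
  a right-skewed scale posterior at $J = 17$ groups.
* The random-walk sampler is adequate for the design sizes it targets
  (hundreds of units, tens of groups, tens of coefficients); it is not
  built for much larger designs, where a gradient-based sampler would be
  the right substitution — the sampling contract (`sample_zoib()`'s
  interface and diagnostics) is deliberately sampler-agnostic.
* Problem sizes used in the shipped validation suites: vertex-enumeration
  cross-checks at $n \le 6$, $m, s \le 2$ (200 instances); recovery
  studies with 20 replicates of the 173-unit benchmark at 4 chains ×
  (500 warmup + 1000 retained) iterations; diagnostic calibration at 4 ×
  5000 iid draws. These sizes were chosen so the full suite documents
  every contract while remaining convenient to run routinely.

## Worked example

```{r example, eval = FALSE}
library(deazoib)

# stage one on a planted technology
prod <- simulate_production(seed = 1)
dea <- run_dea(prod$dataset)
dea$summary

# stage two on the benchmark scenario
sc <- scenario_table3(seed = 1)
chains <- sample_zoib(sc$design, sc$y, chains = 4,
                      warmup = 500, iter = 1000, seed = 2)
summ <- summarize_posterior(chains)
convergence_check(summ[!grepl("^u\\[", summ$parameter), ])
report_table(summ, factor_columns = c(ownership = "public"))
```

The same pipeline runs from a CSV file and a declarative configuration
through `fit_two_stage()` / `study_config()`, or from the shell through
the `inst/cli/deazoib` script (verbs `dea`, `simulate`, `fit`).
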
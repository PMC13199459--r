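---
title: "Modelling FEV crash injury severity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling FEV crash injury severity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fevcrash)
```

This vignette is the package's account of its statistical content: the
ordered-outcome model with a random coefficient, how its likelihood is
simulated and verified, what the synthetic crash generator does and does not
emulate, the support-vector benchmark, and the numerical and design choices
that were genuinely open.

## The severity model

Crash severity is ordinal: property-damage-only (1), injury (2), fatal (3).
The model assigns crash $n$ a latent score

$$Y^*_n = \sum_k \beta_k x_{nk} + \beta'_n d_n + \vartheta_n,$$

where $x_{nk}$ are binary crash attributes, $d_n$ is the single covariate
carrying a random coefficient (the front-to-back-collision indicator in the
default specification), and $\vartheta_n$ is i.i.d. standard logistic noise.
Severity is the cut of $Y^*$ at thresholds $\tau_1 < \tau_2$, giving the
ordered-logit probabilities $F(\tau_1 - v)$, $F(\tau_2-v) - F(\tau_1-v)$,
$1 - F(\tau_2 - v)$ for latent mean $v$.

The random coefficient has *heterogeneity in means*:

$$\beta'_n = a_0 + a_1\,\mathrm{FEV\_at\_Fault}_n +
  a_2\,\mathrm{Straight\_Road}_n + \epsilon_n,
  \qquad \epsilon_n \sim N(0, \sigma^2).$$

So the effect of a rear-end collision is not one number: it has a base level,
systematic shifts with fault attribution and road geometry, and residual
unobserved variation with spread $\sigma$.  The per-observation likelihood
integrates the ordered-logit probability over $\epsilon$; the sample
log-likelihood sums the logs of these mixed probabilities.

**CDF choice.** An ordered model is a *logit* precisely because the latent
noise is logistic; the package uses the standard logistic CDF throughout.
(Extreme-value noise yields a different family; a Gumbel CDF is exposed via
`cdf = "gumbel"` in the likelihood functions for sensitivity analyses, but
the logistic is canonical here.)

**Identification.** A free constant plus two free thresholds is not
identified: adding $c$ to the constant and to both thresholds changes no
probability.  `fit_rpol()` therefore estimates no constant and two free
thresholds.  For comparison with reports that print a constant alongside
both thresholds, `anchor_constant(fit, c)` re-expresses the fit as the
equivalent anchored triple $(c, \tau_1 + c, \tau_2 + c)$.

## Simulated maximum likelihood

The mixing integral has no closed form and is approximated by an average
over $R$ standard-normal draws per observation, transformed to
$\beta'$-space.  Defaults: $R = 500$, base-2 Halton (radical-inverse) points
with the first 10 discarded, and **Owen (nested uniform) scrambling**
implemented with the Laine–Karras hash permutation, one independent scramble
per observation.  Owen scrambling preserves the net structure of the point
set, so the per-observation integration error decays at the scrambled-net
rate rather than the $O(R^{-1})$ of a plain random shift — a difference that
matters when class probabilities are summed on the log scale.  Draws are
held fixed across optimizer iterations (common random numbers), keeping the
simulated likelihood a smooth, deterministic function of the parameters.
`method = "pseudo"` provides ordinary Monte-Carlo draws for comparison.

Per-observation simulated probabilities are floored at $10^{-300}$ before
the log, so the likelihood stays finite even at absurd parameter values.

**Optimization.** The free vector is $(\beta, a_0, a, \log\sigma, \tau_1,
\delta)$ with $\tau_2 = \tau_1 + e^\delta$, enforcing the threshold order,
and $\sigma$ on the log scale for positivity.  BFGS with the analytic
gradient (computed alongside the likelihood in compiled code) does the bulk
of the work; because the $\log\sigma$ direction becomes nearly flat when
$\hat\sigma \to 0$, the fit is polished with damped Newton steps against the
numerical Hessian until the gradient $\infty$-norm falls below `gtol`
(default $10^{-5}$), which is also the convergence flag.  Start values:
zero coefficients, $\sigma = 0.5$, thresholds at the logistic quantiles of
the empirical class shares.

**Standard errors** come from the inverse numerical Hessian; if it is not
positive definite the BHHH outer product of per-observation scores is used
instead (`$vcov_method` records which).

**Verification.** Two independent evaluations of the same integral guard the
simulation: `quadrature_loglik()` (Gauss–Hermite, internal Golub–Welsch
nodes, default 64 — accurate to ~$10^{-12}$ on these smooth integrands) and,
in the tests, a brute-force trapezoid over $\pm 8\sigma$.  With $\sigma = 0$
the mixture degenerates and both must equal the closed-form ordered logit
exactly; with $\sigma > 0$, 2000 scrambled Halton draws agree with 64-node
quadrature to about $10^{-3}$ in total log-likelihood on a 50-row fixture
whose class probabilities are bounded away from zero.  That conditioning
caveat is real: an observation whose realized class has probability ~0.01
contributes its *relative* integration error to the log-likelihood, and at
$R = 2000$ that term alone can exceed $10^{-3}$ whatever the scramble.  The
degenerate-and-extreme regime is therefore tested through the exact
$\sigma = 0$ route rather than the stochastic one.  A fixed-coefficient fit
is also cross-checked against `MASS::polr` (agreement to ~$10^{-6}$ at
$n = 2000$).

**Baselines.** McFadden's $\rho^2 = 1 - LL/LL_0$ needs a baseline $LL_0$.
The package uses the thresholds-only model, whose maximum is the closed form
$\sum_j n_j \log(n_j/n)$, and additionally reports the log-likelihood at the
start vector (`ll_start`), since published "initial log-likelihood" figures
can refer to either.

## The synthetic registry

The confidential crash registry (768 FEV-involved crashes, 2019–2024)
cannot be shipped, so `synth_data` draws tables with its marginal structure:

* **Exclusive groups** (hour block, weather, accident type, collision type,
  accident cause, second involved vehicle, lighting, pavement condition) are
  sampled one-hot from the registry's category counts, stored as counts out
  of 768 so probabilities sum to exactly 1.  Single-vehicle crashes carry an
  explicit `No_Second_Vehicle` category (379 of 768), which also fixes the
  denominator of second-vehicle shares at 389.
* **Flags** are independent Bernoulli.  `Weekend` and `Holiday` use registry
  frequencies; `FEV_at_Fault`, `Straight_Road` and `Single_Lane_Road` are
  not tabulated in the registry summaries and default to probability 0.5 —
  a deliberately uninformative choice, documented as unconstrained.
* **Severity** is simulated from the latent model with the published
  coefficient estimates as the generating truth (constant 0.07, nine fixed
  effects, random-coefficient mean $-0.99$ shifted by $-0.74$ and $+0.913$,
  thresholds $(-1.07, 3.18)$).  The published model reports no spread for
  the random coefficient, so the generator defaults to $\sigma = 1$ — the
  unit-spread convention for a coefficient of this magnitude.
* **Calibration.** With those coefficients and thresholds the implied class
  shares do not match the registry's 22.01 / 58.33 / 19.66%, so by default
  the two thresholds are re-solved by monotone bisection *on the realized
  latent values* until the cumulative shares match the target; because the
  empirical CDF steps in units of $1/n$, achieved shares are within $1/n$
  of the target, and the thresholds actually used are returned in the
  `"calibration"` attribute.  Pass `calibrate_to_shares = NULL` to use the
  thresholds as-is (the mode used for parameter-recovery studies, where the
  generating thresholds must be known).
* **Seeding.** One master seed is split into independent sub-streams for
  covariate sampling, the random-coefficient draw and the latent noise, so
  changing one stage never perturbs another.

What the generator does **not** emulate: cross-covariate dependence (the
registry publishes marginals only — a Gaussian-copula option exists for the
flags but is off by default), spatial structure, seasonality, reporting
artefacts, and any real association between pavement condition and the
other covariates.  Passing tests therefore demonstrate that the estimation
and evaluation machinery is correct under the model's own assumptions, not
that the published substantive findings generalize.

## Preprocessing

* **Pavement classification** combines PCI (0–100, higher is better) and
  IRI (m/km, higher is rougher) bands: PCI 90–100 / 60–90 / 40–60 / <40 and
  IRI ≤3 / 3–4 / >4.  IRI ≤ 3 is compatible with both of the two best
  categories, so that combination defers to PCI; any other disagreement
  returns the worse category with a conflict flag — the conservative rule
  for a maintenance-oriented index.
* **Screening** uses a chi-square test of each binary column against the
  3-class outcome (default $\alpha = 0.05$, with Cramér's V reported) and a
  phi-coefficient collinearity cutoff of 0.8, keeping the earlier column in
  specification order — deterministic tie-breaking.  The random-coefficient
  column is never dropped without an explicit override, because the model is
  undefined without it.  The statistic and thresholds are package choices;
  the tests verify the chi-square p-value against a permutation null.
* **Splitting** uses `floor(test_fraction * n)` test rows: at $n = 768$,
  fraction 0.2, this gives the 615/153 partition (plain rounding would give
  614/154).  Selected indices are exposed for exact reruns.
* **Descriptive tables** keep one denominator convention rather than mixing
  them: category shares divide by the rows with any indicator set in the
  grouping (= $n$ for exhaustive groups), per-severity shares divide by that
  severity's count among the same rows, all rounded to 2 decimals.

## The MC-SVM benchmark

The Crammer–Singer problem is solved in the dual by exact per-observation
coordinate minimization: each subproblem is a projection solved by monotone
root-finding, so the dual objective is non-increasing by construction (the
trace is returned).  Stopping: maximal per-observation KKT violation
$\le 10^{-6}$ or 1000 epochs; on a 30-point instance the achieved objective
matches an interior-point QP oracle to ~$10^{-12}$ relative.  The bias is
handled by unit-feature augmentation, which mildly regularizes it —
`objective_value()` evaluates the solver's (augmented) objective by default
and the textbook norm (bias excluded) on request.  Features are standardized
to mean 0 / sd 1 before fitting (stored in the model); predictions are
invariant to the round-trip.  Ties in the argmax go to the lower class
index.

The printed optimization problem is linear, and linear is the package's
canonical mode; because kernel methods are sometimes used for this problem,
an `"rbf"` mode exists as kernelized one-vs-rest hinge classifiers (via
kernlab), explicitly labelled an approximation rather than the joint
Crammer–Singer problem.

Regularization is chosen by stratified 5-fold cross-validation over
$C \in \{0.01, 0.1, 1, 10, 100\}$ on mean one-vs-rest macro-AUC, ties to the
smaller $C$ — protocol details the package fixes deterministically.

## Evaluation

ROC curves sweep a threshold over each class's score with tied scores
grouped into single steps; AUC is the trapezoid area, algebraically the
tie-corrected Mann–Whitney statistic (verified against a brute-force
pairwise count and against pROC).  Reporting is per-class one-vs-rest, with
macro-averaging used only inside cross-validation.  The generalization gap
is $\Delta AUC = AUC_{train} - AUC_{test}$ per class plus the mean, stored
exactly and rounded to 3 decimals only for display.  RPOL scores for ROC
purposes are the simulation-averaged class probabilities (probabilities at
the mean coefficient would be the alternative; AUC is invariant to any
monotone rescaling, but the mixture average is the model's actual
prediction).  Permutation importance shuffles one column at a time (default
metric: macro one-vs-rest AUC drop, 20 repeats); partial dependence clamps a
feature to each grid value and averages per-class predictions.

## Problem sizes in the test suite

The suite runs the full estimator at the registry scale (n = 615–768,
R = 100–500) and a 20-replication parameter-recovery study at n = 5000,
R = 200, in which the pooled 95%-interval coverage across the nine fixed
coefficients is required to reach 90%.  Pooling is deliberate: with only 20
replications, a per-coefficient 18-of-20 rule rejects a perfectly calibrated
estimator about half the time across nine coefficients, so it cannot
separate correct from incorrect implementations; the pooled rate over 180
cells has small enough binomial noise to do so.

## Known limitations

* One random coefficient, normal mixing, means-only heterogeneity: no
  heterogeneity in variances, no panel structure, no multinomial outcomes.
* The generator's independence assumptions understate real-world covariate
  correlation; estimated standard errors on synthetic data will be
  correspondingly clean.
* $\hat\sigma$ can sit on the $\sigma = 0$ boundary at registry-scale n;
  its standard error (reported on the log scale) is then uninformative, and
  the convergence flag relies on the Newton polish handling the flat
  direction.
* No probability calibration for SVM scores, no class re-weighting, no
  statistical tests comparing AUCs — out of scope by design.
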
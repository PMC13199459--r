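# fevcrash

Injury-severity analysis for crashes involving farm equipment vehicles
(FEVs) — tractors, harvesters and other farm machinery operating in mixed
traffic.  FEV crashes on interurban and rural roads are disproportionately
fatal, and their severity is shaped by interacting factors (collision
configuration, fault attribution, road geometry, lighting) whose effects
vary across crashes.  `fevcrash` packages the two complementary models used
to study this problem, together with a synthetic crash-registry generator so
the whole pipeline is runnable and testable without access to confidential
crash records:

* a **random-parameters ordered logit (RPOL) with heterogeneity in means**,
  estimated by simulated maximum likelihood, for interpretable inference on
  risk factors; and
* a **Crammer–Singer multi-class SVM (MC-SVM)** as a predictive benchmark,
  compared through per-class one-vs-rest ROC/AUC on train and test splits.

## The models

Crash severity is an ordinal outcome with three levels (1 = property damage
only, PDO; 2 = injury; 3 = fatal).  A latent severity score for crash *n*

```
Y*_n = Σ_k β_k x_nk + β′_n d_n + ϑ_n,        ϑ_n ~ standard logistic
```

is cut at thresholds τ₁ < τ₂: severity is 1 if `Y* ≤ τ₁`, 2 if
`τ₁ < Y* ≤ τ₂`, 3 otherwise, so the class probabilities are
`F(τ₁ − v)`, `F(τ₂ − v) − F(τ₁ − v)` and `1 − F(τ₂ − v)` with `F` the
logistic CDF.  One coefficient — on the front-to-back-collision indicator
`d_n` — is random with a mean that shifts with observed covariates
(heterogeneity in means):

```
β′_n = a₀ + a₁ FEV_at_Fault_n + a₂ Straight_Road_n + ε_n,   ε_n ~ N(0, σ²)
```

The likelihood integrates the ordered-logit probability over ε; the package
approximates this integral by averaging over Owen-scrambled Halton draws
(simulated maximum likelihood) and cross-checks it against deterministic
Gauss–Hermite quadrature.  Fit quality is summarized by McFadden ρ², AIC and
BIC.

The benchmark classifier solves the Crammer–Singer joint problem

```
min  ½ Σ_j ‖w_j‖² + C Σ_i ξ_i
s.t. w_{y_i}·x_i + b_{y_i} ≥ w_j·x_i + b_j + 1 − ξ_i   ∀ j ≠ y_i,  ξ_i ≥ 0
```

by exact per-observation dual coordinate descent, predicting
`argmax_j (w_j·x + b_j)`.

## Worked example

```r
library(fevcrash)

crashes <- simulate_crashes(768, seed = 42)        # synthetic registry
split   <- split_train_test(crashes, 0.2, seed = 42)
design  <- encode_design(split$train, fev_model_spec())

fit <- fit_rpol(design, R = 500, seed = 42)
fit
#> Random-parameters ordered logit (heterogeneity in means)
#>   observations: 615   parameters: 15   converged: TRUE
#>   log-likelihood: -476.460 (null -599.106, start -597.971)
#>   AIC 982.92  BIC 1049.25  rho2 0.205  rho2_bar 0.180

tidy(fit)[c(1, 4, 8, 10:12), ]
#>                                   term    group estimate std.error statistic  p.value
#>                  Unsafe_Distance_cause    fixed   -1.051     0.501     -2.10 0.035778
#>                      Overturn_Occurred    fixed    0.968     0.256      3.77 0.000161
#>                    Motorcycle_Involved    fixed    0.957     0.314      3.05 0.002308
#>    Front_to_Back_Collision (base mean) het_mean   -1.111     0.329     -3.38 0.000734
#>   Front_to_Back_Collision:FEV_at_Fault het_mean   -0.662     0.340     -1.95 0.051314
#>  Front_to_Back_Collision:Straight_Road het_mean    0.886     0.347      2.56 0.010583
```

Overturns and motorcycle involvement push crashes toward the fatal end of
the scale, keeping safe distance as the recorded cause pulls them down, and
the rear-end-collision effect is heterogeneous: protective on average
(−1.11), more protective when the FEV itself was at fault (−0.66), but
eroded on straight road segments (+0.89), where approach speeds are higher.

```r
svm  <- fit_mcsvm(design, C = 10, seed = 42)
test <- encode_design(split$test, fev_model_spec())
sp   <- score_and_predict(svm, test$X)
ovr_roc_auc(cbind(sp$score_pdo, sp$score_injury, sp$score_fatal), test$y)
#>   class       auc n_pos n_neg
#>     PDO 0.8075489    37   116
#>  Injury 0.6448029    93    60
#>   Fatal 0.8046823    23   130
```

Per-class test AUCs around 0.64–0.81: the extreme classes (PDO, Fatal)
separate well, the middle Injury class is hardest — the typical pattern for
ordinal outcomes.  `evaluation_report()` stacks train/test AUCs and their
generalization gaps (ΔAUC) for both models; `permutation_importance()` and
`partial_dependence()` probe which features drive the scores.

## Package layout

| Area | Functions |
| --- | --- |
| Synthetic registry | `fev_prevalence_config()`, `fev_dgp_params()`, `generate_covariates()`, `simulate_severity()`, `simulate_crashes()` |
| Preprocessing | `classify_pavement()`, `fev_model_spec()`, `encode_design()`, `screen_features()`, `split_train_test()`, `descriptive_table()` |
| Ordered logit | `fit_rpol()`, `simulated_loglik()`, `quadrature_loglik()`, `make_draws()`, `ordered_class_probs()`, `predict_class_probs()`, `fit_statistics()` |
| SVM benchmark | `fit_mcsvm()`, `select_C_cv()`, `score_and_predict()`, `objective_value()` |
| Evaluation | `ovr_roc_auc()`, `generalization_gap()`, `evaluation_report()`, `permutation_importance()`, `partial_dependence()` |

Fitted objects support `tidy()`, `glance()` and `autoplot()`; the methods
vignette (`vignettes/injury-severity-modelling.Rmd`) documents the model,
the generator's assumptions and the numerical choices in detail.
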
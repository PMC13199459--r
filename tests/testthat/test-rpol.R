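fixture_design <- function(n = 50L, seed = 7L) {
  tab <- simulate_crashes(n = max(n, 60L), seed = seed)
  encode_design(tab[seq_len(n), ], fev_model_spec())
}

fixture_params <- function(log_sd = log(0.8)) {
  rpol_params(
    fixed_coefs = c(-1.35, 1.1, -3.16, 1.25, -1.87, 1.12, -2.2, 1.13, 0.391),
    het_coefs = c(-0.99, -0.74, 0.913),
    log_sd = log_sd,
    thresholds = c(-1.07, 3.18)
  )
}

closed_form_loglik <- function(params, design, cdf = "logistic") {
  p <- ncol(design$X)
  v <- drop(design$X[, -p, drop = FALSE] %*% params$fixed_coefs) +
    design$X[, p] * random_coef_mean(params$het_coefs, design$Z)
  probs <- ordered_class_probs(v, params$thresholds, cdf)
  sum(log(probs[cbind(seq_len(nrow(probs)), design$y)]))
}

test_that("ordered class probabilities follow the logistic threshold bands", {
  expect_equal(ordered_class_probs(-1.07, c(-1.07, 3.18))[1], 0.5)
  p <- ordered_class_probs(0.07, c(-1.07, 3.18))
  expect_equal(as.numeric(p), c(0.2423, 0.7150, 0.0427), tolerance = 1e-4)
  narrow <- ordered_class_probs(0, c(0.5, 0.5 + 1e-13))
  expect_lt(narrow[2], 1e-12)
  expect_error(ordered_class_probs(0, c(1, 1)), class = "fevcrash_parameter_error")

  # algebraic identities and monotonicity under random parameters
  withr::with_seed(3, {
    for (i in 1:25) {
      tau <- sort(rnorm(2, sd = 3))
      if (diff(tau) == 0) next
      v <- sort(rnorm(9, sd = 4))
      pr <- ordered_class_probs(v, tau)
      expect_equal(rowSums(pr), rep(1, 9), tolerance = 1e-12)
      expect_true(all(pr >= 0 & pr <= 1))
      expect_true(all(diff(pr[, "Fatal"]) >= 0))
      expect_true(all(diff(pr[, "PDO"]) <= 0))
    }
  })
})

test_that("the random coefficient's mean combines base and shifters", {
  a <- c(-0.99, -0.74, 0.913)
  expect_equal(random_coef_mean(a, c(0, 0)), -0.99)
  expect_equal(random_coef_mean(a, c(1, 1)), -0.817)
  expect_equal(random_coef_mean(c(0, 0, 0), c(5, -3)), 0)
  Z <- rbind(c(0, 0), c(1, 1), c(1, 0))
  expect_equal(random_coef_mean(a, Z), c(-0.99, -0.817, -1.73))
  expect_error(random_coef_mean(a, c(1, 2, 3)), class = "fevcrash_schema_error")
})

test_that("draw sets are reproducible low-discrepancy sequences", {
  expect_equal(halton_sequence(5), c(1/2, 1/4, 3/4, 1/8, 5/8))
  expect_equal(halton_sequence(3, base = 3), c(1/3, 2/3, 1/9))
  expect_equal(halton_sequence(2, burn = 3), c(1/8, 5/8))

  d1 <- make_draws(20, 64, seed = 5)
  d2 <- make_draws(20, 64, seed = 5)
  expect_identical(d1$values, d2$values)
  expect_false(identical(d1$values, make_draws(20, 64, seed = 6)$values))

  big <- make_draws(10, 2048, seed = 2)
  expect_true(all(abs(rowMeans(big$values)) < 4 / sqrt(2048)))
  ps <- make_draws(10, 2048, method = "pseudo", seed = 2)
  expect_true(all(abs(rowMeans(ps$values)) < 4 / sqrt(2048)))
  expect_error(make_draws(10, 0), class = "fevcrash_parameter_error")
})

test_that("a degenerate spread collapses the simulated likelihood to closed form", {
  des <- fixture_design(50)
  params <- fixture_params(log_sd = -400)
  draws <- make_draws(50, 50, seed = 3)
  expect_equal(simulated_loglik(params, des, draws),
               closed_form_loglik(params, des), tolerance = 1e-12)

  # single observation, y = 2, v = 0, tau = (-1, 1)
  one <- list(
    X = matrix(c(0, 0), 1, 2, dimnames = list(NULL, c("a", "d"))),
    Z = matrix(numeric(0), 1, 0), y = 2L,
    one_hot = matrix(c(0L, 1L, 0L), 1), x_names = c("a", "d"),
    z_names = character(), random_var = "d"
  )
  class(one) <- "crash_design"
  p1 <- rpol_params(0, 0, -400, c(-1, 1))
  ll <- simulated_loglik(p1, one, make_draws(1, 10, seed = 1))
  expect_equal(as.numeric(ll), log(plogis(1) - plogis(-1)), tolerance = 1e-12)
  # frozen from the closed-form oracle: log(0.4621172) = -0.7719368
  expect_equal(as.numeric(ll), -0.7719368, tolerance = 1e-5)
})

test_that("scrambled Halton simulation agrees with Gauss-Hermite quadrature", {
  # well-conditioned fixture: every class probability is bounded away from
  # zero, so the log-likelihood difference reflects integration error alone
  des <- fixture_design(50)
  params <- rpol_params(
    fixed_coefs = c(0.4, -0.3, 0.5, 0.25, -0.4, 0.3, -0.5, 0.35, 0.2),
    het_coefs = c(-0.5, 0.3, 0.3),
    log_sd = log(0.8), thresholds = c(-1, 1.2)
  )
  draws <- make_draws(50, 2000, seed = 1)
  expect_lt(
    abs(simulated_loglik(params, des, draws) - quadrature_loglik(params, des, 64)),
    1e-3
  )
})

test_that("simulation error shrinks at least at the Monte-Carlo rate in R", {
  des <- fixture_design(50)
  params <- fixture_params(log_sd = log(0.8))
  target <- quadrature_loglik(params, des, 96)
  Rs <- c(64, 256, 1024, 4096)
  errs <- vapply(Rs, function(R) {
    # average |error| over shifts to smooth the randomization
    mean(vapply(1:4, function(s) {
      abs(simulated_loglik(params, des, make_draws(50, R, seed = s)) - target)
    }, numeric(1)))
  }, numeric(1))
  slope <- coef(lm(log(errs) ~ log(Rs)))[2]
  expect_lt(slope, -0.75)
})

test_that("the quadrature oracle is self-consistent and matches brute force", {
  des <- fixture_design(20)
  params <- fixture_params(log_sd = log(0.8))
  expect_equal(quadrature_loglik(params, des, 64),
               quadrature_loglik(params, des, 128), tolerance = 1e-8)
  p0 <- fixture_params(log_sd = -400)
  expect_equal(quadrature_loglik(p0, des, 64), closed_form_loglik(p0, des),
               tolerance = 1e-12)

  # brute-force trapezoid over +/- 8 sd on a 5-row fixture
  des5 <- fixture_design(5)
  sigma <- 0.8
  grid <- seq(-8 * sigma, 8 * sigma, length.out = 1e6)
  w <- stats::dnorm(grid, sd = sigma)
  p <- ncol(des5$X)
  vf <- drop(des5$X[, -p, drop = FALSE] %*% params$fixed_coefs)
  mu <- random_coef_mean(params$het_coefs, des5$Z)
  P <- vapply(seq_len(5), function(i) {
    v <- vf[i] + des5$X[i, p] * (mu[i] + grid)
    probs <- ordered_class_probs(v, params$thresholds)[, des5$y[i]]
    sum((probs[-1] * w[-1] + probs[-1e6] * w[-1e6]) / 2) * diff(grid[1:2])
  }, numeric(1))
  expect_equal(quadrature_loglik(params, des5, 64), sum(log(P)),
               tolerance = 1e-6)

  # internal Gauss-Hermite rule matches the pracma reference
  gh <- fevcrash:::gauss_hermite(32)
  ref <- pracma::gaussHermite(32)
  expect_equal(gh$nodes, ref$x, tolerance = 1e-10)
  expect_equal(gh$weights, ref$w, tolerance = 1e-10)
})

test_that("the analytic gradient matches central differences", {
  des <- fixture_design(30)
  draws <- make_draws(30, 80, seed = 4)
  params <- fixture_params(log_sd = log(0.7))
  ll <- simulated_loglik(params, des, draws, gradient = TRUE)
  g <- attr(ll, "gradient")
  pack <- function(p) c(p$fixed_coefs, p$het_coefs, p$log_sd, p$thresholds)
  unpack <- function(t) rpol_params(t[1:9], t[10:12], t[13], t[14:15])
  t0 <- pack(params)
  gn <- vapply(seq_along(t0), function(i) {
    h <- 1e-6
    tp <- t0; tp[i] <- tp[i] + h
    tm <- t0; tm[i] <- tm[i] - h
    (as.numeric(simulated_loglik(unpack(tp), des, draws)) -
       as.numeric(simulated_loglik(unpack(tm), des, draws))) / (2 * h)
  }, numeric(1))
  expect_equal(g, gn, tolerance = 1e-5)
})

test_that("estimation with a degenerate spread recovers the ordered-logit oracle", {
  dgp0 <- dgp_params(
    fixed_coefs = c(constant = 0, Overturn_Occurred = 1.2,
                    Truck_Involved = -1.5, Motorcycle_Involved = 0.9),
    random_var = "Front_to_Back_Collision",
    het_mean_coefs = c(constant = -0.8),
    random_sd = 0, thresholds = c(-1, 1.5)
  )
  tab <- simulate_severity(
    generate_covariates(fev_prevalence_config(2000L), seed = 5), dgp0, seed = 9
  )
  spec <- model_spec(
    c("Overturn_Occurred", "Truck_Involved", "Motorcycle_Involved"),
    "Front_to_Back_Collision"
  )
  des <- encode_design(tab, spec)
  fit <- fit_rpol(des, R = 200, seed = 3)
  expect_true(fit$converged)

  po <- MASS::polr(
    factor(severity) ~ Overturn_Occurred + Truck_Involved +
      Motorcycle_Involved + Front_to_Back_Collision,
    data = as.data.frame(tab), method = "logistic"
  )
  mine <- c(fit$params$fixed_coefs, fit$params$het_coefs[1])
  expect_equal(unname(mine), unname(coef(po)), tolerance = 1e-3)
  expect_equal(unname(fit$params$thresholds), unname(po$zeta), tolerance = 1e-3)
  expect_lt(exp(fit$theta[["log_sd"]]), 0.05)

  # likelihood-ratio sanity: the mixed model cannot fall below the nested
  # fixed-coefficient fit (up to simulation noise)
  expect_gte(fit$ll_final, as.numeric(logLik(po)) - 0.01)
  expect_gte(fit$ll_final, fit$ll_null - 1e-6)
})

test_that("estimation rejects degenerate outcomes and non-finite starts", {
  tab <- simulate_crashes(100L, seed = 2)
  tab$severity <- 2L
  des <- encode_design(tab, fev_model_spec())
  expect_error(fit_rpol(des), class = "fevcrash_validation_error")
})

test_that("estimation is invariant to row order", {
  tab <- simulate_crashes(400L, seed = 23)
  des <- encode_design(tab, fev_model_spec())
  perm <- withr::with_seed(1, sample.int(400L))
  des_p <- encode_design(tab[perm, ], fev_model_spec())

  params <- fixture_params()
  expect_equal(quadrature_loglik(params, des, 64),
               quadrature_loglik(params, des_p, 64), tolerance = 1e-10)

  fit_a <- fit_rpol(des, R = 100, seed = 2)
  fit_b <- fit_rpol(des_p, R = 100, seed = 2)
  expect_equal(fit_a$ll_final, fit_b$ll_final, tolerance = 0.5)
  expect_equal(fit_a$params$fixed_coefs, fit_b$params$fixed_coefs,
               tolerance = 0.1)
})

test_that("fit statistics reproduce the reported arithmetic", {
  fs <- fit_statistics(-545.12, -799.48, k = 15, n = 615)
  expect_equal(round(fs$rho2, 3), 0.318)
  expect_equal(round(fs$rho2_bar, 3), 0.299)
  expect_equal(fs$AIC, 1120.24)
  zero <- fit_statistics(-100, -100, k = 2, n = 50)
  expect_equal(zero$rho2, 0)
  expect_error(fit_statistics(-10, 0, 1, 10), class = "fevcrash_parameter_error")
})

test_that("predicted probabilities normalize and match the quadrature oracle", {
  des <- fixture_design(20)
  tab <- simulate_crashes(200L, seed = 3)
  dtrain <- encode_design(tab, fev_model_spec())
  fit <- fit_rpol(dtrain, R = 100, seed = 2)

  probs <- predict_class_probs(fit, des, allow_unconverged = TRUE)
  expect_equal(rowSums(probs), rep(1, 20), tolerance = 1e-10)
  expect_true(all(probs >= 0 & probs <= 1))

  # high-R simulation vs quadrature, per class
  draws <- make_draws(20, 4000, seed = 9)
  probs_hi <- predict_class_probs(fit, des, draws = draws,
                                  allow_unconverged = TRUE)
  gh <- pracma::gaussHermite(64)
  sigma <- exp(fit$params$log_sd)
  p <- ncol(des$X)
  vf <- drop(des$X[, -p, drop = FALSE] %*% fit$params$fixed_coefs)
  mu <- random_coef_mean(fit$params$het_coefs, des$Z)
  quad <- matrix(0, 20, 3)
  for (k in seq_along(gh$x)) {
    v <- vf + des$X[, p] * (mu + sigma * sqrt(2) * gh$x[k])
    quad <- quad + (gh$w[k] / sqrt(pi)) *
      ordered_class_probs(v, fit$params$thresholds)
  }
  expect_lt(max(abs(probs_hi - quad)), 2e-3)

  # with a degenerate spread the rows equal the closed-form probabilities
  fit0 <- fit
  fit0$params$log_sd <- -400
  probs0 <- predict_class_probs(fit0, des, allow_unconverged = TRUE)
  v0 <- vf + des$X[, p] * mu
  expect_equal(probs0, ordered_class_probs(v0, fit0$params$thresholds),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("tidy, glance and the anchored layout expose the fit coherently", {
  tab <- simulate_crashes(300L, seed = 31)
  des <- encode_design(tab, fev_model_spec())
  fit <- fit_rpol(des, R = 100, seed = 4)
  td <- tidy(fit)
  expect_equal(nrow(td), 15L)
  expect_equal(sum(td$group == "fixed"), 9L)
  expect_equal(sum(td$group == "het_mean"), 3L)
  gl <- glance(fit)
  expect_equal(gl$k, 15L)
  expect_equal(gl$AIC, -2 * gl$logLik + 2 * gl$k)
  expect_equal(gl$rho2, 1 - gl$logLik / gl$null.logLik)

  anchored <- anchor_constant(fit, 0.07)
  expect_equal(anchored$tau_1 - 0.07, fit$params$thresholds[1])

  path <- withr::local_tempfile(fileext = ".json")
  write_rpol_json(fit, path)
  rt <- read_rpol_json(path)
  expect_equal(rt$ll_final, fit$ll_final)
  expect_equal(unlist(rt$fixed_coefs), fit$params$fixed_coefs)
})
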
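# Random-parameters ordered logit with heterogeneity in means, estimated by
# simulated maximum likelihood.  The latent severity is
#   Y* = x' beta + beta' d + noise,   beta' = a0 + z' a + sigma eps,
# with eps ~ N(0, 1) draws (scrambled Halton by default) and standard
# logistic latent noise; severity is the cut of Y* at thresholds (tau1,
# tau2).  A Gauss-Hermite quadrature evaluation of the same mixing integral
# serves as a deterministic cross-check of the simulated likelihood.

#' Parameter set of the random-parameters ordered logit
#'
#' @param fixed_coefs Named numeric vector aligned to the non-random columns
#'   of the design's `X` (specification order, interactions included).
#' @param het_coefs Numeric vector `(a0, a1, ...)`: the random coefficient's
#'   base mean followed by one coefficient per heterogeneity shifter.
#' @param log_sd Log of the random coefficient's spread (estimated on the
#'   log scale for positivity).
#' @param thresholds Strictly increasing numeric pair.
#' @return An object of class `rpol_params`.
#' @export
rpol_params <- function(fixed_coefs, het_coefs, log_sd, thresholds) {
  if (!all(is.finite(c(fixed_coefs, het_coefs, log_sd, thresholds)))) {
    stop_parameter("All parameters must be finite (use a very negative `log_sd` for a degenerate spread).")
  }
  if (length(thresholds) != 2L || diff(thresholds) <= 0) {
    stop_parameter("`thresholds` must be a strictly increasing pair.")
  }
  structure(
    list(
      fixed_coefs = fixed_coefs,
      het_coefs = het_coefs,
      log_sd = log_sd,
      thresholds = thresholds
    ),
    class = "rpol_params"
  )
}

#' Ordered-model class probabilities at a latent mean
#'
#' For latent mean \eqn{v} and thresholds \eqn{\tau_1 < \tau_2}, the three
#' class probabilities are \eqn{F(\tau_1 - v)},
#' \eqn{F(\tau_2 - v) - F(\tau_1 - v)} and \eqn{1 - F(\tau_2 - v)}, with
#' \eqn{F} the standard logistic CDF (a Gumbel CDF is available for
#' sensitivity analyses).
#'
#' @param v Numeric vector of latent means.
#' @param thresholds Strictly increasing pair \eqn{(\tau_1, \tau_2)}.
#' @param cdf `"logistic"` (default) or `"gumbel"`.
#' @return An `length(v)`-by-3 matrix with columns `PDO`, `Injury`, `Fatal`;
#'   rows sum to 1.
#' @examples
#' ordered_class_probs(0.07, c(-1.07, 3.18))
#' @export
ordered_class_probs <- function(v, thresholds, cdf = "logistic") {
  if (length(thresholds) != 2L || thresholds[1L] >= thresholds[2L]) {
    stop_parameter("`thresholds` must satisfy tau1 < tau2.")
  }
  F1 <- latent_cdf(thresholds[1L] - v, cdf)
  F2 <- latent_cdf(thresholds[2L] - v, cdf)
  out <- cbind(F1, F2 - F1, 1 - F2)
  colnames(out) <- severity_labels()
  out
}

#' Deterministic part of the random coefficient's mean
#'
#' Evaluates \eqn{a_0 + a^\top z}: the base mean plus the
#' heterogeneity-in-means shift for shifter values `z`.
#'
#' @param het_coefs Numeric vector `(a0, a1, ..., aq)`.
#' @param z Numeric vector of length `q`, or an n-by-q matrix of shifter
#'   rows.
#' @return A single mean, or a vector of means for a matrix `z`.
#' @examples
#' random_coef_mean(c(-0.99, -0.74, 0.913), c(0, 0))
#' @export
random_coef_mean <- function(het_coefs, z) {
  q <- length(het_coefs) - 1L
  if (is.matrix(z)) {
    if (ncol(z) != q) {
      stop_schema(sprintf("`z` has %d columns but %d shifter coefficients.",
                          ncol(z), q))
    }
    return(drop(het_coefs[1L] + z %*% het_coefs[-1L]))
  }
  if (length(z) != q) {
    stop_schema(sprintf("`z` has length %d but %d shifter coefficients.",
                        length(z), q))
  }
  het_coefs[1L] + sum(het_coefs[-1L] * z)
}

#' Standard-normal draws for the simulated mixing integral
#'
#' Generates an n-by-R matrix of standard-normal variates, either from a
#' scrambled base-2 Halton sequence or from the seeded pseudo-random
#' generator.  In the Halton case every observation shares the same
#' radical-inverse point set (`burn` initial points discarded) and receives
#' its own nested uniform (Owen) scramble, implemented with the hash-based
#' bit permutation of Laine and Karras; Owen scrambling preserves the
#' net structure of the point set, so the per-observation integration error
#' decays at the scrambled-net rate rather than the plain Monte-Carlo rate.
#' The probit transform then maps to standard normals.  Draws are reused
#' across optimizer iterations (common random numbers) to keep the
#' simulated likelihood smooth.
#'
#' @param n Observations.
#' @param R Draws per observation.
#' @param method `"halton"` (default) or `"pseudo"`.
#' @param seed Integer seed (drives the scramble shift or the RNG).
#' @param burn Initial Halton points to discard (default 10).
#' @param scramble Apply the random shift (default `TRUE`).
#' @return An object of class `draw_set` with the matrix in `$values` and
#'   the generating metadata.
#' @export
make_draws <- function(n, R, method = c("halton", "pseudo"), seed = 1L,
                       burn = 10L, scramble = TRUE) {
  method <- match.arg(method)
  n <- as.integer(n)
  R <- as.integer(R)
  if (n < 1L || R < 1L) stop_parameter("`n` and `R` must be at least 1.")
  if (method == "halton") {
    if (scramble) {
      keys <- withr::with_seed(as.integer(seed),
                               sample.int(.Machine$integer.max - 1L, n))
      u <- owen_halton_cpp(n, R, as.integer(burn), keys)
    } else {
      base_u <- halton_sequence(R, base = 2L, burn = burn)
      u <- matrix(base_u, nrow = n, ncol = R, byrow = TRUE)
    }
    u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
    values <- matrix(qnorm(u), nrow = n, ncol = R)
  } else {
    values <- withr::with_seed(as.integer(seed),
                               matrix(rnorm(n * R), nrow = n, ncol = R))
  }
  structure(
    list(values = values, method = method, n = n, R = R,
         seed = as.integer(seed), burn = as.integer(burn),
         scramble = scramble),
    class = "draw_set"
  )
}

check_alignment <- function(params, design, draws = NULL) {
  pf <- ncol(design$X) - 1L
  if (length(params$fixed_coefs) != pf) {
    stop_schema(sprintf(
      "%d fixed coefficients for %d non-random design columns.",
      length(params$fixed_coefs), pf
    ))
  }
  if (length(params$het_coefs) != ncol(design$Z) + 1L) {
    stop_schema(sprintf(
      "%d heterogeneity coefficients for %d shifters (need q + 1).",
      length(params$het_coefs), ncol(design$Z)
    ))
  }
  if (!is.null(draws) && draws$n < nrow(design$X)) {
    stop_schema(sprintf(
      "Draw set has %d rows but the design has %d.", draws$n, nrow(design$X)
    ))
  }
  invisible(TRUE)
}

split_design <- function(design) {
  p <- ncol(design$X)
  list(
    Xf = design$X[, -p, drop = FALSE],
    d = design$X[, p],
    Z = design$Z
  )
}

#' Simulated log-likelihood
#'
#' Approximates the mixing integral over the random coefficient by the
#' average over the supplied draws of the ordered-model likelihood, then
#' sums the logs of the per-observation simulated probabilities (floored at
#' 1e-300).
#'
#' @param params An [rpol_params()] object.
#' @param design A [encode_design()] result.
#' @param draws A [make_draws()] object with at least `nrow(design$X)` rows.
#' @param cdf `"logistic"` or `"gumbel"`.
#' @param gradient Attach the analytic gradient (parameter order: fixed
#'   coefficients, `a0`, shifters, `log_sd`, `tau1`, `tau2`) as the
#'   `"gradient"` attribute.
#' @return The log-likelihood (a finite scalar).
#' @export
simulated_loglik <- function(params, design, draws, cdf = "logistic",
                             gradient = FALSE) {
  check_alignment(params, design, draws)
  parts <- split_design(design)
  eps <- draws$values[seq_len(nrow(design$X)), , drop = FALSE]
  res <- rpol_sll_cpp(
    parts$Xf, parts$d, parts$Z, design$y,
    as.numeric(params$fixed_coefs), as.numeric(params$het_coefs),
    params$log_sd, params$thresholds[1L], params$thresholds[2L],
    eps, identical(cdf, "gumbel"), gradient, FALSE
  )
  ll <- res$ll
  if (gradient) attr(ll, "gradient") <- res$grad
  ll
}

#' Gauss-Hermite quadrature log-likelihood
#'
#' Evaluates the same mixing integral as [simulated_loglik()] by
#' Gauss-Hermite quadrature over the normal random coefficient.  Being
#' deterministic and rapidly convergent in the node count, it serves as the
#' independent oracle for the simulated likelihood.
#'
#' @inheritParams simulated_loglik
#' @param nodes Number of quadrature nodes (default 64).
#' @return The log-likelihood.
#' @export
quadrature_loglik <- function(params, design, nodes = 64L, cdf = "logistic") {
  check_alignment(params, design)
  parts <- split_design(design)
  gh <- gauss_hermite(nodes)
  sigma <- exp(params$log_sd)
  vf <- drop(parts$Xf %*% params$fixed_coefs)
  mu <- params$het_coefs[1L]
  if (ncol(parts$Z) > 0L) mu <- mu + drop(parts$Z %*% params$het_coefs[-1L])
  tau <- params$thresholds
  w <- gh$weights / sqrt(pi)
  P <- numeric(nrow(design$X))
  for (k in seq_along(gh$nodes)) {
    v <- vf + parts$d * (mu + sigma * sqrt(2) * gh$nodes[k])
    F1 <- latent_cdf(tau[1L] - v, cdf)
    F2 <- latent_cdf(tau[2L] - v, cdf)
    pk <- cbind(F1, F2 - F1, 1 - F2)[cbind(seq_along(v), design$y)]
    P <- P + w[k] * pk
  }
  sum(log(pmax(P, 1e-300)))
}

# Free-parameter vector <-> rpol_params.  Thresholds are parameterized as
# (tau1, tau1 + exp(delta)) to enforce the ordering during optimization.
theta_to_params <- function(theta, pf, q) {
  beta <- theta[seq_len(pf)]
  a <- theta[pf + seq_len(q + 1L)]
  log_sd <- theta[pf + q + 2L]
  tau1 <- theta[pf + q + 3L]
  delta <- theta[pf + q + 4L]
  rpol_params(beta, a, log_sd, c(tau1, tau1 + exp(delta)))
}

# Chain rule from the natural gradient (d ll / d tau1, d ll / d tau2) to the
# free parameterization (tau1_free, delta).
grad_to_free <- function(grad, pf, q, delta) {
  g <- grad
  i1 <- pf + q + 3L
  i2 <- pf + q + 4L
  g[i1] <- grad[i1] + grad[i2]
  g[i2] <- grad[i2] * exp(delta)
  g
}

null_loglik <- function(y) {
  counts <- table(factor(y, levels = 1:3))
  counts <- counts[counts > 0]
  sum(counts * log(counts / length(y)))
}

#' Fit the random-parameters ordered logit
#'
#' Maximizes the simulated log-likelihood over the free parameter vector
#' (fixed coefficients, heterogeneity-in-means coefficients, log spread,
#' thresholds as \eqn{(\tau_1, \tau_1 + e^\delta)}) with BFGS and analytic
#' gradients; draws are held fixed across iterations.  Standard errors come
#' from the inverse numerical Hessian, with a BHHH (outer-product-of-scores)
#' fallback when the Hessian is not positive definite.  No free constant is
#' estimated by default: with both thresholds free, a constant is not
#' separately identified (see [anchor_constant()] for a constant-anchored
#' report layout).
#'
#' @param design A [encode_design()] result with at least two outcome
#'   classes.
#' @param R Draws per observation (default 500).
#' @param draw_method `"halton"` (default) or `"pseudo"`.
#' @param seed Seed for the draw set.
#' @param burn Halton burn-in (default 10).
#' @param cdf `"logistic"` or `"gumbel"`.
#' @param start Optional start vector (free parameterization); defaults to
#'   zero coefficients, `log_sd = log(0.5)` and thresholds from the
#'   empirical class shares.
#' @param gtol Gradient infinity-norm tolerance for the convergence flag
#'   (default 1e-5).
#' @param max_iter BFGS iteration cap per restart (default 500).
#' @param restarts Additional polishing runs if the gradient tolerance is
#'   not met (default 2).
#' @return An object of class `rpol_fit`; see [tidy.rpol_fit()] and
#'   [glance.rpol_fit()].
#' @export
fit_rpol <- function(design, R = 500L, draw_method = "halton", seed = 1L,
                     burn = 10L, cdf = "logistic", start = NULL,
                     gtol = 1e-5, max_iter = 500L, restarts = 2L) {
  if (!inherits(design, "crash_design")) {
    stop_schema("`design` must be a `crash_design` object.")
  }
  if (length(unique(design$y)) < 2L) {
    stop_validation("Outcome has a single class; the model is not estimable.")
  }
  n <- nrow(design$X)
  pf <- ncol(design$X) - 1L
  q <- ncol(design$Z)
  K <- pf + q + 4L

  draws <- make_draws(n, R, method = draw_method, seed = seed, burn = burn)

  if (is.null(start)) {
    shares <- as.numeric(table(factor(design$y, levels = 1:3))) / n
    cum <- pmin(pmax(cumsum(shares)[1:2], 1e-4), 1 - 1e-4)
    tau_emp <- qlogis(cum)
    if (diff(tau_emp) <= 0) tau_emp <- c(tau_emp[1L], tau_emp[1L] + 0.5)
    start <- c(rep(0, pf), rep(0, q + 1L), log(0.5),
               tau_emp[1L], log(diff(tau_emp)))
  }
  if (length(start) != K) {
    stop_parameter(sprintf("`start` must have length %d.", K))
  }

  parts <- split_design(design)
  # Robust evaluation for the optimizer: clamp the log-scale parameters so
  # that wild line-search steps stay finite, and penalize non-finite
  # proposals instead of erroring.
  eval_ll <- function(theta, gradient = FALSE, scores = FALSE) {
    beta <- theta[seq_len(pf)]
    a <- theta[pf + seq_len(q + 1L)]
    log_sd <- min(max(theta[pf + q + 2L], -30), 30)
    tau1 <- theta[pf + q + 3L]
    delta <- min(max(theta[pf + q + 4L], -30), 30)
    if (!all(is.finite(c(beta, a, tau1)))) return(NULL)
    rpol_sll_cpp(
      parts$Xf, parts$d, parts$Z, design$y,
      as.numeric(beta), as.numeric(a), log_sd, tau1, tau1 + exp(delta),
      draws$values, identical(cdf, "gumbel"), gradient, scores
    )
  }
  negll <- function(theta) {
    res <- eval_ll(theta)
    if (is.null(res) || !is.finite(res$ll)) return(1e15)
    -res$ll
  }
  neggrad <- function(theta) {
    res <- eval_ll(theta, gradient = TRUE)
    if (is.null(res) || !is.finite(res$ll)) return(rep(0, K))
    -grad_to_free(res$grad, pf, q, min(max(theta[K], -30), 30))
  }

  ll_start <- eval_ll(start)$ll
  if (!is.finite(ll_start)) {
    stop_validation(paste(
      "Log-likelihood is not finite at the start values;",
      "check the design for degenerate columns or supply `start`."
    ))
  }

  theta <- start
  opt <- NULL
  grad_norm <- Inf
  for (attempt in seq_len(restarts + 1L)) {
    opt <- optim(theta, negll, neggrad, method = "BFGS",
                 control = list(maxit = max_iter, reltol = 1e-12))
    theta <- opt$par
    grad_norm <- max(abs(neggrad(theta)))
    if (grad_norm <= gtol) break
  }

  # BFGS can stall short of the gradient tolerance when the spread
  # parameter sits in a nearly flat region; polish with damped Newton steps
  # against the numerical Hessian (which is needed for the standard errors
  # regardless).
  H <- tryCatch(optimHess(theta, negll, neggrad), error = function(e) NULL)
  if (!is.null(H)) {
    H_age <- 0L
    for (it in seq_len(60L)) {
      if (grad_norm <= gtol) break
      if (H_age >= 8L) {
        H <- tryCatch(optimHess(theta, negll, neggrad), error = function(e) H)
        H_age <- 0L
      }
      g <- -neggrad(theta)
      step <- tryCatch(solve(H, g), error = function(e) NULL)
      if (is.null(step)) break
      ll_cur <- -negll(theta)
      accepted <- FALSE
      for (bt in seq_len(8L)) {
        cand <- theta + step
        if (-negll(cand) >= ll_cur - 1e-9) {
          theta <- cand
          accepted <- TRUE
          break
        }
        step <- step / 2
      }
      if (!accepted) break
      grad_norm <- max(abs(neggrad(theta)))
      H_age <- H_age + 1L
    }
    H <- tryCatch(optimHess(theta, negll, neggrad), error = function(e) H)
  }
  converged <- grad_norm <= gtol
  ll_final <- -negll(theta)

  # covariance: inverse numerical Hessian, BHHH on failure
  vcov <- NULL
  vcov_method <- "hessian"
  if (!is.null(H)) {
    ev <- tryCatch(eigen(H, symmetric = TRUE, only.values = TRUE)$values,
                   error = function(e) -1)
    if (all(ev > 0)) {
      vcov <- tryCatch(solve(H), error = function(e) NULL)
    }
  }
  if (is.null(vcov)) {
    vcov_method <- "bhhh"
    res <- eval_ll(theta, scores = TRUE)
    S <- res$scores
    Sfree <- S
    i1 <- pf + q + 3L
    i2 <- pf + q + 4L
    Sfree[, i1] <- S[, i1] + S[, i2]
    Sfree[, i2] <- S[, i2] * exp(theta[K])
    vcov <- tryCatch(solve(crossprod(Sfree)), error = function(e) {
      matrix(NA_real_, K, K)
    })
  }
  se <- sqrt(pmax(diag(vcov), 0))
  se[diag(vcov) < 0 | !is.finite(diag(vcov))] <- NA_real_

  params <- theta_to_params(theta, pf, q)
  names(params$fixed_coefs) <- design$x_names[seq_len(pf)]
  names(params$het_coefs) <- c(
    paste0(design$random_var, " (base mean)"),
    if (q > 0L) paste0(design$random_var, ":", design$z_names)
  )

  term_names <- c(
    names(params$fixed_coefs), names(params$het_coefs),
    "log_sd", "tau_1", "delta"
  )
  groups <- c(
    rep("fixed", pf), rep("het_mean", q + 1L),
    "spread", "threshold", "threshold"
  )

  ll_null <- null_loglik(design$y)
  stats <- fit_statistics(ll_final, ll_null, K, n)

  structure(
    list(
      params = params,
      theta = setNames(theta, term_names),
      std_errors = setNames(se, term_names),
      vcov = vcov,
      vcov_method = vcov_method,
      term_groups = setNames(groups, term_names),
      ll_final = ll_final,
      ll_null = ll_null,
      ll_start = ll_start,
      n_obs = n,
      k_params = K,
      converged = converged,
      grad_norm = grad_norm,
      fit_stats = stats,
      cdf = cdf,
      draws_meta = draws[c("method", "R", "seed", "burn", "scramble")],
      x_names = design$x_names,
      z_names = design$z_names,
      random_var = design$random_var
    ),
    class = "rpol_fit"
  )
}

#' Likelihood-based fit statistics
#'
#' \eqn{AIC = -2\,LL + 2k}; \eqn{BIC = -2\,LL + k \ln n};
#' McFadden \eqn{\rho^2 = 1 - LL/LL_0} and its parameter-penalized version
#' \eqn{\bar\rho^2 = 1 - (LL - k)/LL_0}.
#'
#' @param ll_final Maximized log-likelihood.
#' @param ll_baseline Baseline log-likelihood (must be negative).
#' @param k Number of estimated parameters.
#' @param n Number of observations.
#' @return A one-row tibble with `AIC`, `BIC`, `rho2`, `rho2_bar`.
#' @examples
#' fit_statistics(-545.12, -799.48, k = 15, n = 615)
#' @export
fit_statistics <- function(ll_final, ll_baseline, k, n) {
  check_scalar_number(ll_final, "ll_final")
  check_scalar_number(ll_baseline, "ll_baseline", upper = -1e-12)
  check_scalar_number(k, "k", lower = 1)
  check_scalar_number(n, "n", lower = 1)
  tibble(
    AIC = -2 * ll_final + 2 * k,
    BIC = -2 * ll_final + k * log(n),
    rho2 = 1 - ll_final / ll_baseline,
    rho2_bar = 1 - (ll_final - k) / ll_baseline
  )
}

#' Simulation-averaged class probabilities from a fitted model
#'
#' @param fit An [fit_rpol()] result.
#' @param design A [encode_design()] result with matching columns.
#' @param draws Optional [make_draws()] set; regenerated from the fit's
#'   draw metadata when omitted.
#' @param allow_unconverged Predict from a non-converged fit.
#' @return An n-by-3 matrix of class probabilities (rows sum to 1).
#' @export
predict_class_probs <- function(fit, design, draws = NULL,
                                allow_unconverged = FALSE) {
  if (!inherits(fit, "rpol_fit")) stop_schema("`fit` must be an `rpol_fit`.")
  if (!fit$converged && !allow_unconverged) {
    stop_validation("Fit did not converge; pass `allow_unconverged = TRUE` to predict anyway.")
  }
  if (!identical(colnames(design$X), fit$x_names)) {
    stop_schema("Design columns do not match the fitted model.")
  }
  if (is.null(draws)) {
    m <- fit$draws_meta
    draws <- make_draws(nrow(design$X), m$R, method = m$method,
                        seed = m$seed, burn = m$burn, scramble = m$scramble)
  }
  check_alignment(fit$params, design, draws)
  parts <- split_design(design)
  probs <- rpol_probs_cpp(
    parts$Xf, parts$d, parts$Z,
    as.numeric(fit$params$fixed_coefs), as.numeric(fit$params$het_coefs),
    fit$params$log_sd, fit$params$thresholds[1L], fit$params$thresholds[2L],
    draws$values[seq_len(nrow(design$X)), , drop = FALSE],
    identical(fit$cdf, "gumbel")
  )
  colnames(probs) <- severity_labels()
  probs
}

#' Constant-anchored threshold layout
#'
#' With both thresholds free, the latent constant is not separately
#' identified: adding \eqn{c} to the constant and to both thresholds leaves
#' every probability unchanged.  For comparability with reports that print a
#' constant alongside two thresholds, this helper re-expresses a fit as the
#' equivalent `(constant, tau_1, tau_2)` triple anchored at a chosen
#' constant.
#'
#' @param fit An [fit_rpol()] result.
#' @param constant The anchor value.
#' @return A one-row tibble with `constant`, `tau_1`, `tau_2`.
#' @export
anchor_constant <- function(fit, constant = 0) {
  tibble(
    constant = constant,
    tau_1 = fit$params$thresholds[1L] + constant,
    tau_2 = fit$params$thresholds[2L] + constant
  )
}

#' @export
print.rpol_fit <- function(x, ...) {
  cat("Random-parameters ordered logit (heterogeneity in means)\n")
  cat(sprintf("  observations: %d   parameters: %d   converged: %s\n",
              x$n_obs, x$k_params, x$converged))
  cat(sprintf("  log-likelihood: %.3f (null %.3f, start %.3f)\n",
              x$ll_final, x$ll_null, x$ll_start))
  cat(sprintf("  AIC %.2f  BIC %.2f  rho2 %.3f  rho2_bar %.3f\n",
              x$fit_stats$AIC, x$fit_stats$BIC,
              x$fit_stats$rho2, x$fit_stats$rho2_bar))
  invisible(x)
}

#' Tidy a fitted random-parameters ordered logit
#'
#' @param x An `rpol_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `group`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.  The spread row reports `log_sd`; thresholds
#'   appear as `tau_1` and `delta` (with `tau_2 = tau_1 + exp(delta)`
#'   available via `x$params$thresholds`).
#' @export
tidy.rpol_fit <- function(x, ...) {
  est <- x$theta
  se <- x$std_errors
  z <- est / se
  tibble(
    term = names(est),
    group = unname(x$term_groups),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(z),
    p.value = unname(2 * pnorm(-abs(z)))
  )
}

#' Glance at a fitted random-parameters ordered logit
#'
#' @param x An `rpol_fit`.
#' @param ... Unused.
#' @return A one-row tibble of fit statistics.
#' @export
glance.rpol_fit <- function(x, ...) {
  tibble(
    logLik = x$ll_final,
    null.logLik = x$ll_null,
    start.logLik = x$ll_start,
    AIC = x$fit_stats$AIC,
    BIC = x$fit_stats$BIC,
    rho2 = x$fit_stats$rho2,
    rho2_bar = x$fit_stats$rho2_bar,
    nobs = x$n_obs,
    k = x$k_params,
    converged = x$converged
  )
}

#' Coefficient plot for a fitted model
#'
#' @param object An `rpol_fit`.
#' @param ... Unused.
#' @return A ggplot of estimates with 95% intervals, faceted by parameter
#'   group.
#' @export
autoplot.rpol_fit <- function(object, ...) {
  td <- tidy(object)
  td$term <- factor(td$term, levels = rev(td$term))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$std.error,
                   xmax = .data$estimate + 1.96 * .data$std.error),
      height = 0.2
    ) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$group),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "Estimate (95% interval)", y = NULL)
}

#' Serialize a fitted model to JSON (and back)
#'
#' Stores estimates, standard errors, thresholds, draw metadata and fit
#' statistics; enough to reconstruct predictions, not the estimation state.
#'
#' @param fit An `rpol_fit`.
#' @param path Output path.
#' @return `write_rpol_json()` returns `path` invisibly;
#'   `read_rpol_json()` returns the parsed list.
#' @export
write_rpol_json <- function(fit, path) {
  out <- list(
    fixed_coefs = as.list(fit$params$fixed_coefs),
    het_coefs = as.list(fit$params$het_coefs),
    log_sd = fit$params$log_sd,
    thresholds = fit$params$thresholds,
    std_errors = as.list(fit$std_errors),
    ll_final = fit$ll_final,
    ll_null = fit$ll_null,
    ll_start = fit$ll_start,
    n_obs = fit$n_obs,
    k_params = fit$k_params,
    converged = fit$converged,
    fit_stats = as.list(fit$fit_stats),
    draws = fit$draws_meta,
    cdf = fit$cdf,
    x_names = fit$x_names,
    z_names = fit$z_names,
    random_var = fit$random_var
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rpol_json
#' @export
read_rpol_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
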
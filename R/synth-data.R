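# Synthetic crash-record generator.  The confidential registry behind the
# analysis cannot be shipped, so this module draws crash tables with the same
# marginal structure: one-hot exclusive groups (collision type, cause, hour
# block, ...) with the registry's category frequencies, independent binary
# flags, and an ordinal severity simulated from the latent-variable model the
# estimator assumes.

#' Prevalence configuration for the covariate generator
#'
#' Describes the marginal distribution of a crash table: mutually exclusive
#' category groups (sampled one-hot) and independent Bernoulli flags.
#'
#' @param exclusive_groups A list of groups, each a list with elements
#'   `name` (string), `categories` (character vector of column names) and
#'   `probs` (numeric vector summing to 1).
#' @param independent_flags Named numeric vector of Bernoulli probabilities
#'   in `[0, 1]`, one per flag column.
#' @param n_records Positive integer number of rows to generate.
#' @return An object of class `prevalence_config`.
#' @seealso [fev_prevalence_config()] for the packaged default,
#'   [generate_covariates()].
#' @export
prevalence_config <- function(exclusive_groups = list(),
                              independent_flags = numeric(),
                              n_records = 1L) {
  n_records <- as.integer(n_records)
  if (is.na(n_records) || n_records < 1L) {
    stop_config("`n_records` must be a positive integer.")
  }
  for (g in exclusive_groups) {
    if (!all(c("name", "categories", "probs") %in% names(g))) {
      stop_config("Each exclusive group needs `name`, `categories`, `probs`.")
    }
    if (length(g$categories) != length(g$probs)) {
      stop_config(sprintf(
        "Group `%s`: %d categories but %d probabilities.",
        g$name, length(g$categories), length(g$probs)
      ))
    }
    if (any(g$probs < 0 | g$probs > 1)) {
      stop_config(sprintf(
        "Group `%s` has probabilities outside [0, 1].", g$name
      ))
    }
    if (abs(sum(g$probs) - 1) > 1e-12) {
      stop_config(sprintf(
        "Group `%s` probabilities sum to %.15f, not 1.", g$name, sum(g$probs)
      ))
    }
  }
  if (length(independent_flags) > 0L) {
    if (is.null(names(independent_flags)) || any(names(independent_flags) == "")) {
      stop_config("`independent_flags` must be a fully named vector.")
    }
    bad <- independent_flags < 0 | independent_flags > 1
    if (any(bad)) {
      stop_config(sprintf(
        "Flag probability outside [0, 1] for: %s.",
        paste0("`", names(independent_flags)[bad], "`", collapse = ", ")
      ))
    }
  }
  structure(
    list(
      exclusive_groups = exclusive_groups,
      independent_flags = independent_flags,
      n_records = n_records
    ),
    class = "prevalence_config"
  )
}

#' Default prevalence configuration of the national FEV crash registry
#'
#' Category frequencies are stored as registry counts out of 768 crashes
#' (2019-2024), so each exclusive group's probabilities sum to exactly 1:
#' hour-of-day block, weather, accident type, collision type, accident cause,
#' second involved vehicle (with an explicit no-second-vehicle category for
#' single-vehicle crashes), lighting and pavement condition.  Road-geometry
#' and fault flags (`FEV_at_Fault`, `Straight_Road`, `Single_Lane_Road`) are
#' not tabulated in the registry summaries and default to Bernoulli(0.5).
#'
#' @param n_records Number of rows to generate (default 768, the registry
#'   size).
#' @return A [prevalence_config()] object.
#' @export
fev_prevalence_config <- function(n_records = 768L) {
  grp <- function(name, categories, counts) {
    list(name = name, categories = categories, probs = counts / sum(counts))
  }
  prevalence_config(
    exclusive_groups = list(
      grp("hour",
          c("Accident_0000_to_0600", "Accident_0600_to_1200",
            "Accident_1200_to_1800", "Accident_1800_to_2400"),
          c(52, 210, 249, 257)),
      grp("weather",
          c("Weather_Sunny", "Weather_Rainy", "Weather_Snowy",
            "Weather_Cloudy"),
          c(756, 2, 2, 8)),
      grp("accident_type",
          c("Overturn_Occurred", "One_Vehicle_Accident",
            "Collision_with_Fixed_Object", "Multiple_Vehicle_Accident",
            "Pedestrian_Accident", "Other_Accident_Type"),
          c(108, 483, 12, 89, 23, 53)),
      grp("collision_type",
          c("Front_to_Back_Collision", "Sliding_Out_of_Road",
            "Front_to_Front_Collision", "Front_to_Side_Collision",
            "Upside_Down_Collision", "Side_to_Side_Collision",
            "Other_Collision_Type"),
          c(260, 56, 174, 177, 65, 22, 14)),
      grp("accident_cause",
          c("Inattention_Cause", "Loss_of_Control_Cause",
            "Speeding_Cause", "Left_Deviation_Cause",
            "Priority_Violation_Cause", "Unsafe_Distance_cause",
            "Lane_Change_Cause", "Alertness_Cause",
            "Vehicle_Defect_Cause", "Reversing_Cause",
            "Wrong_Way_Cause", "Overtaking_Cause",
            "Prohibited_Turn_Cause", "Other_Cause"),
          c(347, 68, 31, 59, 91, 28, 18, 3, 23, 18, 10, 5, 5, 62)),
      grp("second_vehicle",
          c("Truck_Involved", "Bus_Involved", "Motorcycle_Involved",
            "No_Second_Vehicle"),
          c(300, 11, 78, 379)),
      grp("lighting",
          c("Daylight", "Dark", "Dusk_Dawn"),
          c(429, 145, 194)),
      grp("pavement",
          c("Pavement_Acceptable", "Pavement_Low_Failure",
            "Pavement_Moderate_Failure", "Pavement_Severe_Failure"),
          c(489, 245, 28, 6))
    ),
    independent_flags = c(
      Weekend = 221 / 768,
      Holiday = 163 / 768,
      FEV_at_Fault = 0.5,
      Straight_Road = 0.5,
      Single_Lane_Road = 0.5
    ),
    n_records = n_records
  )
}

#' Data-generating-process parameters for the latent severity model
#'
#' The latent severity of crash \eqn{i} is
#' \deqn{Y_i^* = \sum_k \beta_k x_{ik} + \beta'_i d_i + \vartheta_i,}
#' where \eqn{d_i} is the single random-coefficient carrier,
#' \eqn{\beta'_i = a_0 + a^\top z_i + \epsilon_i} with
#' \eqn{\epsilon_i \sim N(0, \sigma^2)} (heterogeneity in the mean), and
#' \eqn{\vartheta_i} is standard logistic noise.  Severity is the threshold
#' cut of \eqn{Y_i^*} at strictly increasing \eqn{(\tau_1, \tau_2)}:
#' 1 = PDO, 2 = Injury, 3 = Fatal.
#'
#' @param fixed_coefs Named numeric vector of fixed coefficients; the name
#'   `"constant"` denotes the intercept, all other names must match covariate
#'   columns.
#' @param random_var Name of the column carrying the random coefficient.
#' @param het_mean_coefs Named numeric vector for the random coefficient's
#'   mean: the element named `"constant"` is the base mean \eqn{a_0}, the
#'   remaining names are shifter columns.
#' @param random_sd Non-negative spread \eqn{\sigma} of the random
#'   coefficient.
#' @param thresholds Strictly increasing numeric pair \eqn{(\tau_1, \tau_2)}.
#' @param noise_law Law of the latent noise; only `"logistic"` is currently
#'   supported.
#' @return An object of class `dgp_params`.
#' @seealso [fev_dgp_params()] for the packaged defaults,
#'   [simulate_severity()].
#' @export
dgp_params <- function(fixed_coefs,
                       random_var,
                       het_mean_coefs = c(constant = 0),
                       random_sd = 1,
                       thresholds = c(-1.07, 3.18),
                       noise_law = "logistic") {
  if (is.null(names(fixed_coefs)) || any(names(fixed_coefs) == "")) {
    stop_config("`fixed_coefs` must be a fully named vector.")
  }
  if (!is.character(random_var) || length(random_var) != 1L) {
    stop_config("`random_var` must be a single column name.")
  }
  if (is.null(names(het_mean_coefs)) ||
      names(het_mean_coefs)[1L] != "constant") {
    stop_config("`het_mean_coefs` must be named and start with `constant`.")
  }
  check_scalar_number(random_sd, "random_sd", lower = 0)
  if (length(thresholds) != 2L || !all(is.finite(thresholds)) ||
      diff(thresholds) <= 0) {
    stop_parameter("`thresholds` must be a strictly increasing finite pair.")
  }
  noise_law <- match.arg(noise_law, "logistic")
  structure(
    list(
      fixed_coefs = fixed_coefs,
      random_var = random_var,
      het_mean_coefs = het_mean_coefs,
      random_sd = random_sd,
      thresholds = thresholds,
      noise_law = noise_law
    ),
    class = "dgp_params"
  )
}

#' Default data-generating parameters (registry model estimates)
#'
#' Coefficients of the fitted injury-severity function: nine fixed crash
#' attributes plus a constant, a random coefficient on
#' `Front_to_Back_Collision` whose mean shifts with `FEV_at_Fault` and
#' `Straight_Road`, and thresholds \eqn{(-1.07, 3.18)}.  The registry model
#' does not report the random coefficient's spread; the generator defaults to
#' `random_sd = 1`.
#'
#' @param random_sd Spread of the random coefficient (default 1).
#' @return A [dgp_params()] object.
#' @export
fev_dgp_params <- function(random_sd = 1) {
  dgp_params(
    fixed_coefs = c(
      constant = 0.07,
      Unsafe_Distance_cause = -1.35,
      Vehicle_Defect_Cause = 1.1,
      Reversing_Cause = -3.16,
      Overturn_Occurred = 1.25,
      Collision_with_Fixed_Object = -1.87,
      Accident_0000_to_0600 = 1.12,
      Truck_Involved = -2.2,
      Motorcycle_Involved = 1.13,
      Single_Lane_Road = 0.391
    ),
    random_var = "Front_to_Back_Collision",
    het_mean_coefs = c(
      constant = -0.99,
      FEV_at_Fault = -0.74,
      Straight_Road = 0.913
    ),
    random_sd = random_sd,
    thresholds = c(-1.07, 3.18)
  )
}

#' Generate binary crash covariates
#'
#' Samples a crash table (without severity) from a [prevalence_config()]:
#' each exclusive group is drawn one-hot from its category probabilities and
#' each flag independently Bernoulli.  Optionally, flags can be given a
#' Gaussian-copula dependence structure; the registry reports marginals only,
#' so flags are independent by default.
#'
#' @param config A [prevalence_config()].
#' @param seed Integer seed; the same config and seed reproduce the same
#'   table.
#' @param flag_correlation Optional correlation matrix (dimnames matching
#'   flag names) inducing Gaussian-copula dependence between flags.
#' @return A tibble of 0/1 integer columns with `n_records` rows.
#' @export
generate_covariates <- function(config, seed = 1L, flag_correlation = NULL) {
  if (!inherits(config, "prevalence_config")) {
    stop_config("`config` must be a `prevalence_config` object.")
  }
  n <- config$n_records
  seeds <- seed_substreams(seed, 2L)
  cols <- list()

  withr::with_seed(seeds[1L], {
    for (g in config$exclusive_groups) {
      k <- length(g$categories)
      pick <- sample.int(k, n, replace = TRUE, prob = g$probs)
      for (j in seq_len(k)) {
        cols[[g$categories[j]]] <- as.integer(pick == j)
      }
    }
  })

  flags <- config$independent_flags
  withr::with_seed(seeds[2L], {
    if (length(flags) > 0L) {
      if (is.null(flag_correlation)) {
        for (nm in names(flags)) {
          cols[[nm]] <- rbinom(n, 1L, flags[[nm]])
        }
      } else {
        nm <- names(flags)
        if (!all(nm %in% rownames(flag_correlation))) {
          stop_config("`flag_correlation` dimnames must cover all flags.")
        }
        Sigma <- flag_correlation[nm, nm, drop = FALSE]
        L <- chol(Sigma)
        Zmat <- matrix(rnorm(n * length(nm)), n) %*% L
        for (j in seq_along(nm)) {
          cols[[nm[j]]] <- as.integer(Zmat[, j] < qnorm(flags[[nm[j]]]))
        }
      }
    }
  })

  as_tibble(cols)
}

#' Simulate ordinal injury severity from the latent model
#'
#' Draws the random coefficient \eqn{\beta'_i} per row, forms the latent mean,
#' adds standard logistic noise and cuts at the thresholds.  When
#' `calibrate_to_shares` is given, the two thresholds are re-solved by
#' monotone bisection on the realized latent values so that the empirical
#' class shares match the target (to within the empirical CDF's 1/n
#' granularity); the thresholds actually used are returned in the
#' `"calibration"` attribute.
#'
#' @param covariates Tibble of covariate columns (no `severity`).
#' @param dgp A [dgp_params()] object.
#' @param seed Integer seed (split into sub-streams for the random
#'   coefficient and the latent noise).
#' @param calibrate_to_shares Optional length-3 target class shares summing
#'   to 1.
#' @param .suppress_noise Test hook: drop the logistic noise term (the latent
#'   is then the deterministic mean plus the random-coefficient draw).
#' @return The input tibble with an integer `severity` column in
#'   `{1, 2, 3}`, carrying a `"calibration"` attribute (thresholds used,
#'   achieved shares).
#' @export
simulate_severity <- function(covariates, dgp, seed = 1L,
                              calibrate_to_shares = NULL,
                              .suppress_noise = FALSE) {
  if (!inherits(dgp, "dgp_params")) {
    stop_parameter("`dgp` must be a `dgp_params` object.")
  }
  if (diff(dgp$thresholds) <= 0) {
    stop_parameter("`thresholds` must be strictly increasing.")
  }
  fixed_vars <- setdiff(names(dgp$fixed_coefs), "constant")
  shifters <- setdiff(names(dgp$het_mean_coefs), "constant")
  check_columns_present(covariates, c(fixed_vars, dgp$random_var, shifters))
  if (!is.null(calibrate_to_shares)) {
    if (length(calibrate_to_shares) != 3L ||
        abs(sum(calibrate_to_shares) - 1) > 1e-8 ||
        any(calibrate_to_shares <= 0)) {
      stop_parameter("`calibrate_to_shares` must be 3 positive shares summing to 1.")
    }
  }

  n <- nrow(covariates)
  seeds <- seed_substreams(seed, 2L)

  const <- if ("constant" %in% names(dgp$fixed_coefs)) {
    dgp$fixed_coefs[["constant"]]
  } else 0
  v_fixed <- rep(const, n)
  for (nm in fixed_vars) {
    v_fixed <- v_fixed + dgp$fixed_coefs[[nm]] * covariates[[nm]]
  }

  mu <- rep(dgp$het_mean_coefs[["constant"]], n)
  for (nm in shifters) {
    mu <- mu + dgp$het_mean_coefs[[nm]] * covariates[[nm]]
  }
  eps <- withr::with_seed(seeds[1L], rnorm(n, sd = dgp$random_sd))
  beta_rand <- mu + eps
  latent_mean <- v_fixed + beta_rand * covariates[[dgp$random_var]]

  noise <- if (.suppress_noise) {
    rep(0, n)
  } else {
    withr::with_seed(seeds[2L], rlogis_std(n))
  }
  latent <- latent_mean + noise

  thresholds <- dgp$thresholds
  if (!is.null(calibrate_to_shares)) {
    thresholds <- calibrate_thresholds(latent, calibrate_to_shares)
  }

  severity <- 1L + (latent > thresholds[1L]) + (latent > thresholds[2L])
  out <- covariates
  out$severity <- as.integer(severity)
  achieved <- as.numeric(table(factor(severity, levels = 1:3)) / n)
  attr(out, "calibration") <- list(
    thresholds = thresholds,
    target_shares = calibrate_to_shares,
    achieved_shares = achieved
  )
  out
}

rlogis_std <- function(n) stats::rlogis(n)

# Monotone bisection on the empirical CDF of the realized latent values:
# tau_1 targets the first cumulative share and tau_2 the first two.  The
# empirical CDF is a step function with steps of size 1/n, so the achieved
# share is within 1/n of the target; bisection stops when the share is within
# 1e-4 or the bracketing interval collapses onto a step.
calibrate_thresholds <- function(latent, shares) {
  targets <- cumsum(shares)[1:2]
  lo0 <- min(latent) - 1
  hi0 <- max(latent) + 1
  solve_one <- function(target) {
    lo <- lo0
    hi <- hi0
    for (it in seq_len(200L)) {
      mid <- (lo + hi) / 2
      share <- mean(latent <= mid)
      if (abs(share - target) <= 1e-4 || (hi - lo) < 1e-12) break
      if (share < target) lo <- mid else hi <- mid
    }
    mid
  }
  tau1 <- solve_one(targets[1L])
  tau2 <- solve_one(targets[2L])
  if (tau2 <= tau1) tau2 <- tau1 + 1e-8
  c(tau1, tau2)
}

#' Simulate a complete synthetic crash table
#'
#' Convenience wrapper: draws covariates from [fev_prevalence_config()] (or a
#' supplied configuration) and simulates severity from [fev_dgp_params()] (or
#' a supplied DGP), calibrating the thresholds to the registry class shares
#' 22.01 / 58.33 / 19.66 per cent by default.
#'
#' @param n Number of crashes (default 768).
#' @param seed Integer seed.
#' @param config Optional [prevalence_config()] (defaults to
#'   `fev_prevalence_config(n)`).
#' @param dgp Optional [dgp_params()] (defaults to `fev_dgp_params()`).
#' @param calibrate_to_shares Target class shares, or `NULL` to use the DGP
#'   thresholds as-is.
#' @return A crash tibble with a `severity` column.
#' @export
simulate_crashes <- function(n = 768L, seed = 1L,
                             config = NULL, dgp = NULL,
                             calibrate_to_shares = c(0.2201, 0.5833, 0.1966)) {
  if (is.null(config)) config <- fev_prevalence_config(n)
  if (is.null(dgp)) dgp <- fev_dgp_params()
  if (!is.null(calibrate_to_shares)) {
    calibrate_to_shares <- calibrate_to_shares / sum(calibrate_to_shares)
  }
  seeds <- seed_substreams(seed, 2L)
  covariates <- generate_covariates(config, seed = seeds[1L])
  simulate_severity(covariates, dgp, seed = seeds[2L],
                    calibrate_to_shares = calibrate_to_shares)
}

#' Read or write a generator configuration as YAML
#'
#' The YAML layout mirrors [prevalence_config()] and [dgp_params()]:
#' top-level keys `n_records`, `exclusive_groups`, `independent_flags` and
#' `dgp` (with `fixed_coefs`, `random_var`, `het_mean_coefs`, `random_sd`,
#' `thresholds`, `noise_law`).  The file shipped at
#' `system.file("extdata", "fev_generator.yaml", package = "fevcrash")`
#' reproduces the packaged defaults.
#'
#' @param path Path to a YAML file.
#' @return `read_generator_config()` returns a list with elements `config`
#'   (a [prevalence_config()]) and `dgp` (a [dgp_params()] or `NULL`).
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  groups <- lapply(raw$exclusive_groups, function(g) {
    list(name = g$name, categories = unlist(g$categories),
         probs = unlist(g$probs) / sum(unlist(g$probs)))
  })
  flags <- unlist(raw$independent_flags)
  config <- prevalence_config(groups, flags, raw$n_records)
  dgp <- NULL
  if (!is.null(raw$dgp)) {
    d <- raw$dgp
    dgp <- dgp_params(
      fixed_coefs = unlist(d$fixed_coefs),
      random_var = d$random_var,
      het_mean_coefs = unlist(d$het_mean_coefs),
      random_sd = d$random_sd,
      thresholds = unlist(d$thresholds),
      noise_law = d$noise_law %||% "logistic"
    )
  }
  list(config = config, dgp = dgp)
}

#' @rdname read_generator_config
#' @param config A [prevalence_config()].
#' @param dgp Optional [dgp_params()].
#' @export
write_generator_config <- function(config, dgp = NULL, path) {
  out <- list(
    n_records = config$n_records,
    exclusive_groups = lapply(config$exclusive_groups, function(g) {
      list(name = g$name, categories = as.list(g$categories),
           probs = as.list(g$probs))
    }),
    independent_flags = as.list(config$independent_flags)
  )
  if (!is.null(dgp)) {
    out$dgp <- list(
      fixed_coefs = as.list(dgp$fixed_coefs),
      random_var = dgp$random_var,
      het_mean_coefs = as.list(dgp$het_mean_coefs),
      random_sd = dgp$random_sd,
      thresholds = as.list(dgp$thresholds),
      noise_law = dgp$noise_law
    )
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Read or write a crash table as CSV
#'
#' Plain UTF-8 comma-separated files with a header row; column names are the
#' covariate identifiers used throughout the package (e.g.
#' `Overturn_Occurred`, `Front_to_Back_Collision`) plus `severity`.
#' `read_crash_table()` validates the severity domain on the way in.
#'
#' @param path File path.
#' @return `read_crash_table()` returns a tibble; `write_crash_table()`
#'   returns `path` invisibly.
#' @export
read_crash_table <- function(path) {
  tab <- as_tibble(utils::read.csv(path, check.names = FALSE,
                                   fileEncoding = "UTF-8"))
  if ("severity" %in% names(tab) && !all(tab$severity %in% 1:3)) {
    stop_validation("`severity` must take values in {1, 2, 3}.")
  }
  tab
}

#' @rdname read_crash_table
#' @param table Crash tibble.
#' @export
write_crash_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
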
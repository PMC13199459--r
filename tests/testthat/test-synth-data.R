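test_that("covariate generation honours degenerate and fixed probabilities", {
  cfg <- prevalence_config(
    exclusive_groups = list(list(
      name = "g", categories = c("A", "B"), probs = c(0.3, 0.7)
    )),
    independent_flags = c(never = 0, always = 1, half = 0.5),
    n_records = 200L
  )
  tab <- generate_covariates(cfg, seed = 11)
  expect_identical(unique(tab$never), 0L)
  expect_identical(unique(tab$always), 1L)
  expect_true(all(tab$A + tab$B == 1L))

  tab2 <- generate_covariates(cfg, seed = 11)
  expect_identical(tab, tab2)
  tab3 <- generate_covariates(cfg, seed = 12)
  expect_false(identical(tab, tab3))
})

test_that("sampled prevalences match the registry marginals within binomial noise", {
  cfg <- fev_prevalence_config(768L)
  tab <- generate_covariates(cfg, seed = 99)
  p <- 108 / 768  # overturn-and-fall share, 14.06% of crashes
  expect_lt(abs(mean(tab$Overturn_Occurred) - p), 3 * sqrt(p * (1 - p) / 768))
  # exclusive groups stay one-hot
  hour <- tab[c("Accident_0000_to_0600", "Accident_0600_to_1200",
                "Accident_1200_to_1800", "Accident_1800_to_2400")]
  expect_true(all(rowSums(hour) == 1L))
})

test_that("invalid configurations are rejected with the offending entry named", {
  expect_error(
    prevalence_config(independent_flags = c(ok = 0.5, bad = 1.2)),
    "bad", class = "fevcrash_config_error"
  )
  expect_error(
    prevalence_config(exclusive_groups = list(list(
      name = "g", categories = c("A", "B"), probs = c(0.5, 0.6)
    ))),
    "sum", class = "fevcrash_config_error"
  )
  expect_error(prevalence_config(n_records = 0), class = "fevcrash_config_error")
  expect_error(
    dgp_params(c(constant = 1), "x", thresholds = c(2, 1)),
    class = "fevcrash_parameter_error"
  )
})

test_that("thresholds dominate and the deterministic cut matches the band", {
  cov <- generate_covariates(fev_prevalence_config(300L), seed = 1)
  dgp_hi <- fev_dgp_params()
  dgp_hi$thresholds <- c(1e6, 2e6)
  out <- simulate_severity(cov, dgp_hi, seed = 1)
  expect_true(all(out$severity == 1L))

  # noise suppressed, sd = 0, latent exactly the constant 0.5: always Injury
  dgp0 <- dgp_params(
    fixed_coefs = c(constant = 0.5),
    random_var = "Front_to_Back_Collision",
    het_mean_coefs = c(constant = 0),
    random_sd = 0, thresholds = c(-1.07, 3.18)
  )
  out0 <- simulate_severity(cov, dgp0, seed = 1, .suppress_noise = TRUE)
  expect_true(all(out0$severity == 2L))

  expect_error(
    simulate_severity(cov[, 1:3], fev_dgp_params(), seed = 1),
    class = "fevcrash_schema_error"
  )
})

test_that("threshold calibration hits the registry class shares", {
  target <- c(0.2201, 0.5833, 0.1966)
  tab <- simulate_crashes(768L, seed = 4)
  shares <- as.numeric(table(factor(tab$severity, levels = 1:3))) / 768
  expect_true(all(abs(shares - target / sum(target)) <= 0.02))
  cal <- attr(tab, "calibration")
  expect_true(cal$thresholds[1] < cal$thresholds[2])
  expect_equal(cal$achieved_shares, shares)
})

test_that("class shares move monotonically with the first threshold", {
  cov <- generate_covariates(fev_prevalence_config(500L), seed = 3)
  dgp <- fev_dgp_params()
  share1 <- vapply(c(-2, -1, 0, 1, 2), function(t1) {
    dgp$thresholds <- c(t1, 5)
    mean(simulate_severity(cov, dgp, seed = 8)$severity == 1L)
  }, numeric(1))
  expect_true(all(diff(share1) >= 0))
})

test_that("with zero coefficients the shares follow the logistic CDF", {
  n <- 20000L
  cov <- generate_covariates(prevalence_config(
    independent_flags = c(Front_to_Back_Collision = 0.3), n_records = n
  ), seed = 6)
  dgp <- dgp_params(
    fixed_coefs = c(constant = 0),
    random_var = "Front_to_Back_Collision",
    het_mean_coefs = c(constant = 0),
    random_sd = 0, thresholds = c(-0.8, 1.2)
  )
  out <- simulate_severity(cov, dgp, seed = 21)
  expected <- c(plogis(-0.8), plogis(1.2) - plogis(-0.8), 1 - plogis(1.2))
  shares <- as.numeric(table(factor(out$severity, levels = 1:3))) / n
  tol <- 3 * sqrt(expected * (1 - expected) / n)
  expect_true(all(abs(shares - expected) < tol))
})

test_that("sd = 0 reduces the generator to a fixed-coefficient ordered logit", {
  # 4 distinct covariate patterns, each heavily replicated; class counts per
  # pattern must be consistent with the closed-form trinomial probabilities
  n_rep <- 12500L
  grid <- tibble::tibble(
    Overturn_Occurred = rep(c(0L, 1L, 0L, 1L), each = n_rep),
    Front_to_Back_Collision = rep(c(0L, 0L, 1L, 1L), each = n_rep)
  )
  dgp <- dgp_params(
    fixed_coefs = c(constant = 0.2, Overturn_Occurred = 1.1),
    random_var = "Front_to_Back_Collision",
    het_mean_coefs = c(constant = -0.9),
    random_sd = 0, thresholds = c(-1, 1.4)
  )
  out <- simulate_severity(grid, dgp, seed = 31)
  pattern <- interaction(grid$Overturn_Occurred, grid$Front_to_Back_Collision)
  for (lev in levels(pattern)) {
    rows <- pattern == lev
    v <- 0.2 + 1.1 * grid$Overturn_Occurred[rows][1] -
      0.9 * grid$Front_to_Back_Collision[rows][1]
    probs <- ordered_class_probs(v, c(-1, 1.4))
    counts <- as.numeric(table(factor(out$severity[rows], levels = 1:3)))
    gof <- suppressWarnings(chisq.test(counts, p = as.numeric(probs)))
    expect_gt(gof$p.value, 0.01)
  }
})

test_that("the packaged YAML configuration reproduces the defaults", {
  path <- system.file("extdata", "fev_generator.yaml", package = "fevcrash")
  rt <- read_generator_config(path)
  expect_equal(rt$config$n_records, 768L)
  expect_equal(rt$config$independent_flags,
               fev_prevalence_config()$independent_flags, tolerance = 1e-6)
  expect_equal(rt$dgp$fixed_coefs, fev_dgp_params()$fixed_coefs)
  expect_equal(rt$dgp$thresholds, c(-1.07, 3.18))
  # generation through the file matches generation through the defaults
  a <- generate_covariates(rt$config, seed = 2)
  b <- generate_covariates(fev_prevalence_config(), seed = 2)
  expect_identical(a, b)
})

test_that("crash tables round-trip through CSV", {
  tab <- simulate_crashes(40L, seed = 19)
  path <- withr::local_tempfile(fileext = ".csv")
  write_crash_table(tab, path)
  rt <- read_crash_table(path)
  # CSV carries the cells, not the calibration attribute
  expect_equal(as.data.frame(rt), as.data.frame(tab), ignore_attr = TRUE)

  bad <- tab
  bad$severity[1] <- 7L
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, path2, row.names = FALSE)
  expect_error(read_crash_table(path2), class = "fevcrash_validation_error")
})

test_that("gaussian-copula flags reproduce marginals and induce dependence", {
  flags <- c(FEV_at_Fault = 0.5, Straight_Road = 0.5)
  cfg <- prevalence_config(independent_flags = flags, n_records = 8000L)
  Sigma <- matrix(c(1, 0.7, 0.7, 1), 2, 2,
                  dimnames = list(names(flags), names(flags)))
  tab <- generate_covariates(cfg, seed = 5, flag_correlation = Sigma)
  expect_lt(abs(mean(tab$FEV_at_Fault) - 0.5), 0.02)
  expect_gt(cor(tab$FEV_at_Fault, tab$Straight_Road), 0.3)
})
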
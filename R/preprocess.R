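# Preprocessing: pavement classification, model specification and design
# encoding, correlation-based feature screening, train/test splitting and
# registry-style descriptive tables.

#' Classify pavement condition from PCI and IRI
#'
#' Maps Pavement Condition Index (0-100, higher is better) and International
#' Roughness Index (m/km, higher is rougher) readings onto the four
#' maintenance categories used by the national pavement-management system:
#' \itemize{
#'   \item PCI 90-100 / IRI 0-3: `Acceptable`
#'   \item PCI 60-90 / IRI 0-3: `LowFailure`
#'   \item PCI 40-60 / IRI 3-4: `ModerateFailure`
#'   \item PCI < 40 / IRI > 4: `SevereFailure`
#' }
#' An IRI of at most 3 m/km is compatible with both `Acceptable` and
#' `LowFailure`; outside that overlap, when the two indicators disagree the
#' worse (more deteriorated) category is returned and the `conflict` flag is
#' set.
#'
#' @param pci Numeric vector of PCI values in `[0, 100]`.
#' @param iri Numeric vector of non-negative IRI values (m/km), recycled
#'   against `pci`.
#' @return A tibble with columns `pci`, `iri`, `category` (ordered factor)
#'   and `conflict` (logical).
#' @examples
#' classify_pavement(c(95, 50, 70), c(1, 3.5, 5))
#' @export
classify_pavement <- function(pci, iri) {
  if (any(!is.finite(pci)) || any(pci < 0 | pci > 100)) {
    stop_validation("`pci` must lie in [0, 100].")
  }
  if (any(!is.finite(iri)) || any(iri < 0)) {
    stop_validation("`iri` must be non-negative.")
  }
  n <- max(length(pci), length(iri))
  pci <- rep_len(pci, n)
  iri <- rep_len(iri, n)

  pci_level <- ifelse(pci >= 90, 1L, ifelse(pci >= 60, 2L, ifelse(pci >= 40, 3L, 4L)))
  iri_level <- ifelse(iri <= 3, 1L, ifelse(iri <= 4, 3L, 4L))

  level <- pmax(pci_level, iri_level)
  # IRI <= 3 spans the Acceptable/LowFailure columns, so that combination is
  # not a conflict; any other disagreement is.
  overlap <- iri_level == 1L & pci_level <= 2L
  conflict <- pci_level != iri_level & !overlap

  cats <- c("Acceptable", "LowFailure", "ModerateFailure", "SevereFailure")
  tibble(
    pci = pci,
    iri = iri,
    category = factor(cats[level], levels = cats, ordered = TRUE),
    conflict = conflict
  )
}

#' Model specification for the ordered severity model
#'
#' Names the columns that enter the latent severity function: the fixed-
#' coefficient covariates, the single random-coefficient carrier, the
#' heterogeneity-in-means shifters, and optional pairwise interactions
#' (materialized as elementwise products at encoding time).
#'
#' @param fixed_vars Ordered character vector of fixed-coefficient columns.
#' @param random_var Name of the random-coefficient column.
#' @param het_mean_vars Character vector of mean-shifter columns.
#' @param interactions List of length-2 character vectors; each pair is
#'   appended as a product column.
#' @param outcome Name of the ordinal outcome column (default `"severity"`).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(fixed_vars,
                       random_var,
                       het_mean_vars = character(),
                       interactions = list(),
                       outcome = "severity") {
  if (anyDuplicated(c(fixed_vars, random_var))) {
    stop_config("`fixed_vars` and `random_var` must not overlap or repeat.")
  }
  for (p in interactions) {
    if (length(p) != 2L || !is.character(p)) {
      stop_config("Each interaction must be a pair of column names.")
    }
  }
  structure(
    list(
      fixed_vars = fixed_vars,
      random_var = random_var,
      het_mean_vars = het_mean_vars,
      interactions = interactions,
      outcome = outcome
    ),
    class = "model_spec"
  )
}

#' Default model specification of the registry severity function
#'
#' Nine fixed crash attributes, a random coefficient on
#' `Front_to_Back_Collision`, and mean shifters `FEV_at_Fault` and
#' `Straight_Road`.
#'
#' @return A [model_spec()] object.
#' @export
fev_model_spec <- function() {
  model_spec(
    fixed_vars = c(
      "Unsafe_Distance_cause", "Vehicle_Defect_Cause", "Reversing_Cause",
      "Overturn_Occurred", "Collision_with_Fixed_Object",
      "Accident_0000_to_0600", "Truck_Involved", "Motorcycle_Involved",
      "Single_Lane_Road"
    ),
    random_var = "Front_to_Back_Collision",
    het_mean_vars = c("FEV_at_Fault", "Straight_Road")
  )
}

#' Encode a crash table into model matrices
#'
#' Materializes the design for estimation: `X` holds the fixed-coefficient
#' columns in specification order, then interaction products, then the
#' random-coefficient column last; `Z` holds the heterogeneity shifters;
#' `one_hot` is the n-by-3 outcome indicator matrix.
#'
#' @param table Crash tibble including the outcome column.
#' @param spec A [model_spec()].
#' @return An object of class `crash_design` with elements `X`, `Z`, `y`,
#'   `one_hot`, `x_names`, `z_names`, `random_var` and `spec`.
#' @export
encode_design <- function(table, spec) {
  if (!inherits(spec, "model_spec")) {
    stop_schema("`spec` must be a `model_spec` object.")
  }
  needed <- unique(c(spec$fixed_vars, spec$random_var, spec$het_mean_vars,
                     unlist(spec$interactions), spec$outcome))
  check_columns_present(table, needed)
  if (anyNA(table[needed])) {
    stop_validation("Design columns contain missing cells; impute upstream or drop rows.")
  }
  y <- table[[spec$outcome]]
  if (!all(y %in% 1:3)) {
    stop_validation(sprintf(
      "Outcome `%s` must take values in {1, 2, 3}.", spec$outcome
    ))
  }
  y <- as.integer(y)

  X <- as.matrix(table[spec$fixed_vars])
  storage.mode(X) <- "double"
  inter_names <- character()
  for (p in spec$interactions) {
    nm <- paste(p, collapse = ":")
    X <- cbind(X, table[[p[1L]]] * table[[p[2L]]])
    inter_names <- c(inter_names, nm)
  }
  X <- cbind(X, as.numeric(table[[spec$random_var]]))
  x_names <- c(spec$fixed_vars, inter_names, spec$random_var)
  colnames(X) <- x_names

  Z <- as.matrix(table[spec$het_mean_vars])
  storage.mode(Z) <- "double"
  if (ncol(Z) > 0L) colnames(Z) <- spec$het_mean_vars

  if (any(!is.finite(X)) || any(!is.finite(Z))) {
    stop_validation("Design matrices contain non-finite entries.")
  }

  one_hot <- matrix(0L, nrow(X), 3L,
                    dimnames = list(NULL, severity_labels()))
  one_hot[cbind(seq_along(y), y)] <- 1L

  structure(
    list(
      X = X, Z = Z, y = y, one_hot = one_hot,
      x_names = x_names, z_names = spec$het_mean_vars,
      random_var = spec$random_var, spec = spec
    ),
    class = "crash_design"
  )
}

#' @export
print.crash_design <- function(x, ...) {
  cat(sprintf(
    "<crash_design> %d obs, %d X columns (random: %s), %d Z columns\n",
    nrow(x$X), ncol(x$X), x$random_var, ncol(x$Z)
  ))
  invisible(x)
}

#' Correlation-based feature screening
#'
#' Mirrors the pre-modelling correlation analysis: drops constant columns,
#' resolves near-collinear pairs (absolute phi coefficient at or above the
#' cutoff) by keeping the earlier column in specification order, and drops
#' columns whose chi-square association with the 3-class outcome has a
#' p-value above `alpha`.  The random-coefficient column is never dropped
#' unless `allow_drop_random = TRUE`, since estimation would be undefined
#' without it.
#'
#' @param design A [encode_design()] result.
#' @param alpha Significance level for the outcome-association test
#'   (default 0.05).
#' @param collinearity_cutoff Absolute phi-coefficient threshold (default
#'   0.8).
#' @param allow_drop_random Permit dropping the random-coefficient column.
#' @return A list with `retained` (character vector) and `report` (tibble
#'   with one row per column: action, reason, p-value, Cramer's V, partner).
#' @export
screen_features <- function(design, alpha = 0.05, collinearity_cutoff = 0.8,
                            allow_drop_random = FALSE) {
  if (!inherits(design, "crash_design")) {
    stop_schema("`design` must be a `crash_design` object.")
  }
  if (nrow(design$X) == 0L || ncol(design$X) == 0L) {
    stop_validation("Empty design.")
  }
  check_scalar_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  check_scalar_number(collinearity_cutoff, "collinearity_cutoff",
                      lower = 1e-12, upper = 1)

  X <- design$X
  y <- design$y
  nms <- colnames(X)
  action <- setNames(rep("kept", ncol(X)), nms)
  reason <- setNames(rep(NA_character_, ncol(X)), nms)
  partner <- setNames(rep(NA_character_, ncol(X)), nms)
  p_value <- setNames(rep(NA_real_, ncol(X)), nms)
  cramers_v <- setNames(rep(NA_real_, ncol(X)), nms)

  protect <- function(nm) nm == design$random_var && !allow_drop_random

  # 1. constants
  for (nm in nms) {
    if (sd(X[, nm]) == 0) {
      if (protect(nm)) {
        reason[nm] <- "constant but retained (random-coefficient column)"
      } else {
        action[nm] <- "dropped"
        reason[nm] <- "constant column"
      }
    }
  }

  # 2. collinearity: keep the earlier column of each offending pair
  alive <- nms[action == "kept"]
  for (i in seq_along(alive)) {
    for (j in seq_along(alive)) {
      if (j <= i) next
      a <- alive[i]; b <- alive[j]
      if (action[a] == "dropped" || action[b] == "dropped") next
      if (sd(X[, a]) == 0 || sd(X[, b]) == 0) next
      phi <- cor(X[, a], X[, b])
      if (is.finite(phi) && abs(phi) >= collinearity_cutoff) {
        drop_nm <- b
        if (protect(b)) drop_nm <- if (protect(a)) NA_character_ else a
        if (!is.na(drop_nm)) {
          action[drop_nm] <- "dropped"
          reason[drop_nm] <- sprintf("collinear (|phi| = %.3f)", abs(phi))
          partner[drop_nm] <- setdiff(c(a, b), drop_nm)
        }
      }
    }
  }

  # 3. outcome association (chi-square on the column x 3-class table)
  for (nm in nms) {
    if (action[nm] == "dropped") next
    tab <- table(X[, nm], y)
    if (nrow(tab) < 2L) next
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    p_value[nm] <- ct$p.value
    k <- min(dim(tab)) - 1L
    cramers_v[nm] <- sqrt(as.numeric(ct$statistic) / (length(y) * max(k, 1L)))
    if (is.finite(ct$p.value) && ct$p.value > alpha) {
      if (protect(nm)) {
        reason[nm] <- sprintf(
          "p = %.3f > alpha but retained (random-coefficient column)",
          ct$p.value
        )
      } else {
        action[nm] <- "dropped"
        reason[nm] <- sprintf("outcome association p = %.3f > %.3f",
                              ct$p.value, alpha)
      }
    }
  }

  report <- tibble(
    column = nms,
    action = unname(action),
    reason = unname(reason),
    p_value = unname(p_value),
    cramers_v = unname(cramers_v),
    collinear_with = unname(partner)
  )
  list(retained = nms[action == "kept"], report = report)
}

#' Random train/test split of a crash table
#'
#' The test set holds `floor(test_fraction * n)` rows, which reproduces the
#' registry partition of 768 crashes into 615 training and 153 test
#' observations at `test_fraction = 0.2` (plain rounding would give
#' 614/154).  The split is a disjoint, exhaustive, seed-reproducible random
#' partition.
#'
#' @param table Crash tibble.
#' @param test_fraction Fraction in (0, 1) assigned to the test set.
#' @param seed Integer seed.
#' @return A list with tibbles `train` and `test`; the `"test_indices"`
#'   attribute records the selected row indices for exact reruns.
#' @export
split_train_test <- function(table, test_fraction = 0.2, seed = 1L) {
  n <- nrow(table)
  if (n < 2L) stop_validation("Need at least 2 rows to split.")
  if (!is.numeric(test_fraction) || length(test_fraction) != 1L ||
      test_fraction <= 0 || test_fraction >= 1) {
    stop_parameter("`test_fraction` must lie strictly between 0 and 1.")
  }
  n_test <- floor(test_fraction * n)
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  test_idx <- sort(perm[seq_len(n_test)])
  out <- list(
    train = table[-test_idx, , drop = FALSE],
    test = table[test_idx, , drop = FALSE]
  )
  attr(out, "test_indices") <- test_idx
  out
}

#' Descriptive crash statistics by severity
#'
#' Registry-style summary: for each category column in each grouping, the
#' total count and per-severity counts with percentages rounded to 2
#' decimals, plus the overall class-share rows.  Denominators are explicit
#' rather than mixed: `pct_total` divides by the number of rows with any
#' indicator set in the grouping (equal to n for exhaustive groups), and the
#' per-severity percentages divide by that severity's count among the same
#' rows.
#'
#' @param table Crash tibble with a `severity` column.
#' @param groupings Named list of character vectors; each vector is a set of
#'   mutually exclusive indicator columns.  Defaults to every non-severity
#'   column as its own (flag) grouping.
#' @return A tibble with columns `group`, `category`, `n`, `pct_total` and
#'   per-severity counts/percentages; class-share rows appear under group
#'   `"severity"`.
#' @export
descriptive_table <- function(table, groupings = NULL) {
  check_columns_present(table, "severity")
  y <- as.integer(table[["severity"]])
  if (!all(y %in% 1:3)) {
    stop_validation("`severity` must take values in {1, 2, 3}.")
  }
  n <- nrow(table)
  if (is.null(groupings)) {
    flags <- setdiff(names(table), "severity")
    groupings <- setNames(as.list(flags), flags)
  }
  pct <- function(num, den) round(100 * num / max(den, 1L), 2)

  rows <- list()
  for (g in names(groupings)) {
    cols <- groupings[[g]]
    check_columns_present(table, cols)
    ind <- as.matrix(table[cols]) > 0
    in_group <- rowSums(ind) > 0
    den_total <- sum(in_group)
    den_sev <- vapply(1:3, function(j) sum(in_group & y == j), integer(1))
    for (nm in cols) {
      hit <- table[[nm]] > 0
      n_hit <- sum(hit)
      n_sev <- vapply(1:3, function(j) sum(hit & y == j), integer(1))
      rows[[length(rows) + 1L]] <- tibble(
        group = g, category = nm,
        n = n_hit, pct_total = pct(n_hit, den_total),
        n_pdo = n_sev[1L], pct_pdo = pct(n_sev[1L], den_sev[1L]),
        n_injury = n_sev[2L], pct_injury = pct(n_sev[2L], den_sev[2L]),
        n_fatal = n_sev[3L], pct_fatal = pct(n_sev[3L], den_sev[3L])
      )
    }
  }
  class_n <- vapply(1:3, function(j) sum(y == j), integer(1))
  class_pct <- pct(class_n, n)
  for (j in 1:3) {
    rows[[length(rows) + 1L]] <- tibble(
      group = "severity", category = severity_labels()[j],
      n = class_n[j], pct_total = class_pct[j],
      n_pdo = NA_integer_, pct_pdo = NA_real_,
      n_injury = NA_integer_, pct_injury = NA_real_,
      n_fatal = NA_integer_, pct_fatal = NA_real_
    )
  }
  dplyr::bind_rows(rows)
}
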
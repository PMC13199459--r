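# Crammer-Singer multi-class SVM benchmark.  Single joint optimization: the
# true class's score must beat every other class's score by a margin of 1
# minus a shared slack, with squared-norm regularization traded against the
# summed slacks by C.  Solved in the dual by exact per-observation
# coordinate minimization (see src/mcsvm_cd.cpp); the bias enters through
# constant-feature augmentation, so it is (mildly) regularized.

#' Construct a multi-class SVM model object
#'
#' Mostly useful for tests and hand-built examples; fitted models come from
#' [fit_mcsvm()].
#'
#' @param W k-by-p matrix of class weight vectors (original feature scale).
#' @param b Length-k bias vector.
#' @param C Positive regularization constant.
#' @param feature_names Character vector of length p.
#' @param center,scale Per-feature standardization parameters applied before
#'   scoring (defaults: no standardization).
#' @return An object of class `mcsvm_model`.
#' @export
mcsvm_model <- function(W, b, C, feature_names = colnames(W),
                        center = rep(0, ncol(W)), scale = rep(1, ncol(W))) {
  if (!is.matrix(W) || !all(is.finite(W))) {
    stop_parameter("`W` must be a finite numeric matrix.")
  }
  check_scalar_number(C, "C", lower = 1e-300)
  if (length(b) != nrow(W)) stop_schema("`b` must have one entry per class.")
  if (!is.null(feature_names) && length(feature_names) != ncol(W)) {
    stop_schema("`feature_names` must align with the columns of `W`.")
  }
  structure(
    list(W = W, b = as.numeric(b), C = C,
         feature_names = feature_names,
         center = as.numeric(center), scale = as.numeric(scale)),
    class = "mcsvm_model"
  )
}

features_from <- function(data, feature_names) {
  if (inherits(data, "crash_design")) {
    X <- data$X
  } else if (is.matrix(data)) {
    X <- data
  } else {
    check_columns_present(data, feature_names)
    X <- as.matrix(data[feature_names])
  }
  if (!is.null(feature_names)) {
    if (is.null(colnames(X))) {
      if (ncol(X) != length(feature_names)) {
        stop_schema("Feature matrix width does not match the model.")
      }
      colnames(X) <- feature_names
    } else {
      check_columns_present(as.data.frame(X), feature_names, "feature")
      X <- X[, feature_names, drop = FALSE]
    }
  }
  storage.mode(X) <- "double"
  X
}

#' Fit the Crammer-Singer multi-class SVM
#'
#' Linear model by default, matching the printed optimization problem;
#' features are standardized to mean 0 / sd 1 (constant columns pass
#' through) and a unit constant feature carries the bias.  The optional
#' `"rbf"` kernel mode fits kernelized one-vs-rest hinge classifiers via
#' \pkg{kernlab} and is an explicitly labelled approximation, not the
#' Crammer-Singer joint problem.
#'
#' @param design A [encode_design()] result (all `X` columns are used as
#'   features), or a list with elements `X` (matrix) and `y` (labels in
#'   1..3).
#' @param C Positive regularization constant (default 1).
#' @param kernel `"linear"` (default) or `"rbf"`.
#' @param standardize Standardize features before fitting (default `TRUE`).
#' @param max_epochs Epoch cap for the dual coordinate descent (default
#'   1000).
#' @param tol Maximal dual KKT violation at convergence (default 1e-6).
#' @param seed Seed for the per-epoch observation shuffle.
#' @return An `mcsvm_model` with solver diagnostics in `$diagnostics`
#'   (dual objective trace, epochs, convergence flag).
#' @export
fit_mcsvm <- function(design, C = 1, kernel = c("linear", "rbf"),
                      standardize = TRUE, max_epochs = 1000L, tol = 1e-6,
                      seed = 1L) {
  kernel <- match.arg(kernel)
  check_scalar_number(C, "C", lower = 1e-300)
  X <- if (is.matrix(design$X)) design$X else as.matrix(design$X)
  y <- as.integer(design$y)
  if (length(unique(y)) < 2L) {
    stop_validation("Training data contain a single class.")
  }
  if (!all(y %in% 1:3)) stop_validation("Labels must lie in {1, 2, 3}.")
  storage.mode(X) <- "double"
  feature_names <- colnames(X) %||% paste0("x", seq_len(ncol(X)))

  center <- rep(0, ncol(X))
  scl <- rep(1, ncol(X))
  if (standardize) {
    center <- colMeans(X)
    scl <- apply(X, 2L, sd)
    scl[scl == 0] <- 1
  }
  Xs <- sweep(sweep(X, 2L, center), 2L, scl, "/")

  if (kernel == "rbf") {
    return(fit_mcsvm_rbf(Xs, y, C, feature_names, center, scl))
  }

  Xa <- cbind(Xs, `(bias)` = 1)
  res <- mcsvm_cd_cpp(Xa, y, 3L, C, as.integer(max_epochs), tol,
                      as.integer(seed))
  W_aug <- res$W
  # back out original-scale weights: s = W_std (x - c)/s + w_bias
  W_std <- W_aug[, -ncol(Xa), drop = FALSE]
  W_orig <- sweep(W_std, 2L, scl, "/")
  b <- W_aug[, ncol(Xa)] - drop(W_orig %*% center)
  colnames(W_orig) <- feature_names

  model <- mcsvm_model(W_orig, b, C, feature_names, center, scl)
  model$W_augmented <- W_aug
  model$kernel <- "linear"
  model$diagnostics <- list(
    dual_objective_trace = res$dual_objective_trace,
    epochs = res$epochs,
    converged = res$converged,
    max_violation = res$max_violation,
    seed = as.integer(seed)
  )
  model
}

fit_mcsvm_rbf <- function(Xs, y, C, feature_names, center, scl) {
  if (!requireNamespace("kernlab", quietly = TRUE)) {
    stop_parameter("The rbf mode requires the kernlab package.")
  }
  fits <- lapply(1:3, function(j) {
    kernlab::ksvm(Xs, factor(y == j, levels = c(FALSE, TRUE)),
                  type = "C-svc", kernel = "rbfdot", C = C, scaled = FALSE)
  })
  structure(
    list(fits = fits, C = C, feature_names = feature_names,
         center = center, scale = scl, kernel = "rbf"),
    class = c("mcsvm_rbf_model")
  )
}

#' Decision scores and predicted classes
#'
#' Scores are \eqn{s_j = w_j \cdot x + b_j}; the predicted class is the
#' argmax, with ties broken toward the lower class index.  Raw decision
#' scores (no probability calibration) are the inputs to the ROC analysis.
#'
#' @param model An `mcsvm_model`.
#' @param data A crash tibble, feature matrix or `crash_design`.
#' @return A tibble with `score_pdo`, `score_injury`, `score_fatal` and
#'   `.pred_class` (integer in 1..3).
#' @export
score_and_predict <- function(model, data) {
  if (inherits(model, "mcsvm_rbf_model")) {
    X <- features_from(data, model$feature_names)
    Xs <- sweep(sweep(X, 2L, model$center), 2L, model$scale, "/")
    scores <- vapply(model$fits, function(f) {
      drop(kernlab::predict(f, Xs, type = "decision"))
    }, numeric(nrow(Xs)))
    if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  } else {
    X <- features_from(data, model$feature_names)
    scores <- X %*% t(model$W)
    scores <- sweep(scores, 2L, model$b, "+")
  }
  labels <- max.col(scores, ties.method = "first")
  tibble(
    score_pdo = scores[, 1L],
    score_injury = scores[, 2L],
    score_fatal = scores[, 3L],
    .pred_class = as.integer(labels)
  )
}

#' Primal objective of the Crammer-Singer problem
#'
#' \eqn{\frac{1}{2}\sum_j \lVert w_j\rVert^2 + C\sum_i \xi_i} with the
#' slacks recomputed from the data:
#' \eqn{\xi_i = \max(0, \max_{j \ne y_i}(s_j - s_{y_i} + 1))}.  By default
#' the norm is taken over the augmented (standardized + bias) weights, which
#' is the objective the solver actually minimizes; set
#' `include_bias = FALSE` to evaluate the textbook objective excluding the
#' bias from the norm (on the model's stored scale).
#'
#' @param model An `mcsvm_model`.
#' @param design A `crash_design`, or list with `X` and `y`.
#' @param include_bias Include the bias component in the norm (default
#'   `TRUE` when the model carries augmented weights).
#' @return A non-negative scalar.
#' @export
objective_value <- function(model, design, include_bias = NULL) {
  X <- if (is.matrix(design$X)) design$X else as.matrix(design$X)
  y <- as.integer(design$y)
  if (ncol(X) != ncol(model$W)) {
    stop_schema("Design width does not match the model's features.")
  }
  if (is.null(include_bias)) include_bias <- !is.null(model$W_augmented)

  sp <- score_and_predict(model, X)
  scores <- cbind(sp$score_pdo, sp$score_injury, sp$score_fatal)
  s_true <- scores[cbind(seq_along(y), y)]
  scores[cbind(seq_along(y), y)] <- -Inf
  s_best_other <- apply(scores, 1L, max)
  xi <- pmax(0, s_best_other - s_true + 1)

  if (include_bias) {
    if (!is.null(model$W_augmented)) {
      norm2 <- sum(model$W_augmented^2)
    } else {
      norm2 <- sum(model$W^2) + sum(model$b^2)
    }
  } else {
    norm2 <- sum(model$W^2)
  }
  0.5 * norm2 + model$C * sum(xi)
}

#' Training slacks of a fitted model
#'
#' @param model An `mcsvm_model`.
#' @param design A `crash_design` or list with `X` and `y`.
#' @return Numeric vector of recomputed slack variables.
#' @export
training_slacks <- function(model, design) {
  X <- if (is.matrix(design$X)) design$X else as.matrix(design$X)
  y <- as.integer(design$y)
  sp <- score_and_predict(model, X)
  scores <- cbind(sp$score_pdo, sp$score_injury, sp$score_fatal)
  s_true <- scores[cbind(seq_along(y), y)]
  scores[cbind(seq_along(y), y)] <- -Inf
  s_best_other <- apply(scores, 1L, max)
  pmax(0, s_best_other - s_true + 1)
}

#' Select the regularization constant by stratified cross-validation
#'
#' Stratified k-fold cross-validation over a grid of C values, scored by the
#' mean one-vs-rest macro-AUC on the held-out folds; ties go to the smaller
#' C (stronger regularization).
#'
#' @param design A `crash_design` or list with `X` and `y`.
#' @param grid Positive candidate C values (default
#'   `c(0.01, 0.1, 1, 10, 100)`).
#' @param folds Number of folds (default 5).
#' @param seed Seed for fold assignment and solver shuffles.
#' @param ... Passed to [fit_mcsvm()].
#' @return A list with `best_C` and `cv_table` (tibble of C, fold,
#'   macro-AUC).
#' @export
select_C_cv <- function(design, grid = c(0.01, 0.1, 1, 10, 100),
                        folds = 5L, seed = 1L, ...) {
  if (length(grid) == 0L || any(grid <= 0)) {
    stop_parameter("`grid` must be a non-empty vector of positive values.")
  }
  folds <- as.integer(folds)
  if (folds < 2L) stop_parameter("`folds` must be at least 2.")
  X <- if (is.matrix(design$X)) design$X else as.matrix(design$X)
  y <- as.integer(design$y)

  fold_id <- make_stratified_folds(y, folds, seed)

  rows <- list()
  for (C in sort(grid)) {
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      te <- !tr
      model <- fit_mcsvm(list(X = X[tr, , drop = FALSE], y = y[tr]),
                         C = C, seed = seed, ...)
      sp <- score_and_predict(model, X[te, , drop = FALSE])
      scores <- cbind(sp$score_pdo, sp$score_injury, sp$score_fatal)
      roc <- ovr_roc_auc(scores, y[te])
      rows[[length(rows) + 1L]] <- tibble(
        C = C, fold = f, macro_auc = mean(roc$auc)
      )
    }
  }
  cv_table <- dplyr::bind_rows(rows)
  summary <- dplyr::summarise(
    dplyr::group_by(cv_table, .data$C),
    mean_macro_auc = mean(.data$macro_auc), .groups = "drop"
  )
  best <- summary$C[which.max(summary$mean_macro_auc)]  # ties: smaller C
  list(best_C = best, cv_table = cv_table, summary = summary)
}

# Stratified fold labels: within each class, rows are shuffled and dealt
# round-robin.  Re-stratifies once with a derived seed if some fold misses a
# class, then errors.
make_stratified_folds <- function(y, folds, seed) {
  assign_once <- function(s) {
    fold_id <- integer(length(y))
    withr::with_seed(as.integer(s), {
      for (cls in unique(y)) {
        idx <- which(y == cls)
        idx <- idx[sample.int(length(idx))]
        fold_id[idx] <- rep_len(seq_len(folds), length(idx))
      }
    })
    fold_id
  }
  fold_id <- assign_once(seed)
  ok <- all(vapply(seq_len(folds), function(f) {
    length(unique(y[fold_id == f])) == length(unique(y))
  }, logical(1)))
  if (!ok) {
    fold_id <- assign_once(seed + 1L)
    ok <- all(vapply(seq_len(folds), function(f) {
      length(unique(y[fold_id == f])) == length(unique(y))
    }, logical(1)))
    if (!ok) {
      stop_validation("A fold lost a class even after re-stratification; reduce `folds`.")
    }
  }
  fold_id
}

#' @export
print.mcsvm_model <- function(x, ...) {
  cat(sprintf(
    "Crammer-Singer multi-class SVM (linear), C = %g, %d features\n",
    x$C, ncol(x$W)
  ))
  if (!is.null(x$diagnostics)) {
    cat(sprintf("  solver: %d epochs, converged: %s (max violation %.2e)\n",
                x$diagnostics$epochs, x$diagnostics$converged,
                x$diagnostics$max_violation))
  }
  invisible(x)
}

#' Tidy a fitted multi-class SVM
#'
#' @param x An `mcsvm_model`.
#' @param ... Unused.
#' @return A tibble with one row per (class, feature) weight plus per-class
#'   bias rows.
#' @export
tidy.mcsvm_model <- function(x, ...) {
  cls <- severity_labels()
  w <- as_tibble(x$W)
  w$class <- cls
  out <- tidyr::pivot_longer(w, -"class", names_to = "term",
                             values_to = "estimate")
  bias <- tibble(class = cls, term = "(bias)", estimate = x$b)
  dplyr::bind_rows(out, bias)
}

#' Glance at a fitted multi-class SVM
#'
#' @param x An `mcsvm_model`.
#' @param ... Unused.
#' @return A one-row tibble with C, solver epochs and convergence.
#' @export
glance.mcsvm_model <- function(x, ...) {
  tibble(
    C = x$C,
    epochs = x$diagnostics$epochs %||% NA_integer_,
    converged = x$diagnostics$converged %||% NA,
    dual_objective = if (length(x$diagnostics$dual_objective_trace)) {
      utils::tail(x$diagnostics$dual_objective_trace, 1L)
    } else NA_real_
  )
}

#' Serialize a fitted multi-class SVM to JSON
#'
#' @param model An `mcsvm_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mcsvm_json <- function(model, path) {
  out <- list(
    W = unclass(as.data.frame(model$W)),
    b = model$b,
    C = model$C,
    feature_names = model$feature_names,
    center = model$center,
    scale = model$scale,
    diagnostics = model$diagnostics[c("epochs", "converged", "seed")]
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
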
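# Model comparison: per-class one-vs-rest ROC/AUC on train and test splits,
# generalization gaps, permutation importance and partial dependence.

#' One-vs-rest ROC curves and AUCs for a 3-class problem
#'
#' For each severity class, builds the one-vs-rest ROC by sweeping a
#' threshold over the class's score column with ties grouped into single
#' sweep steps, and computes the AUC by the trapezoid rule (algebraically
#' equal to the tie-corrected Mann-Whitney rank statistic).
#'
#' @param scores n-by-3 numeric matrix (or data frame) of per-class scores
#'   or probabilities, columns ordered PDO, Injury, Fatal.
#' @param labels Integer vector in `{1, 2, 3}`.
#' @return A tibble of class `fev_roc` with one row per class: `class`,
#'   `auc`, `n_pos`, `n_neg`, and a `curve` list-column of tibbles
#'   `(threshold, fpr, tpr)`.
#' @export
ovr_roc_auc <- function(scores, labels) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 3L) stop_schema("`scores` must have 3 columns.")
  labels <- as.integer(labels)
  if (length(labels) != nrow(scores)) {
    stop_schema("`labels` length must match the rows of `scores`.")
  }
  if (!all(labels %in% 1:3)) stop_validation("Labels must lie in {1, 2, 3}.")

  rows <- lapply(1:3, function(j) {
    pos <- labels == j
    n_pos <- sum(pos)
    n_neg <- sum(!pos)
    if (n_pos == 0L || n_neg == 0L) {
      stop_validation(sprintf(
        "Class %s has no %s examples; its one-vs-rest ROC is undefined.",
        severity_labels()[j], if (n_pos == 0L) "positive" else "negative"
      ))
    }
    s <- scores[, j]
    curve <- roc_sweep(s, pos)
    auc <- trapezoid_auc(curve$fpr, curve$tpr)
    tibble(
      class = severity_labels()[j], auc = auc,
      n_pos = n_pos, n_neg = n_neg, curve = list(curve)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("fev_roc", class(out))
  out
}

# Threshold sweep with tied scores grouped: one (FPR, TPR) point per unique
# score value, descending, prefixed by (0, 0).
roc_sweep <- function(scores, positive) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- positive[ord]
  uniq_last <- !duplicated(s, fromLast = TRUE)
  tp <- cumsum(p)[uniq_last]
  fp <- cumsum(!p)[uniq_last]
  tibble(
    threshold = c(Inf, s[uniq_last]),
    fpr = c(0, fp / sum(!positive)),
    tpr = c(0, tp / sum(positive))
  )
}

trapezoid_auc <- function(fpr, tpr) {
  sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
}

#' ROC curve plot
#'
#' @param object An [ovr_roc_auc()] result.
#' @param ... Unused.
#' @return A ggplot of the three one-vs-rest ROC curves with AUCs in the
#'   legend.
#' @export
autoplot.fev_roc <- function(object, ...) {
  curves <- tidyr::unnest(
    dplyr::mutate(object,
                  label = sprintf("%s (AUC %.3f)", .data$class, .data$auc)),
    "curve"
  )
  ggplot2::ggplot(curves, ggplot2::aes(.data$fpr, .data$tpr,
                                       colour = .data$label)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = NULL)
}

#' Train-to-test AUC degradation
#'
#' Per-class \eqn{\Delta AUC = AUC_{train} - AUC_{test}} and the arithmetic
#' mean over the three classes; the summary of overfitting used to compare
#' the ordered-logit and SVM models.
#'
#' @param train_aucs,test_aucs Length-3 numeric vectors in `[0, 1]`, ordered
#'   PDO, Injury, Fatal.
#' @return A tibble with rows PDO, Injury, Fatal and `mean`; `delta_auc`
#'   holds the exact differences (round to 3 decimals for reporting).
#' @examples
#' generalization_gap(c(0.763, 0.745, 0.817), c(0.729, 0.740, 0.721))
#' @export
generalization_gap <- function(train_aucs, test_aucs) {
  for (v in list(train_aucs, test_aucs)) {
    if (length(v) != 3L || any(v < 0 | v > 1)) {
      stop_parameter("AUC vectors must have length 3 with entries in [0, 1].")
    }
  }
  delta <- train_aucs - test_aucs
  tibble(
    class = c(severity_labels(), "mean"),
    train_auc = c(train_aucs, mean(train_aucs)),
    test_auc = c(test_aucs, mean(test_aucs)),
    delta_auc = c(delta, mean(delta))
  )
}

default_macro_auc_metric <- function(scores, labels) {
  mean(ovr_roc_auc(scores, labels)$auc)
}

#' Permutation feature importance
#'
#' For each feature, shuffles the column within the data `repeats` times and
#' reports the mean and standard deviation of the resulting drop in the
#' evaluation metric (default: macro one-vs-rest AUC of the model's
#' scores).
#'
#' @param predict_fn Function taking a feature matrix and returning an
#'   n-by-3 score matrix.
#' @param X Feature matrix (columns named).
#' @param labels Integer outcome vector in `{1, 2, 3}`.
#' @param features Columns to assess (default: all).
#' @param metric Function `(scores, labels) -> scalar`; defaults to macro
#'   one-vs-rest AUC.
#' @param repeats Number of shuffles per feature (default 20).
#' @param seed Integer seed.
#' @return A tibble with `feature`, `mean_drop`, `sd_drop`, `base_metric`.
#' @export
permutation_importance <- function(predict_fn, X, labels, features = NULL,
                                   metric = default_macro_auc_metric,
                                   repeats = 20L, seed = 1L) {
  repeats <- as.integer(repeats)
  if (repeats < 1L) stop_parameter("`repeats` must be at least 1.")
  X <- as.matrix(X)
  if (is.null(features)) features <- colnames(X)
  check_columns_present(as.data.frame(X), features, "feature")
  base <- metric(predict_fn(X), labels)
  if (!is.finite(base)) stop_validation("Metric is undefined on this split.")

  seeds <- seed_substreams(seed, length(features))
  rows <- purrr::map2(features, seeds, function(f, s) {
    drops <- withr::with_seed(s, {
      vapply(seq_len(repeats), function(r) {
        Xp <- X
        Xp[, f] <- Xp[sample.int(nrow(X)), f]
        base - metric(predict_fn(Xp), labels)
      }, numeric(1))
    })
    tibble(feature = f, mean_drop = mean(drops),
           sd_drop = if (repeats > 1L) sd(drops) else NA_real_,
           base_metric = base)
  })
  dplyr::bind_rows(rows)
}

#' Partial dependence of model output on one feature
#'
#' Clamps the feature at each grid value for every row and averages the
#' model's per-class predictions; for a binary indicator the grid defaults
#' to `c(0, 1)`.
#'
#' @param predict_fn Function taking a feature matrix and returning an
#'   n-by-3 matrix of scores or probabilities.
#' @param X Feature matrix (columns named).
#' @param feature Feature to vary.
#' @param grid Grid values (default: sorted unique values of the feature).
#' @return A tibble with `value`, `class`, `average_prediction`.
#' @export
partial_dependence <- function(predict_fn, X, feature, grid = NULL) {
  X <- as.matrix(X)
  check_columns_present(as.data.frame(X), feature, "feature")
  if (is.null(grid)) grid <- sort(unique(X[, feature]))
  if (length(grid) == 0L) stop_parameter("`grid` must be non-empty.")
  rows <- lapply(grid, function(g) {
    Xg <- X
    Xg[, feature] <- g
    avg <- colMeans(predict_fn(Xg))
    tibble(value = g, class = severity_labels(),
           average_prediction = as.numeric(avg))
  })
  dplyr::bind_rows(rows)
}

#' Combined train/test evaluation report for two models
#'
#' Runs [ovr_roc_auc()] on both splits for each named score set and stacks
#' the per-class AUCs with their generalization gaps.
#'
#' @param score_sets Named list; each element is a list with elements
#'   `train` and `test`, each an n-by-3 score matrix.
#' @param train_labels,test_labels Integer outcome vectors.
#' @return A tibble with `model`, `class`, `train_auc`, `test_auc`,
#'   `delta_auc` (classes plus a `mean` row per model).
#' @export
evaluation_report <- function(score_sets, train_labels, test_labels) {
  rows <- lapply(names(score_sets), function(nm) {
    tr <- ovr_roc_auc(score_sets[[nm]]$train, train_labels)
    te <- ovr_roc_auc(score_sets[[nm]]$test, test_labels)
    gap <- generalization_gap(tr$auc, te$auc)
    gap$model <- nm
    gap
  })
  dplyr::relocate(dplyr::bind_rows(rows), "model")
}
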
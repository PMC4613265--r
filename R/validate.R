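#' Stratified random split
#'
#' Holds out `round(fraction * n_class)` samples per class (at least one,
#' with a warning if rounding would give zero), drawn uniformly at random
#' within class.
#'
#' @param labels 0/1 vector.
#' @param fraction Held-out fraction, in (0, 1).
#' @param seed Optional integer seed (draws from the current RNG stream if
#'   `NULL`).
#' @return List with integer index vectors `holdout` and `rest`.
#' @export
stratified_split <- function(labels, fraction, seed = NULL) {
  stopifnot(fraction > 0, fraction < 1)
  run <- function() {
    holdout <- integer(0)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      k <- round(fraction * length(idx))
      if (k == 0) {
        warning("class ", cl, " would get 0 held-out members; taking 1")
        k <- 1
      }
      holdout <- c(holdout, sample(idx, k))
    }
    holdout <- sort(holdout)
    list(holdout = holdout, rest = setdiff(seq_along(labels), holdout))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Stratified k-fold assignment (used by the selection module's CV).
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Receiver operating characteristic curve
#'
#' Threshold sweep with the convention "positive = score > threshold".
#' Threshold values are the midpoints between consecutive distinct scores
#' (with infinite end points), so the operating points are exactly the
#' observed ones but a selected cutoff sits centrally in the score gap it
#' splits. The curve starts at (0, 0) and ends at (1, 1); no
#' interpolation is applied.
#'
#' @param scores Numeric classifier scores (higher = more case-like).
#' @param labels 0/1 vector with both classes present.
#' @return A `roc_curve` object: data.frame with `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("roc_curve needs both classes in labels")
  }
  stopifnot(length(scores) == length(labels))
  u <- sort(unique(scores), decreasing = TRUE)
  thr <- c(Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, -Inf)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  tpr <- vapply(thr, function(t) sum(scores > t & labels == 1) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(scores > t & labels == 0) / n_neg, 0)
  structure(data.frame(threshold = thr, fpr = fpr, tpr = tpr),
            class = c("roc_curve", "data.frame"))
}

#' Area under the ROC curve
#'
#' Trapezoidal area; ties in the scores produce diagonal segments, so a
#' degenerate single-valued score yields 0.5.
#'
#' @param r A [roc_curve()].
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(r) {
  sum(diff(r$fpr) * (r$tpr[-1] + r$tpr[-length(r$tpr)]) / 2)
}

#' Sensitivity at a false-positive-rate cap
#'
#' Maximum true-positive rate over curve points with `fpr <= fpr_cap`
#' (step-function reading, no interpolation). This is the screening
#' metric "sensitivity at 10% FPR".
#'
#' @param r A [roc_curve()].
#' @param fpr_cap FPR bound (default 0.10).
#' @return Sensitivity in `[0, 1]`.
#' @export
sensitivity_at_fpr <- function(r, fpr_cap = 0.10) {
  max(r$tpr[r$fpr <= fpr_cap])
}

#' Best (Youden) cutoff of a ROC curve
#'
#' The threshold maximizing `tpr - fpr`; ties are broken toward the higher
#' threshold.
#'
#' @param r A [roc_curve()].
#' @return Threshold value (classify positive when score > threshold).
#' @export
best_cutoff <- function(r) {
  j <- r$tpr - r$fpr
  max(r$threshold[j == max(j)])
}

confusion_rates <- function(scores, labels, threshold) {
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & labels == 1); fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0); fp <- sum(pred == 1 & labels == 0)
  c(accuracy = (tp + tn) / length(labels),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

# Mean inner-loop misclassification per component count. For each of
# n_inner stratified calibration/test splits a PLS path model is fitted on
# the calibration block and the test block is scored for every component
# count at the test-ROC best cutoff.
inner_component_search <- function(X, y, A_max, n_inner, inner_fraction) {
  A_fit <- min(A_max, sum(y == 1) + sum(y == 0) - 1, ncol(X),
               length(y) - 1)
  err <- matrix(NA_real_, n_inner, A_fit)
  for (r in seq_len(n_inner)) {
    for (try in 1:20) {
      sp <- stratified_split(y, inner_fraction)
      if (length(unique(y[sp$holdout])) == 2 &&
          length(unique(y[sp$rest])) == 2) break
      if (try == 20) stop("could not draw a two-class inner split")
    }
    m <- pls_fit(X[sp$rest, , drop = FALSE], y[sp$rest],
                 min(A_fit, length(sp$rest) - 1))
    pred <- pls_predict_path(m, X[sp$holdout, , drop = FALSE])
    for (a in seq_len(m$n_components)) {
      rc <- roc_curve(pred[, a], y[sp$holdout])
      cut <- best_cutoff(rc)
      err[r, a] <- 1 - confusion_rates(pred[, a], y[sp$holdout],
                                       cut)[["accuracy"]]
    }
  }
  colMeans(err, na.rm = TRUE)
}

#' Stratified double cross-validation of a PLS-DA model
#'
#' Per outer repetition, a stratified 20% block is held out for validation;
#' on the remainder, `n_inner` stratified calibration/test splits choose
#' the latent-variable count minimizing mean inner misclassification (at
#' the inner-ROC best cutoff; ties toward fewer components). The model is
#' refitted on the full remainder with the chosen count, the decision
#' threshold is the Youden cutoff of the remainder's fitted scores, and the
#' held-out block is scored. Reported metrics are per-repetition and mean
#' accuracy/sensitivity/specificity, plus a pooled-score ROC with AUC and
#' sensitivity at 10% FPR. All centering, component choice and thresholds
#' derive from the training remainder only.
#'
#' @param X Preprocessed predictor matrix.
#' @param y 0/1 outcome labels.
#' @param A_max Maximum latent variables considered (default 10).
#' @param outer_fraction Held-out fraction per repetition (default 0.2).
#' @param n_outer,n_inner Outer and inner repetition counts (default 20
#'   each).
#' @param inner_fraction Inner test fraction (default 0.2).
#' @param fpr_cap FPR cap for the pooled sensitivity metric (default 0.10).
#' @param seed Integer seed; the full report is reproducible given the
#'   seed.
#' @return A `validation_report`: list with `per_repetition` (data.frame),
#'   `mean_accuracy`, `mean_sensitivity`, `mean_specificity`,
#'   `pooled_scores`, `pooled_labels`, `roc`, `auc`, `sens_at_fpr`,
#'   `chosen_components`, `mean_error`, `seed`.
#' @export
double_cv <- function(X, y, A_max = 10, outer_fraction = 0.2,
                      n_outer = 20, n_inner = 20, inner_fraction = 0.2,
                      fpr_cap = 0.10, seed = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(A_max >= 1, length(y) == nrow(X))
  if (length(unique(y)) < 2) stop("both classes must be present")
  run <- function() {
    per_rep <- matrix(NA_real_, n_outer, 3,
                      dimnames = list(NULL, c("accuracy", "sensitivity",
                                              "specificity")))
    chosen <- integer(n_outer)
    pooled_scores <- numeric(0)
    pooled_labels <- integer(0)
    for (r in seq_len(n_outer)) {
      sp <- stratified_split(y, outer_fraction)
      X_rest <- X[sp$rest, , drop = FALSE]
      y_rest <- y[sp$rest]
      err_by_A <- inner_component_search(X_rest, y_rest, A_max, n_inner,
                                         inner_fraction)
      A_star <- which.min(err_by_A)  # ties -> smaller A
      m <- pls_fit(X_rest, y_rest, A_star)
      cut <- best_cutoff(roc_curve(m$fitted, y_rest))
      val_scores <- pls_predict(m, X[sp$holdout, , drop = FALSE])
      per_rep[r, ] <- confusion_rates(val_scores, y[sp$holdout], cut)
      chosen[r] <- m$n_components
      pooled_scores <- c(pooled_scores, val_scores)
      pooled_labels <- c(pooled_labels, y[sp$holdout])
    }
    rc <- roc_curve(pooled_scores, pooled_labels)
    structure(list(per_repetition = as.data.frame(per_rep),
                   mean_accuracy = mean(per_rep[, "accuracy"]),
                   mean_sensitivity = mean(per_rep[, "sensitivity"],
                                           na.rm = TRUE),
                   mean_specificity = mean(per_rep[, "specificity"],
                                           na.rm = TRUE),
                   pooled_scores = pooled_scores,
                   pooled_labels = pooled_labels,
                   roc = rc, auc = auc(rc),
                   sens_at_fpr = sensitivity_at_fpr(rc, fpr_cap),
                   chosen_components = chosen,
                   mean_error = 1 - mean(per_rep[, "accuracy"]),
                   seed = seed),
              class = "validation_report")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(paste0("Double cross-validation (%d outer repetitions)\n",
                     "  mean accuracy    %.1f%%\n",
                     "  mean sensitivity %.1f%%\n",
                     "  mean specificity %.1f%%\n",
                     "  pooled AUC       %.3f\n",
                     "  sensitivity at 10%% FPR %.1f%%\n"),
              nrow(x$per_repetition), 100 * x$mean_accuracy,
              100 * x$mean_sensitivity, 100 * x$mean_specificity,
              x$auc, 100 * x$sens_at_fpr))
  if (!is.null(x$permutation_p)) {
    cat(sprintf("  permutation p    %.4f\n", x$permutation_p))
  }
  invisible(x)
}

#' Permutation test of a modelling procedure
#'
#' Re-runs the full modelling procedure on label-reshuffled data `n_perm`
#' times and compares the observed mean classification error with the null
#' distribution: `p = (1 + #{permuted error <= observed}) / (n_perm + 1)`.
#'
#' @param procedure Function `(X, y) -> numeric mean error` implementing
#'   the complete pipeline under test (selection and/or double CV).
#' @param X,y Data and 0/1 labels.
#' @param n_perm Number of permutations (default 100).
#' @param seed Integer seed.
#' @return List with `p_value`, `observed_error`, `null_errors`,
#'   `n_failed` (permutations redrawn after a procedure failure).
#' @export
permutation_test <- function(procedure, X, y, n_perm = 100, seed = NULL) {
  stopifnot(n_perm >= 1)
  run <- function() {
    observed <- procedure(X, y)
    null_errors <- numeric(n_perm)
    n_failed <- 0L
    for (b in seq_len(n_perm)) {
      repeat {
        e <- tryCatch(procedure(X, sample(y)), error = function(err) NULL)
        if (!is.null(e)) break
        n_failed <- n_failed + 1L
        if (n_failed > 10 * n_perm) stop("too many permutation failures")
      }
      null_errors[b] <- e
    }
    list(p_value = (1 + sum(null_errors <= observed)) / (n_perm + 1),
         observed_error = observed, null_errors = null_errors,
         n_failed = n_failed)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
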
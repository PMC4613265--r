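#' CARS exponential retention schedule
#'
#' The retained-variable fraction at iteration `i` is `a exp(-k i)` with
#' `a` and `k` fixed so that `r_1 = 1` (all variables) and
#' `r_n_mc = 2/p` (two variables); retained counts are `ceiling(r_i * p)`.
#'
#' @param p Number of variables.
#' @param n_mc Number of Monte-Carlo iterations.
#' @return Numeric vector of retained fractions, length `n_mc`.
#' @export
cars_schedule <- function(p, n_mc) {
  r <- exp(seq(0, log(2 / p), length.out = n_mc))
  r[1] <- 1
  r[n_mc] <- 2 / p  # pin the anchors against rounding in exp(log(.))
  r
}

# Cross-validated RMSE (on 0/1-coded y) and misclassification error for
# each component count 1..A_max, using stratified k-fold CV.
cv_component_errors <- function(X, y, folds, A_max) {
  n <- nrow(X)
  A_max <- min(A_max, n - ceiling(n / folds) - 1, ncol(X))
  A_max <- max(A_max, 1)
  fold <- stratified_folds(y, folds)
  pred <- matrix(NA_real_, n, A_max)
  for (f in seq_len(folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    if (length(unique(y[tr])) < 2) next
    m <- pls_fit(X[tr, , drop = FALSE], y[tr],
                 min(A_max, length(tr) - 1))
    pred[te, seq_len(m$n_components)] <-
      pls_predict_path(m, X[te, , drop = FALSE])[, seq_len(m$n_components)]
  }
  rmse <- apply(pred, 2, function(p) {
    ok <- !is.na(p)
    sqrt(mean((y[ok] - p[ok])^2))
  })
  misclass <- apply(pred, 2, function(p) {
    ok <- !is.na(p)
    mean((p[ok] > 0.5) != (y[ok] == 1))
  })
  list(rmse = rmse, misclass = misclass)
}

new_selection_result <- function(method, selected, n_retained_trace,
                                 error_trace, seed, extra = list()) {
  structure(c(list(method = method, selected = sort(selected),
                   n_retained_trace = n_retained_trace,
                   error_trace = error_trace, seed = seed), extra),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("%s selection: %d variables retained\n", x$method,
              length(x$selected)))
  invisible(x)
}

#' VIP-filter variable selection
#'
#' Fits a PLS-DA model whose component count minimizes k-fold
#' cross-validated misclassification, then retains the variables with
#' VIP above the threshold (conventionally 1).
#'
#' @param X Preprocessed predictor matrix.
#' @param y 0/1 labels.
#' @param folds Cross-validation folds (default 5).
#' @param threshold VIP threshold (default 1).
#' @param A_max Largest component count searched (default 10).
#' @param seed Integer seed (fold assignment is random).
#' @return A `selection_result` with the retained variable indices, the
#'   VIP scores (`vip`), and the chosen component count (`A`).
#' @export
vip_select <- function(X, y, folds = 5, threshold = 1, A_max = 10,
                       seed = NULL) {
  stopifnot(folds >= 2)
  X <- as.matrix(X); y <- as.integer(y)
  run <- function() {
    errs <- cv_component_errors(X, y, folds, A_max)
    A_star <- which.min(errs$misclass)
    m <- pls_fit(X, y, A_star)
    v <- vip(m)
    # ties at the threshold are retained (symmetric-copy designs put the
    # whole signal exactly at VIP = 1)
    sel <- which(v >= threshold)
    if (!length(sel)) {
      stop("no variable exceeds the VIP threshold ", threshold)
    }
    new_selection_result("VIP", sel,
                         n_retained_trace = length(sel),
                         error_trace = errs$misclass[A_star], seed,
                         extra = list(vip = v, A = A_star))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Competitive adaptive reweighted sampling (CARS)
#'
#' Monte-Carlo variable selection for PLS regression on 0/1-coded labels.
#' At iteration `i` of `n_mc`: a PLS model is fitted on a random
#' `sample_fraction` subset of samples using the currently retained
#' variables; an exponentially decaying schedule
#' `r_i = a exp(-k i)` (anchored so that `r_1 = 1` and `r_n_mc = 2/p`)
#' forces retention of the top `ceil(r_i * p)` variables by absolute
#' regression coefficient; adaptive reweighted sampling then draws the
#' working set with probability proportional to those coefficients; and
#' the retained set's k-fold cross-validated RMSE is recorded. The final
#' selection is the retained set at the minimum-RMSE iteration (ties ->
#' fewer variables).
#'
#' @param X Preprocessed predictor matrix.
#' @param y 0/1 labels.
#' @param n_mc Number of Monte-Carlo iterations (default 50).
#' @param folds Cross-validation folds (default 5).
#' @param sample_fraction Fraction of samples drawn per iteration
#'   (default 0.8).
#' @param A_max Largest component count, chosen per iteration by the same
#'   cross-validation (default 10).
#' @param seed Integer seed; results are bit-reproducible given the seed.
#' @return A `selection_result` with `selected`, per-iteration
#'   `n_retained_trace` and `error_trace` (cross-validated RMSE), and the
#'   iteration chosen (`best_iteration`).
#' @export
cars_select <- function(X, y, n_mc = 50, folds = 5, sample_fraction = 0.8,
                        A_max = 10, seed = NULL) {
  stopifnot(n_mc >= 2, sample_fraction > 0, sample_fraction < 1,
            folds >= 2)
  X <- as.matrix(X); y <- as.integer(y)
  n <- nrow(X); p <- ncol(X)
  r <- cars_schedule(p, n_mc)
  run <- function() {
    retained <- seq_len(p)
    sets <- vector("list", n_mc)
    rmse <- rep(NA_real_, n_mc)
    n_retained <- rep(NA_integer_, n_mc)
    for (i in seq_len(n_mc)) {
      sub <- sort(sample(n, round(sample_fraction * n)))
      if (length(unique(y[sub])) < 2) next
      Xs <- X[sub, retained, drop = FALSE]
      errs <- cv_component_errors(Xs, y[sub], folds, A_max)
      A_i <- which.min(errs$rmse)
      m <- pls_fit(Xs, y[sub], A_i)
      b <- abs(m$coefficients)
      # enforced descent: keep the top ceil(r_i * p) by |coefficient|
      keep_n <- min(length(retained), ceiling(r[i] * p))
      keep <- retained[order(b, decreasing = TRUE)[seq_len(keep_n)]]
      w <- b[match(keep, retained)]
      # adaptive reweighted sampling: draw with probability ~ |coefficient|;
      # if the draw (or degenerate weights) would collapse the set below 2
      # variables, fall back to the enforced-selection set
      if (sum(w > 0) >= 2) {
        drawn <- sample(keep, size = keep_n, replace = TRUE, prob = w)
        if (length(unique(drawn)) >= 2) keep <- sort(unique(drawn))
      }
      retained <- keep
      if (length(retained) < 2) break
      cvr <- cv_component_errors(X[, retained, drop = FALSE], y, folds,
                                 A_max)
      rmse[i] <- min(cvr$rmse)
      n_retained[i] <- length(retained)
      sets[[i]] <- retained
    }
    done <- which(!is.na(rmse))
    if (!length(done)) stop("CARS failed: no evaluable iteration")
    # minimum RMSE; ties broken toward fewer variables
    best <- done[order(rmse[done], n_retained[done])][1]
    new_selection_result("CARS", sets[[best]],
                         n_retained_trace = n_retained,
                         error_trace = rmse, seed,
                         extra = list(best_iteration = best,
                                      schedule = r))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
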
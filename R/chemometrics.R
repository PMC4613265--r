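#' Principal component analysis by singular value decomposition
#'
#' Computes the first `A` components of a mean-centered matrix. The caller
#' is responsible for centering (and any scaling). Sign convention: within
#' each component the loading element of largest magnitude is positive.
#'
#' @param X Numeric matrix, samples in rows (mean-centered).
#' @param A Number of components; must not exceed the numerical rank of
#'   `X` (nor `min(n - 1, p)`).
#' @return A `pca_model`: list with `scores` (n x A), `loadings` (p x A),
#'   `explained` (fraction of variance per component).
#' @export
pca_fit <- function(X, A) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (A < 1 || A > min(n - 1, p)) {
    stop("A must be between 1 and min(n - 1, p) = ", min(n - 1, p))
  }
  sv <- svd(X)
  rank <- sum(sv$d > max(n, p) * .Machine$double.eps * sv$d[1])
  if (A > rank) {
    stop("A = ", A, " exceeds the numerical rank ", rank, " of X")
  }
  loadings <- sv$v[, seq_len(A), drop = FALSE]
  scores <- sv$u[, seq_len(A), drop = FALSE] %*%
    diag(sv$d[seq_len(A)], A, A)
  # sign convention: dominant loading element positive
  for (a in seq_len(A)) {
    s <- sign(loadings[which.max(abs(loadings[, a])), a])
    if (s < 0) {
      loadings[, a] <- -loadings[, a]
      scores[, a] <- -scores[, a]
    }
  }
  structure(list(scores = scores, loadings = loadings,
                 explained = sv$d^2 / sum(sv$d^2), n_components = A),
            class = "pca_model")
}

#' Fit a PLS1 discriminant model (NIPALS)
#'
#' Sequential latent-variable extraction for a single 0/1 response:
#' weights `w_a` proportional to the covariance of the deflated predictors
#' with the deflated response, unit-normalized; scores `t_a = X_a w_a`;
#' predictor and response deflation after each component. Predictors are
#' mean-centered internally (no scaling); the response is centered on
#' `y_mean`. Regression coefficients for direct prediction are assembled
#' as `W (P'W)^{-1} q`.
#'
#' @param X Numeric predictor matrix (n x p).
#' @param y Numeric or integer 0/1 class labels (both classes present).
#' @param A Number of latent variables, `1 <= A <= min(n - 1, p)`.
#' @return A `pls_model`: list with `weights` (p x A), `x_loadings`
#'   (p x A), `y_loadings` (length A), `scores` (n x A), `coefficients`
#'   (length p), `coef_path` (p x A, coefficients for models truncated at
#'   each component count), `n_components`, `y_mean`, `x_center`.
#' @export
pls_fit <- function(X, y, A) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  if (length(unique(y)) < 2) stop("both classes must be present in y")
  if (A < 1 || A > min(n - 1, p)) {
    stop("A must be between 1 and min(n - 1, p) = ", min(n - 1, p))
  }
  x_center <- colMeans(X)
  Xa <- sweep(X, 2, x_center)
  X0 <- Xa
  y_mean <- mean(y)
  ya <- y - y_mean
  W <- matrix(0, p, A); P <- matrix(0, p, A); Tm <- matrix(0, n, A)
  q <- numeric(A)
  a_done <- 0L
  for (a in seq_len(A)) {
    w <- crossprod(Xa, ya)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      warning("response variance exhausted after ", a_done,
              " components; A reduced")
      break
    }
    w <- w / nw
    t <- Xa %*% w
    tt <- sum(t^2)
    if (tt < 1e-12) {
      warning("degenerate score vector at component ", a, "; A reduced")
      break
    }
    pv <- crossprod(Xa, t) / tt
    qa <- sum(ya * t) / tt
    Xa <- Xa - tcrossprod(t, pv)
    ya <- ya - qa * t
    W[, a] <- w; P[, a] <- pv; Tm[, a] <- t; q[a] <- qa
    a_done <- a
  }
  if (a_done == 0L) stop("no PLS component could be extracted")
  W <- W[, seq_len(a_done), drop = FALSE]
  P <- P[, seq_len(a_done), drop = FALSE]
  Tm <- Tm[, seq_len(a_done), drop = FALSE]
  q <- q[seq_len(a_done)]
  # coefficient path: b_A' = W_(1:A') (P'W)^{-1}_(1:A') q_(1:A')
  coef_path <- matrix(0, p, a_done)
  PtW <- crossprod(P, W)
  for (a in seq_len(a_done)) {
    ia <- seq_len(a)
    coef_path[, a] <- W[, ia, drop = FALSE] %*%
      solve(PtW[ia, ia, drop = FALSE], q[ia])
  }
  structure(list(weights = W, x_loadings = P, y_loadings = q,
                 scores = Tm, coefficients = coef_path[, a_done],
                 coef_path = coef_path, n_components = a_done,
                 y_mean = y_mean, x_center = x_center,
                 fitted = as.numeric(y_mean + X0 %*% coef_path[, a_done])),
            class = "pls_model")
}

#' Predict continuous class scores from a PLS model
#'
#' `y_hat = y_mean + (X_new - x_center) b`. Training statistics are never
#' recomputed from the new data.
#'
#' @param m A `pls_model` from [pls_fit()].
#' @param X_new Matrix with the training number of columns.
#' @param A Optional smaller component count; defaults to the fitted one.
#' @return Numeric vector of continuous scores (around 0/1 class coding).
#' @export
pls_predict <- function(m, X_new, A = m$n_components) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(m$x_center)) {
    stop("X_new has ", ncol(X_new), " columns; model expects ",
         length(m$x_center))
  }
  stopifnot(A >= 1, A <= m$n_components)
  as.numeric(m$y_mean + sweep(X_new, 2, m$x_center) %*% m$coef_path[, A])
}

# Prediction matrix for all component counts 1..A (one column each);
# used by the cross-validation loops to score the whole path in one pass.
pls_predict_path <- function(m, X_new) {
  X_new <- as.matrix(X_new)
  m$y_mean + sweep(X_new, 2, m$x_center) %*% m$coef_path
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt( p * sum_a SS_a (w_ja / ||w_a||)^2 / sum_a SS_a )` where
#' `SS_a = q_a^2 t_a' t_a` is the response variance explained by component
#' `a`. Variables with VIP <= 1 are conventionally treated as irrelevant.
#'
#' @param m A `pls_model` from [pls_fit()].
#' @return Numeric vector of VIP scores, one per variable; satisfies
#'   `sum(VIP^2) = p`.
#' @export
vip <- function(m) {
  stopifnot(inherits(m, "pls_model"), m$n_components >= 1)
  p <- nrow(m$weights)
  ss <- m$y_loadings^2 * colSums(m$scores^2)
  w2 <- sweep(m$weights, 2, sqrt(colSums(m$weights^2)), "/")^2
  sqrt(p * as.numeric(w2 %*% ss) / sum(ss))
}
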
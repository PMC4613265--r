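#' Metabolite ratio from spectral integrals
#'
#' Ratio of curve areas over two ppm windows, per sample (e.g. the urinary
#' hippurate/creatinine ratio). Samples with a non-positive denominator
#' integral are set to `NA` with a warning.
#'
#' @param s A [spectrum_set()] (dilution-corrected, unscaled).
#' @param numerator,denominator Length-2 numeric `(lo, hi)` ppm windows.
#' @return Named numeric vector of ratios.
#' @export
#' @examples
#' # default windows: hippurate aromatic 7.45-7.90, creatinine 2.99-3.10
metabolite_ratio <- function(s, numerator, denominator) {
  num <- integrate_region(s, numerator[1], numerator[2])
  den <- integrate_region(s, denominator[1], denominator[2])
  bad <- den <= 0
  if (any(bad)) {
    warning("non-positive denominator integral; samples excluded: ",
            paste(s$sample_id[bad], collapse = ", "))
    den[bad] <- NA_real_
  }
  num / den
}

#' Default integration windows for the urinary risk ratio
#'
#' Hippurate aromatic multiplets 7.45-7.90 ppm; creatinine N-methyl
#' singlet 2.99-3.10 ppm. Conventional reference windows; the regions are
#' configurable wherever they are consumed.
#'
#' @return List with `hippurate` and `creatinine` `(lo, hi)` pairs.
#' @export
default_ratio_windows <- function() {
  list(hippurate = c(7.45, 7.90), creatinine = c(2.99, 3.10))
}

#' High-risk maternal age indicator
#'
#' Women younger than 20 or older than 35 years are categorized as high
#' risk (strict inequalities: exactly 20 or 35 is not high risk).
#'
#' @param age_years Numeric vector of ages.
#' @return Integer 0/1 vector.
#' @export
age_highrisk <- function(age_years) {
  as.integer(age_years > 35 | age_years < 20)
}

#' Maximum-likelihood logistic regression
#'
#' Binomial fit by iteratively reweighted least squares (via
#' [stats::glm()]), with a likelihood-ratio omnibus chi-square test
#' against the intercept-only model. Complete or quasi-separation
#' (diverging coefficients) and singular designs are rejected.
#'
#' @param X Design matrix or data.frame of predictors (no intercept
#'   column; one is added).
#' @param y 0/1 outcome with both classes present.
#' @return A `risk_model`: list with `coefficients` (including
#'   `(Intercept)`), `log_likelihood`, `null_log_likelihood`,
#'   `omnibus_chisq`, `omnibus_p`, `fitted`, and the underlying `glm`
#'   object.
#' @export
logistic_fit <- function(X, y) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) < 2) stop("outcome must contain both classes")
  if (nrow(X) <= ncol(X) + 1) stop("need n > number of predictors + 1")
  if (qr(cbind(1, X))$rank < ncol(X) + 1) {
    stop("singular design matrix")
  }
  df <- data.frame(y = y, X)
  saturated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., family = stats::binomial(), data = df,
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("numerically 0 or 1", conditionMessage(w))) {
        saturated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (!fit$converged) stop("IRLS did not converge")
  if (saturated) {
    # saturation alone can be an innocuous outlier; diverging coefficients
    # mean the fitted probabilities order the classes perfectly
    p_hat <- stats::fitted(fit)
    if (min(p_hat[y == 1]) > max(p_hat[y == 0])) {
      stop("complete or quasi-separation detected (diverging coefficients)")
    }
  }
  ll <- as.numeric(stats::logLik(fit))
  fit0 <- stats::glm(y ~ 1, family = stats::binomial(), data = df)
  ll0 <- as.numeric(stats::logLik(fit0))
  chisq <- 2 * (ll - ll0)
  structure(list(coefficients = stats::coef(fit),
                 log_likelihood = ll, null_log_likelihood = ll0,
                 omnibus_chisq = chisq,
                 omnibus_p = stats::pchisq(chisq, df = ncol(X),
                                           lower.tail = FALSE),
                 fitted = stats::fitted(fit), glm = fit),
            class = "risk_model")
}

#' Predicted probabilities from a risk model
#'
#' @param m A `risk_model` from [logistic_fit()].
#' @param X New design matrix with the training columns.
#' @return Probabilities in `(0, 1)`.
#' @export
risk_predict <- function(m, X) {
  X <- as.matrix(X)
  eta <- m$coefficients[1] + X %*% m$coefficients[-1]
  as.numeric(stats::plogis(eta))
}

# Hanley-McNeil normal-approximation standard error of an AUC.
auc_se_hanley <- function(a, n_pos, n_neg) {
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  sqrt((a * (1 - a) + (n_pos - 1) * (q1 - a^2) +
        (n_neg - 1) * (q2 - a^2)) / (n_pos * n_neg))
}

#' Apparent-performance report for a fitted risk model
#'
#' Computes the ROC of the fitted probabilities and reports the AUC with a
#' Hanley-McNeil 95% confidence interval, the sensitivity at the FPR cap,
#' and PPV/NPV at the corresponding operating threshold, together with the
#' omnibus p-value. This is in-sample (apparent) performance.
#'
#' @param m A `risk_model`.
#' @param X Design matrix used for the fit (or compatible new data).
#' @param y 0/1 outcome.
#' @param fpr_cap Operating false-positive-rate cap (default 0.10).
#' @return A `risk_report`: list with `auc`, `auc_ci`, `sensitivity`,
#'   `ppv`, `npv`, `omnibus_p`, `threshold`, `roc`.
#' @export
risk_report <- function(m, X, y, fpr_cap = 0.10) {
  y <- as.integer(y)
  prob <- risk_predict(m, X)
  rc <- roc_curve(prob, y)
  a <- auc(rc)
  se <- auc_se_hanley(a, sum(y == 1), sum(y == 0))
  sens <- sensitivity_at_fpr(rc, fpr_cap)
  # operating point: the lowest-threshold curve point with fpr <= cap
  # achieving that sensitivity
  ok <- rc$fpr <= fpr_cap & rc$tpr == sens
  thr <- min(rc$threshold[ok])
  pred <- as.integer(prob > thr)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  structure(list(auc = a,
                 auc_ci = c(max(0, a - 1.96 * se), min(1, a + 1.96 * se)),
                 sensitivity = sens,
                 ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
                 omnibus_p = m$omnibus_p, threshold = thr, roc = rc),
            class = "risk_report")
}

#' @export
print.risk_report <- function(x, ...) {
  cat(sprintf(paste0("AUC %.3f (95%% CI %.3f-%.3f)\n",
                     "sensitivity %.1f%% at the operating point, ",
                     "PPV %.3f, NPV %.3f\nomnibus p %.4g\n"),
              x$auc, x$auc_ci[1], x$auc_ci[2], 100 * x$sensitivity,
              x$ppv, x$npv, x$omnibus_p))
  invisible(x)
}
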
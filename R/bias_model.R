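# Bias-slope estimation and effect adjustment.
#
# The case-only log hazard ratio of a SNP decomposes approximately as
#   beta_GY' = beta_GY + b * beta_GX,
# so across many independent SNPs the bias slope b is the regression slope of
# survival effects on risk effects, and the adjusted effect of a target SNP is
#   beta_GY = beta_GY' - b * beta_GX.

new_slope_estimate <- function(fit, method, intercept_flag, n_snps,
                               correction_factor = 1) {
  # exact-fit inputs trigger summary.lm's perfect-fit warning; they are
  # legitimate here (the SE is simply 0-ish)
  cf <- coef(suppressWarnings(summary(fit)))
  b <- unname(cf["beta_gx", "Estimate"])
  se_b <- unname(cf["beta_gx", "Std. Error"])
  icpt <- if (intercept_flag) unname(coef(fit)[["(Intercept)"]]) else 0
  z <- qnorm(0.975)
  p <- 2 * pnorm(-abs(b / se_b))
  structure(list(
    b = b, se_b = se_b,
    ci_low = b - z * se_b, ci_high = b + z * se_b,
    pvalue = max(p, .Machine$double.xmin),
    intercept = icpt, method = method, n_snps = n_snps,
    correction_factor = correction_factor,
    with_intercept = intercept_flag,
    fit = fit
  ), class = "slope_estimate")
}

check_pairs_for_fit <- function(pairs) {
  need <- c("beta_gx", "beta_gy", "se_gy")
  miss <- setdiff(need, names(pairs))
  if (length(miss)) stop("pairs missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(pairs) < 3L) stop("need at least 3 SNPs to estimate the bias slope")
  if (sd(pairs$beta_gx) == 0)
    stop("degenerate design: all risk effects (beta_gx) are identical")
  if (any(pairs$se_gy <= 0)) stop("all se_gy must be strictly positive")
  invisible(pairs)
}

#' Estimate the bias slope by ordinary least squares
#'
#' Regresses case-only survival effects (log hazard ratios) on disease-risk
#' effects (log odds ratios) across independent SNPs. The slope estimates the
#' bias coefficient `b` in the adjustment
#' \eqn{\beta_{GY} \approx \beta_{GY'} - b\,\beta_{GX}}. Confidence interval
#' and p-value use the normal approximation on the slope's standard error,
#' appropriate for the large SNP panels this is designed for.
#'
#' @param pairs data.frame of harmonized pairs (see [harmonize()]).
#' @param intercept fit an intercept (default `TRUE`; robust to directional
#'   pleiotropy in the panel). `FALSE` forces the regression through the
#'   origin, matching the adjustment identity itself.
#' @return object of class `slope_estimate`: list with elements `b`, `se_b`,
#'   `ci_low`, `ci_high`, `pvalue`, `intercept`, `method`, `n_snps`,
#'   `correction_factor` (1 for ols/wls) and the underlying `lm` fit.
#' @export
#' @examples
#' pairs <- data.frame(beta_gx = c(0.1, 0.2, 0.3, 0.5),
#'                     se_gx = 0.01,
#'                     beta_gy = -0.025 * c(0.1, 0.2, 0.3, 0.5),
#'                     se_gy = 0.1)
#' fit_slope_ols(pairs)$b
fit_slope_ols <- function(pairs, intercept = TRUE) {
  check_pairs_for_fit(pairs)
  fml <- if (intercept) beta_gy ~ beta_gx else beta_gy ~ 0 + beta_gx
  fit <- lm(fml, data = pairs)
  new_slope_estimate(fit, "ols", intercept, nrow(pairs))
}

#' Estimate the bias slope by inverse-variance-weighted least squares
#'
#' As [fit_slope_ols()] but weighting each SNP by the reciprocal of the
#' squared standard error of its log hazard ratio, so imprecisely estimated
#' survival effects contribute less. This is the estimator of choice when the
#' unweighted regression's residual diagnostics look non-normal or
#' heteroscedastic.
#'
#' @inheritParams fit_slope_ols
#' @return `slope_estimate` with `method = "wls"`.
#' @export
fit_slope_wls <- function(pairs, intercept = TRUE) {
  check_pairs_for_fit(pairs)
  w <- 1 / pairs$se_gy^2
  df <- pairs
  df$.w <- w
  fml <- if (intercept) beta_gy ~ beta_gx else beta_gy ~ 0 + beta_gx
  fit <- lm(fml, data = df, weights = .w)
  new_slope_estimate(fit, "wls", intercept, nrow(pairs))
}

#' Correct the weighted slope for regression dilution (CWLS)
#'
#' Sampling error in the risk-effect estimates attenuates the regression
#' slope toward zero. The corrected weighted least squares (CWLS) estimator
#' rescales the WLS slope by the dilution factor
#' \deqn{\hat c = \frac{\sum_j w_j \hat\beta_{GX,j}^2}
#'                     {\sum_j w_j (\hat\beta_{GX,j}^2 - se_{GX,j}^2)},
#'       \quad w_j = 1/se_{GY,j}^2,}
#' the standard measurement-error correction: the denominator estimates the
#' weighted sum of squared *true* risk effects. The corrected slope is
#' \eqn{\hat c\, b_{wls}} with standard error \eqn{|\hat c|\, se(b_{wls})}
#' (uncertainty in \eqn{\hat c} itself is ignored; see the package vignette).
#'
#' @param wls a `slope_estimate` with `method = "wls"` from [fit_slope_wls()].
#' @param pairs the harmonized pairs the WLS fit used; must carry `se_gx`.
#' @return `slope_estimate` with `method = "cwls"` and `correction_factor`
#'   set to \eqn{\hat c}.
#' @export
cwls_correct <- function(wls, pairs) {
  if (!inherits(wls, "slope_estimate") || wls$method != "wls")
    stop("cwls_correct() requires a slope_estimate with method 'wls'")
  if (is.null(pairs$se_gx) || anyNA(pairs$se_gx))
    stop("pairs must carry se_gx for the dilution correction")
  if (nrow(pairs) != wls$n_snps)
    stop("pairs do not match the WLS fit (", nrow(pairs), " vs ",
         wls$n_snps, " SNPs)")
  w <- 1 / pairs$se_gy^2
  num <- sum(w * pairs$beta_gx^2)
  den <- sum(w * (pairs$beta_gx^2 - pairs$se_gx^2))
  if (den <= 0)
    stop("dilution correction undefined: weighted sum of (beta_gx^2 - se_gx^2) is ",
         signif(den, 4), " <= 0; measurement error dominates the risk-effect ",
         "signal, so no reliable slope can be recovered from this panel")
  chat <- num / den
  out <- wls
  out$b <- chat * wls$b
  out$se_b <- abs(chat) * wls$se_b
  z <- qnorm(0.975)
  out$ci_low <- out$b - z * out$se_b
  out$ci_high <- out$b + z * out$se_b
  out$pvalue <- wls$pvalue  # z-statistic is invariant to the rescaling
  out$method <- "cwls"
  out$correction_factor <- chat
  out
}

#' @export
print.slope_estimate <- function(x, ...) {
  cat(sprintf("Bias slope estimate (%s%s)\n", toupper(x$method),
              if (x$with_intercept) "" else ", through origin"))
  cat(sprintf("  b       = %.6g (SE %.3g)\n", x$b, x$se_b))
  cat(sprintf("  95%% CI  = [%.6g, %.6g]\n", x$ci_low, x$ci_high))
  cat(sprintf("  p       = %.3g\n", x$pvalue))
  if (x$with_intercept) cat(sprintf("  intercept = %.6g\n", x$intercept))
  if (x$method == "cwls")
    cat(sprintf("  dilution correction factor = %.6g\n", x$correction_factor))
  cat(sprintf("  n SNPs  = %d\n", x$n_snps))
  invisible(x)
}

#' Regression diagnostics for a fitted bias slope
#'
#' Computes the quantities behind the two standard assumption checks for the
#' slope regression: a normal quantile-quantile plot of internally studentized
#' residuals (normality) and a scale-location plot (homogeneity of variance).
#' Residuals are studentized as \eqn{r_i / (\hat\sigma \sqrt{1 - h_{ii}})}
#' using the same weights as the fit; theoretical quantiles use plotting
#' positions \eqn{(i - 0.5)/n}. A perfect fit yields all-zero studentized
#' residuals.
#'
#' @param pairs the harmonized pairs the slope was fitted on.
#' @param slope a `slope_estimate` fitted on `pairs`.
#' @return object of class `diagnostics_bundle`: list with `fitted`,
#'   `std_residuals`, `qq_theoretical` (sorted standard-normal quantiles),
#'   `qq_sample` (sorted studentized residuals) and
#'   `sqrt_abs_std_residuals`.
#' @export
regression_diagnostics <- function(pairs, slope) {
  if (!inherits(slope, "slope_estimate")) stop("slope must be a slope_estimate")
  n <- slope$n_snps
  if (n < 4L) stop("diagnostics require at least 4 SNPs")
  if (nrow(pairs) != n) stop("pairs do not match the fitted slope")
  fit <- slope$fit
  w <- weights(fit) %||% rep(1, n)
  r <- residuals(fit) * sqrt(w)        # weighted residuals
  h <- hatvalues(fit)
  sigma <- sqrt(sum(r^2) / fit$df.residual)
  # an exact fit leaves only floating-point rounding in the residuals; treat
  # sigma as zero when it is negligible against the response scale
  y_scale <- sqrt(mean(w * pairs$beta_gy^2))
  std <- if (sigma > 1e-8 * max(y_scale, .Machine$double.xmin))
    r / (sigma * sqrt(pmax(1 - h, .Machine$double.eps)))
  else rep(0, n)
  structure(list(
    fitted = unname(fitted(fit)),
    std_residuals = unname(std),
    qq_theoretical = qnorm((seq_len(n) - 0.5) / n),
    qq_sample = sort(unname(std)),
    sqrt_abs_std_residuals = sqrt(abs(unname(std)))
  ), class = "diagnostics_bundle")
}

#' @export
print.diagnostics_bundle <- function(x, ...) {
  cat("Regression diagnostics (", length(x$fitted), " SNPs)\n", sep = "")
  cat("  studentized residuals: ",
      sprintf("min %.3g / median %.3g / max %.3g\n",
              min(x$std_residuals), stats::median(x$std_residuals),
              max(x$std_residuals)))
  invisible(x)
}

#' Plot diagnostics: normal QQ and scale-location panels
#'
#' @param x a `diagnostics_bundle`.
#' @param which `"qq"`, `"scale_location"` or `"both"` (default).
#' @param ... passed to [plot()].
#' @export
plot.diagnostics_bundle <- function(x, which = c("both", "qq", "scale_location"),
                                    ...) {
  which <- match.arg(which)
  if (which == "both") {
    op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  }
  if (which %in% c("both", "qq")) {
    plot(x$qq_theoretical, x$qq_sample, xlab = "Theoretical quantiles",
         ylab = "Studentized residuals", main = "Normal Q-Q", ...)
    graphics::abline(0, 1, col = 2)
  }
  if (which %in% c("both", "scale_location")) {
    plot(x$fitted, x$sqrt_abs_std_residuals, xlab = "Fitted values",
         ylab = expression(sqrt(abs("std. residuals"))),
         main = "Scale-Location", ...)
    graphics::lines(stats::lowess(x$fitted, x$sqrt_abs_std_residuals), col = 2)
  }
  invisible(x)
}

#' Adjust a target SNP's survival effect for index event bias
#'
#' Applies \eqn{\beta_{GY} = \beta_{GY'} - b\,\beta_{GX}} with a fitted bias
#' slope and propagates uncertainty by the delta method,
#' \deqn{se_{adj}^2 = se_{GY'}^2 + b^2 se_{GX}^2 + \beta_{GX}^2 se_b^2,}
#' ignoring covariances (the target SNP's leverage on the genome-wide slope
#' estimate is negligible). Results are reported on the hazard-ratio scale
#' with a normal-approximation 95\% CI.
#'
#' @param beta_gy_prime observed case-only log hazard ratio of the target SNP.
#' @param se_gy_prime its standard error (> 0).
#' @param beta_gx the SNP's log odds ratio on disease risk.
#' @param se_gx its standard error (> 0).
#' @param slope a fitted `slope_estimate`.
#' @return object of class `adjusted_effect`: list with `beta_adj`, `se_adj`,
#'   `hr_adj`, `ci_low_hr`, `ci_high_hr`.
#' @export
#' @examples
#' sl <- structure(list(b = -0.025, se_b = 0.003), class = "slope_estimate")
#' adjust_effect(log(0.766), 0.096, log(5.64), 0.089, sl)
adjust_effect <- function(beta_gy_prime, se_gy_prime, beta_gx, se_gx, slope) {
  stopifnot(se_gy_prime > 0, se_gx > 0, inherits(slope, "slope_estimate"))
  se_b <- slope$se_b %||% 0
  beta_adj <- beta_gy_prime - slope$b * beta_gx
  se_adj <- sqrt(se_gy_prime^2 + slope$b^2 * se_gx^2 + beta_gx^2 * se_b^2)
  z <- qnorm(0.975)
  structure(list(
    beta_adj = beta_adj,
    se_adj = se_adj,
    hr_adj = exp(beta_adj),
    ci_low_hr = exp(beta_adj - z * se_adj),
    ci_high_hr = exp(beta_adj + z * se_adj)
  ), class = "adjusted_effect")
}

#' @export
print.adjusted_effect <- function(x, ...) {
  cat(sprintf("Adjusted log HR = %.4g (SE %.3g)\n", x$beta_adj, x$se_adj))
  cat(sprintf("Adjusted HR     = %.4g (95%% CI %.4g to %.4g)\n",
              x$hr_adj, x$ci_low_hr, x$ci_high_hr))
  invisible(x)
}
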
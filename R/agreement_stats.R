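#' Bivariate moment summary of paired scores
#'
#' All agreement indices in the suite derive from the first two joint moments
#' of the paired scores.  Under the default `"n"` convention the variances
#' and covariance use the 1/n denominator of Lin's estimator (so the
#' concordance coefficient matches the printed formula exactly); the sample
#' 1/(n-1) convention is available for comparison.
#'
#' @param x,y numeric vectors of paired scores, index-aligned by subject.
#' @param denominator `"n"` (default, Lin's moment convention) or
#'   `"n_minus_1"`.
#' @return An object of class `moment_summary`: `n`, `x_bar`, `y_bar`,
#'   `sx2`, `sy2`, `sxy`, `sx`, `sy`, `u` (scale-free location shift
#'   `(x_bar - y_bar)/sqrt(sx*sy)`), `v` (scale ratio `sx/sy`), `mu_d`
#'   (mean difference), `sigma_d2` (variance of differences), `msd` (mean
#'   squared difference `mu_d^2 + sigma_d2`), `zero_variance` flag,
#'   `denominator`.
#' @examples
#' moment_summary(c(0, 1, 2), c(1, 2, 3))
#' @export
moment_summary <- function(x, y, denominator = c("n", "n_minus_1")) {
  denominator <- match.arg(denominator)
  check_pairs(x, y)
  n <- length(x)
  div <- if (denominator == "n") n else n - 1L
  x_bar <- mean(x)
  y_bar <- mean(y)
  sx2 <- sum((x - x_bar)^2) / div
  sy2 <- sum((y - y_bar)^2) / div
  sxy <- sum((x - x_bar) * (y - y_bar)) / div
  sx <- sqrt(sx2)
  sy <- sqrt(sy2)
  mu_d <- x_bar - y_bar
  sigma_d2 <- sx2 + sy2 - 2 * sxy
  zero_var <- (sx2 == 0 || sy2 == 0)
  structure(
    list(
      n = n, x_bar = x_bar, y_bar = y_bar,
      sx2 = sx2, sy2 = sy2, sxy = sxy, sx = sx, sy = sy,
      u = if (zero_var) NA_real_ else mu_d / sqrt(sx * sy),
      v = if (zero_var) NA_real_ else sx / sy,
      mu_d = mu_d, sigma_d2 = sigma_d2,
      msd = mu_d^2 + sigma_d2,
      zero_variance = zero_var,
      denominator = denominator
    ),
    class = "moment_summary"
  )
}

check_pairs <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) {
    ccq_validation_error("paired scores must be numeric")
  }
  if (length(x) != length(y)) {
    ccq_validation_error("paired score vectors differ in length")
  }
  if (anyNA(x) || anyNA(y)) {
    ccq_validation_error("paired scores contain missing values")
  }
  if (length(x) < 3L) {
    ccq_validation_error("insufficient data: need at least 3 pairs")
  }
  invisible(TRUE)
}

stop_if_degenerate <- function(ms, what) {
  if (ms$zero_variance) {
    ccq_validation_error(sprintf(
      "%s is undefined: a score series has zero variance", what))
  }
  invisible(TRUE)
}

z_crit <- function(conf, ci) {
  if (ci == "one-sided") qnorm(conf) else qnorm(1 - (1 - conf) / 2)
}

#' Lin's concordance correlation coefficient
#'
#' The concordance correlation coefficient (CCC) between paired measurements,
#' `rho_c = 2*sxy / (sx^2 + sy^2 + (x_bar - y_bar)^2)`, measuring how far the
#' pairs fall from the 45-degree line of perfect agreement.  The confidence
#' limit is computed on the inverse-hyperbolic-tangent (Fisher z) scale with
#' Lin's asymptotic variance (including the published erratum corrections)
#' and back-transformed.  Under the reporting convention of the suite the
#' default limit is one-sided in the unfavourable (lower) direction.
#'
#' @inheritParams moment_summary
#' @param conf confidence level (default 0.95).
#' @param ci `"one-sided"` (default, lower limit only) or `"two-sided"`.
#' @return List with `estimate`, `lower`, `upper` (`NA` for one-sided),
#'   `se_z`, `n`, `conf`, `ci`.
#' @examples
#' ccc(c(0, 1, 2), c(1, 2, 3))$estimate   # 4/7
#' @export
ccc <- function(x, y, conf = 0.95, ci = c("one-sided", "two-sided"),
                denominator = c("n", "n_minus_1")) {
  ci <- match.arg(ci)
  denominator <- match.arg(denominator)
  ms <- moment_summary(x, y, denominator)
  stop_if_degenerate(ms, "CCC")
  est <- 2 * ms$sxy / (ms$sx2 + ms$sy2 + ms$mu_d^2)
  rho <- ms$sxy / (ms$sx * ms$sy)
  n <- ms$n
  if (abs(est) >= 1 - 1e-12 || abs(rho) < 1e-12) {
    # perfect agreement / reversal (zero-width limit) or zero correlation
    # (Lin's variance undefined); report a degenerate limit at the estimate
    se_z <- 0
    lo <- hi <- est
  } else {
    u <- ms$u
    s2z <- ((1 - rho^2) * est^2 / ((1 - est^2) * rho^2) +
              2 * est^3 * (1 - est) * u^2 / (rho * (1 - est^2)^2) -
              est^4 * u^4 / (2 * rho^2 * (1 - est^2)^2)) / (n - 2)
    se_z <- sqrt(max(s2z, 0))
    zc <- z_crit(conf, ci)
    lo <- tanh(atanh(est) - zc * se_z)
    hi <- tanh(atanh(est) + zc * se_z)
  }
  list(estimate = est, lower = lo,
       upper = if (ci == "two-sided") hi else NA_real_,
       se_z = se_z, n = n, conf = conf, ci = ci)
}

#' Precision and accuracy components of the CCC
#'
#' Decomposes the concordance correlation coefficient as
#' `rho_c = rho * C_b`: `rho` (precision) is the Pearson correlation, how
#' tightly the pairs cluster around the best-fit line, and `C_b` (accuracy)
#' is the bias-correction factor `2/(v + 1/v + u^2)` penalizing location
#' (`u`) and scale (`v`) shifts away from the identity line.
#'
#' The precision limit uses the classical Fisher-z transform
#' (variance `1/(n-3)`); the accuracy limit uses a normal-theory delta
#' method on the logit scale (gradient of `C_b` with respect to the five
#' moment estimators, with their asymptotic covariance under bivariate
#' normality).
#'
#' @inheritParams ccc
#' @return List with `precision`, `precision_lower`, `accuracy`,
#'   `accuracy_lower`, upper counterparts for two-sided intervals, and `n`.
#' @export
precision_accuracy <- function(x, y, conf = 0.95,
                               ci = c("one-sided", "two-sided"),
                               denominator = c("n", "n_minus_1")) {
  ci <- match.arg(ci)
  denominator <- match.arg(denominator)
  ms <- moment_summary(x, y, denominator)
  stop_if_degenerate(ms, "precision/accuracy")
  rho <- ms$sxy / (ms$sx * ms$sy)
  cb <- 2 / (ms$v + 1 / ms$v + ms$u^2)
  n <- ms$n
  zc <- z_crit(conf, ci)

  if (abs(rho) >= 1 - 1e-12) {
    rho_lo <- rho_hi <- rho
  } else {
    se_zr <- 1 / sqrt(n - 3)
    rho_lo <- tanh(atanh(rho) - zc * se_zr)
    rho_hi <- tanh(atanh(rho) + zc * se_zr)
  }

  if (cb >= 1 - 1e-12) {
    cb_lo <- cb_hi <- cb
  } else {
    se_cb <- accuracy_se(ms)
    se_l <- se_cb / (cb * (1 - cb))
    l <- qlogis(cb)
    # the logit transform keeps the limit inside (0, 1) but degenerates as
    # C_b approaches its interior maximum at 1 (the gradient vanishes, so
    # the logit SE explodes); fall back on the untransformed bound there by
    # taking the larger of the two asymptotically equivalent lower bounds
    cb_lo <- max(plogis(l - zc * se_l), cb - zc * se_cb)
    cb_hi <- min(plogis(l + zc * se_l), 1)
  }

  list(precision = rho,
       precision_lower = rho_lo,
       precision_upper = if (ci == "two-sided") rho_hi else NA_real_,
       accuracy = cb,
       accuracy_lower = cb_lo,
       accuracy_upper = if (ci == "two-sided") cb_hi else NA_real_,
       n = n, conf = conf, ci = ci)
}

# Delta-method standard error of C_b.  C_b is a smooth function of
# theta = (x_bar, y_bar, sx2, sy2, sxy); under bivariate normality the
# asymptotic covariance of the moment estimators is
#   Var(x_bar) = sx2/m, Cov(x_bar, y_bar) = sxy/m,
#   Var(sx2) = 2 sx2^2/m, Cov(sx2, sy2) = 2 sxy^2/m,
#   Var(sxy) = (sxy^2 + sx2 sy2)/m, Cov(sx2, sxy) = 2 sx2 sxy/m,
# with means independent of second moments.  m = n - 2 keeps the
# small-sample convention of Lin's CCC variance.
accuracy_se <- function(ms) {
  m <- ms$n - 2
  th <- c(ms$x_bar, ms$y_bar, ms$sx2, ms$sy2, ms$sxy)
  cb_of <- function(t) {
    sx <- sqrt(t[3]); sy <- sqrt(t[4])
    v <- sx / sy
    u <- (t[1] - t[2]) / sqrt(sx * sy)
    2 / (v + 1 / v + u^2)
  }
  # central-difference gradient
  grad <- vapply(seq_along(th), function(j) {
    h <- max(abs(th[j]), 1) * 1e-6
    tp <- th; tp[j] <- tp[j] + h
    tm <- th; tm[j] <- tm[j] - h
    (cb_of(tp) - cb_of(tm)) / (2 * h)
  }, numeric(1))
  V <- matrix(0, 5, 5)
  V[1, 1] <- ms$sx2; V[2, 2] <- ms$sy2; V[1, 2] <- V[2, 1] <- ms$sxy
  V[3, 3] <- 2 * ms$sx2^2
  V[4, 4] <- 2 * ms$sy2^2
  V[5, 5] <- ms$sxy^2 + ms$sx2 * ms$sy2
  V[3, 4] <- V[4, 3] <- 2 * ms$sxy^2
  V[3, 5] <- V[5, 3] <- 2 * ms$sx2 * ms$sxy
  V[4, 5] <- V[5, 4] <- 2 * ms$sy2 * ms$sxy
  var_cb <- drop(t(grad) %*% V %*% grad) / m
  sqrt(max(var_cb, 0))
}

#' Total Deviation Index
#'
#' The Total Deviation Index TDI_p is the boundary within which a proportion
#' `p` of absolute differences between the paired measurements fall.  The
#' default mode is Lin's normal approximation
#' `TDI_p = z_((1+p)/2) * sqrt(MSD)` where MSD is the mean squared
#' difference; the `"exact"` mode solves the folded-normal quantile of
#' `|D|, D ~ N(mu_d, sigma_d^2)` instead (the two diverge when `|mu_d|` is
#' large relative to `sigma_d`).  The unfavourable one-sided limit is the
#' upper one, obtained from a log transform of the MSD with delta-method
#' variance `2 (1 - mu_d^4 / MSD^2) / (n - 2)`.
#'
#' @inheritParams ccc
#' @param p proportion of absolute differences to cover (default 0.9).
#' @param mode `"approx"` (Lin's normal approximation, default) or
#'   `"exact"` (folded-normal quantile).
#' @return List with `estimate`, `upper`, `lower` (`NA` for one-sided),
#'   `p`, `mode`, `n`.
#' @export
tdi <- function(x, y, p = 0.9, conf = 0.95, mode = c("approx", "exact"),
                ci = c("one-sided", "two-sided"),
                denominator = c("n", "n_minus_1")) {
  mode <- match.arg(mode)
  ci <- match.arg(ci)
  denominator <- match.arg(denominator)
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1) {
    ccq_validation_error("TDI proportion p must lie strictly between 0 and 1")
  }
  ms <- moment_summary(x, y, denominator)
  est <- tdi_from_moments(ms$mu_d, ms$msd, p, mode)
  if (ms$msd == 0) {
    return(list(estimate = 0, upper = 0, lower = if (ci == "two-sided") 0 else NA_real_,
                p = p, mode = mode, n = ms$n))
  }
  zc <- z_crit(conf, ci)
  var_ln <- 2 * (1 - ms$mu_d^4 / ms$msd^2) / (ms$n - 2)
  se_ln <- sqrt(max(var_ln, 0))
  msd_hi <- exp(log(ms$msd) + zc * se_ln)
  msd_lo <- exp(log(ms$msd) - zc * se_ln)
  if (mode == "approx") {
    up <- qnorm((1 + p) / 2) * sqrt(msd_hi)
    lo <- qnorm((1 + p) / 2) * sqrt(msd_lo)
  } else {
    # propagate the msd limit through the folded-normal quantile at the
    # fitted mean-to-msd ratio
    scale_hi <- sqrt(msd_hi / ms$msd)
    scale_lo <- sqrt(msd_lo / ms$msd)
    up <- tdi_from_moments(ms$mu_d * scale_hi, msd_hi, p, mode)
    lo <- tdi_from_moments(ms$mu_d * scale_lo, msd_lo, p, mode)
  }
  list(estimate = est, upper = up,
       lower = if (ci == "two-sided") lo else NA_real_,
       p = p, mode = mode, n = ms$n)
}

tdi_from_moments <- function(mu_d, msd, p, mode) {
  if (msd <= 0) return(0)
  if (mode == "approx") {
    return(qnorm((1 + p) / 2) * sqrt(msd))
  }
  sigma_d2 <- msd - mu_d^2
  if (sigma_d2 <= 0) return(abs(mu_d))   # point-mass differences
  sd_d <- sqrt(sigma_d2)
  cover <- function(t) {
    pnorm((t - mu_d) / sd_d) - pnorm((-t - mu_d) / sd_d) - p
  }
  upper_bracket <- abs(mu_d) + sd_d * (qnorm((1 + p) / 2) + 8)
  uniroot(cover, lower = 0, upper = upper_bracket, tol = 1e-10)$root
}

#' Coverage Probability at a clinical tolerance
#'
#' The Coverage Probability CP_delta is the model-based probability that a
#' paired difference lies within +/- delta, with delta conventionally set to
#' the instrument's minimal clinically important difference (0.4 CCQ
#' points).  Under the bivariate-normal model,
#' `CP = Phi((delta - mu_d)/sigma_d) - Phi((-delta - mu_d)/sigma_d)` on the
#' fitted moments.  The unfavourable one-sided lower limit comes from a
#' logit-transform delta method over the moments of the differences.
#'
#' @inheritParams ccc
#' @param delta half-width of the agreement band, on the score scale
#'   (default 0.4, the CCQ MCID); must be positive.
#' @return List with `estimate`, `lower`, `upper` (`NA` for one-sided),
#'   `delta`, `n`, and `degenerate` flag (constant differences).
#' @examples
#' # mu_d = 0, sigma_d = 0.4, delta = 0.4 -> Phi(1) - Phi(-1) = 0.6827
#' @export
coverage_prob <- function(x, y, delta = 0.4, conf = 0.95,
                          ci = c("one-sided", "two-sided"),
                          denominator = c("n", "n_minus_1")) {
  ci <- match.arg(ci)
  denominator <- match.arg(denominator)
  if (!is.numeric(delta) || length(delta) != 1L || delta < 0) {
    ccq_validation_error("delta must be a nonnegative scalar")
  }
  ms <- moment_summary(x, y, denominator)
  cp_mom <- cp_from_moments(ms$mu_d, ms$sigma_d2, delta)
  # constant differences up to floating-point residue
  if (ms$sigma_d2 <= 1e-12 * max(ms$msd, 1)) {
    est <- as.numeric(abs(ms$mu_d) < delta)
    return(list(estimate = est, lower = est,
                upper = if (ci == "two-sided") est else NA_real_,
                delta = delta, n = ms$n, degenerate = TRUE))
  }
  est <- cp_mom
  zc <- z_crit(conf, ci)
  se_l <- cp_logit_se(ms$mu_d, sqrt(ms$sigma_d2), delta, ms$n)
  if (est <= 0 || est >= 1 || !is.finite(se_l)) {
    lo <- hi <- est
  } else {
    l <- qlogis(est)
    lo <- plogis(l - zc * se_l)
    hi <- plogis(l + zc * se_l)
  }
  list(estimate = est, lower = lo,
       upper = if (ci == "two-sided") hi else NA_real_,
       delta = delta, n = ms$n, degenerate = FALSE)
}

cp_from_moments <- function(mu_d, sigma_d2, delta) {
  if (sigma_d2 <= 0) return(as.numeric(abs(mu_d) < delta))
  sd_d <- sqrt(sigma_d2)
  pnorm((delta - mu_d) / sd_d) - pnorm((-delta - mu_d) / sd_d)
}

# Delta-method SE of logit(CP): differences D ~ N(mu_d, sigma_d^2) with
# Var(mu_hat) = sigma_d^2/m, Var(sigma_hat) = sigma_d^2/(2m), independent
# under normality; m = n - 2 as elsewhere in the suite.
cp_logit_se <- function(mu_d, sd_d, delta, n) {
  m <- n - 2
  z1 <- (delta - mu_d) / sd_d
  z2 <- (-delta - mu_d) / sd_d
  cp <- pnorm(z1) - pnorm(z2)
  d_mu <- (dnorm(z2) - dnorm(z1)) / sd_d
  d_sd <- (dnorm(z2) * z2 - dnorm(z1) * z1) / sd_d
  var_cp <- (d_mu^2 * sd_d^2 / m) + (d_sd^2 * sd_d^2 / (2 * m))
  sqrt(max(var_cp, 0)) / (cp * (1 - cp))
}

#' Intraclass correlation coefficient (two-way, absolute agreement,
#' single rater)
#'
#' The ICC(A,1) of McGraw & Wong from the two-column rating structure
#' (subjects x 2 raters), the variance-components counterpart of the CCC:
#' `(MSR - MSE) / (MSR + MSE + (2/n)(MSC - MSE))` for two raters, where MSR,
#' MSC, MSE are the rows, columns and error mean squares of the two-way
#' ANOVA.  The one-sided lower confidence limit uses the F-based formula
#' with Satterthwaite degrees of freedom.
#'
#' @inheritParams ccc
#' @return List with `estimate`, `lower`, `upper` (`NA` for one-sided),
#'   `n`, and the mean squares `msr`, `msc`, `mse`.
#' @export
icc <- function(x, y, conf = 0.95, ci = c("one-sided", "two-sided")) {
  ci <- match.arg(ci)
  check_pairs(x, y)
  if (var(x) == 0 && var(y) == 0 && var(x - y) == 0) {
    ccq_validation_error("ICC is undefined: all ratings identical")
  }
  n <- length(x)
  k <- 2
  Y <- cbind(x, y)
  grand <- mean(Y)
  row_means <- rowMeans(Y)
  col_means <- colMeans(Y)
  msr <- k * sum((row_means - grand)^2) / (n - 1)
  msc <- n * sum((col_means - grand)^2) / (k - 1)
  mse <- sum((Y - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2) / ((n - 1) * (k - 1))
  est <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  alpha <- if (ci == "one-sided") 1 - conf else (1 - conf) / 2
  bound <- function(icc_val, lower = TRUE) {
    a <- k * icc_val / (n * (1 - icc_val))
    b <- 1 + k * icc_val * (n - 1) / (n * (1 - icc_val))
    v_num <- (a * msc + b * mse)^2
    v_den <- (a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1))
    v <- v_num / v_den
    if (lower) {
      fs <- qf(1 - alpha, n - 1, v)
      n * (msr - fs * mse) /
        (fs * (k * msc + (k * n - k - n) * mse) + n * msr)
    } else {
      fs <- qf(1 - alpha, v, n - 1)
      n * (fs * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * fs * msr)
    }
  }
  if (abs(est) >= 1 - 1e-12 || mse == 0) {
    lo <- hi <- est
  } else {
    lo <- bound(est, lower = TRUE)
    hi <- bound(est, lower = FALSE)
  }
  list(estimate = est, lower = lo,
       upper = if (ci == "two-sided") hi else NA_real_,
       n = n, msr = msr, msc = msc, mse = mse, conf = conf, ci = ci)
}

#' Categorize an agreement coefficient
#'
#' Conventional cutoffs for rating agreement coefficients (applied here to
#' both ICC and CCC, which measure the same construct): at or below 0.4 is
#' poor to fair, 0.41--0.6 moderate, 0.61--0.8 good, 0.81--1.0 excellent.
#' Negative coefficients fall in the poor-to-fair category.
#'
#' @param coefficient a value in \[-1, 1\].
#' @return Character label, one of `"poor to fair"`, `"moderate"`,
#'   `"good"`, `"excellent"`.
#' @examples
#' categorize_agreement(0.87)  # "excellent"
#' categorize_agreement(0.74)  # "good"
#' @export
categorize_agreement <- function(coefficient) {
  if (!is.numeric(coefficient) || length(coefficient) != 1L ||
      is.na(coefficient) || coefficient < -1 || coefficient > 1) {
    ccq_validation_error("agreement coefficient must lie in [-1, 1]")
  }
  if (coefficient <= 0.4) "poor to fair"
  else if (coefficient <= 0.6) "moderate"
  else if (coefficient <= 0.8) "good"
  else "excellent"
}

#' Bland-Altman quantities for paired scores
#'
#' Per-pair means `(x+y)/2` and differences `x-y`, the bias (mean
#' difference), the SD of the differences, the 95% limits of agreement
#' `bias -/+ 1.96*sd`, and the fraction of pairs whose absolute difference
#' is strictly smaller than the clinical tolerance `delta` (the MCID band).
#' The SD of differences uses the sample (n-1) convention, as is standard
#' for limits of agreement.
#'
#' @inheritParams coverage_prob
#' @return An object of class `bland_altman`: list with `means`, `diffs`,
#'   `bias`, `sd_diff`, `loa_low`, `loa_high`, `delta`,
#'   `within_mcid_fraction`, `n`.
#' @export
bland_altman <- function(x, y, delta = 0.4) {
  check_pairs(x, y)
  diffs <- x - y
  means <- (x + y) / 2
  bias <- mean(diffs)
  sd_diff <- sd(diffs)
  structure(
    list(
      means = means, diffs = diffs,
      bias = bias, sd_diff = sd_diff,
      loa_low = bias - 1.96 * sd_diff,
      loa_high = bias + 1.96 * sd_diff,
      delta = delta,
      within_mcid_fraction = mean(abs(diffs) < delta),
      n = length(x)
    ),
    class = "bland_altman"
  )
}

#' @export
as.data.frame.bland_altman <- function(x, ...) {
  data.frame(mean = x$means, diff = x$diffs)
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman: bias %.3f, limits of agreement [%.3f, %.3f], %.0f%% of %d pairs within +/-%.2f\n",
    x$bias, x$loa_low, x$loa_high, 100 * x$within_mcid_fraction, x$n,
    x$delta))
  invisible(x)
}

#' Plot a Bland-Altman object
#'
#' Difference-versus-mean scatter with the bias, 95% limits of agreement
#' (dashed) and the clinical tolerance band (dotted).
#'
#' @param x a [bland_altman()] object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$diffs, xlab = "Mean of pair",
                 ylab = "Difference (x - y)", ...)
  graphics::abline(h = x$bias, lty = 1)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 2)
  graphics::abline(h = c(-x$delta, x$delta), lty = 3)
  invisible(x)
}

#' Shapiro-Wilk normality check
#'
#' Wraps the Shapiro-Wilk test and reports a pass flag at the chosen alpha;
#' the study pipeline uses it to annotate whether the normal-theory
#' confidence limits of the agreement suite can be trusted for each score
#' series.
#'
#' @param values numeric vector, 3 <= n <= 5000, non-constant.
#' @param alpha significance level for the pass flag (default 0.05).
#' @return List with `W`, `p_value`, `normal` (`TRUE` when `p >= alpha`),
#'   `alpha`, `n`.
#' @export
normality_check <- function(values, alpha = 0.05) {
  if (!is.numeric(values) || anyNA(values)) {
    ccq_validation_error("normality check requires complete numeric input")
  }
  if (length(values) < 3L || length(values) > 5000L) {
    ccq_validation_error("normality check requires 3 <= n <= 5000")
  }
  if (length(unique(values)) == 1L) {
    ccq_validation_error("normality test undefined for constant input")
  }
  sw <- shapiro.test(values)
  list(W = unname(sw$statistic), p_value = sw$p.value,
       normal = sw$p.value >= alpha, alpha = alpha, n = length(values))
}

#' Full pairwise agreement estimate
#'
#' Bundles the whole agreement suite for one pair of score series: CCC with
#' its precision/accuracy decomposition, TDI_p, CP_delta, ICC(A,1), their
#' one-sided 95% limits in the unfavourable direction, the underlying moment
#' summary, and the agreement category of the CCC.
#'
#' @inheritParams ccc
#' @param p TDI proportion (default 0.9).
#' @param delta CP half-width (default 0.4, the CCQ MCID).
#' @param tdi_mode passed to [tdi()].
#' @return An object of class `agreement_estimate`.
#' @export
agreement_estimate <- function(x, y, p = 0.9, delta = 0.4, conf = 0.95,
                               ci = c("one-sided", "two-sided"),
                               denominator = c("n", "n_minus_1"),
                               tdi_mode = c("approx", "exact")) {
  ci <- match.arg(ci)
  denominator <- match.arg(denominator)
  tdi_mode <- match.arg(tdi_mode)
  ms <- moment_summary(x, y, denominator)
  cc <- ccc(x, y, conf = conf, ci = ci, denominator = denominator)
  pa <- precision_accuracy(x, y, conf = conf, ci = ci,
                           denominator = denominator)
  td <- tdi(x, y, p = p, conf = conf, mode = tdi_mode, ci = ci,
            denominator = denominator)
  cp <- coverage_prob(x, y, delta = delta, conf = conf, ci = ci,
                      denominator = denominator)
  ic <- icc(x, y, conf = conf, ci = ci)
  structure(
    list(
      ccc = cc$estimate, ccc_lo = cc$lower,
      precision = pa$precision, precision_lo = pa$precision_lower,
      accuracy = pa$accuracy, accuracy_lo = pa$accuracy_lower,
      tdi = td$estimate, tdi_hi = td$upper,
      cp = cp$estimate, cp_lo = cp$lower,
      icc = ic$estimate, icc_lo = ic$lower,
      p = p, delta = delta, conf = conf, ci = ci,
      icc_variant = "ICC(A,1) two-way absolute-agreement single-rater",
      category = categorize_agreement(cc$estimate),
      moments = ms, n = ms$n
    ),
    class = "agreement_estimate"
  )
}

#' @export
print.agreement_estimate <- function(x, ...) {
  cat(sprintf("Pairwise agreement (n = %d):\n", x$n))
  cat(sprintf("  CCC       %6.3f  (95%% lower %6.3f)  [%s]\n",
              x$ccc, x$ccc_lo, x$category))
  cat(sprintf("  Precision %6.3f  (95%% lower %6.3f)\n",
              x$precision, x$precision_lo))
  cat(sprintf("  Accuracy  %6.3f  (95%% lower %6.3f)\n",
              x$accuracy, x$accuracy_lo))
  cat(sprintf("  TDI_%.2g   %6.3f  (95%% upper %6.3f)\n",
              x$p, x$tdi, x$tdi_hi))
  cat(sprintf("  CP_%.2g    %6.3f  (95%% lower %6.3f)\n",
              x$delta, x$cp, x$cp_lo))
  cat(sprintf("  ICC       %6.3f  (95%% lower %6.3f)\n", x$icc, x$icc_lo))
  invisible(x)
}
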
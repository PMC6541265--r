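#' @title Small-study-effect diagnostics and bias-adjusted estimation
#'
#' @description
#' Small (imprecise) studies that report systematically larger effects than
#' large studies produce an asymmetric funnel plot, typically a footprint of
#' publication selection.  This module provides the regression test of
#' funnel asymmetry (Egger), the Duval-Tweedie trim-and-fill, cumulative
#' meta-analysis by precision, the TOP10 estimator, and limit meta-analysis
#' (the extended random-effects model whose adjusted estimate is the model
#' expectation as study precision grows without bound).  All methods operate
#' on the Fisher-z scale and back-transform to r.
#'
#' @name bias
NULL

#' Egger regression test of funnel-plot asymmetry
#'
#' Classical Egger test: ordinary least squares of the standardized effect
#' \eqn{z_i/se_i} on precision \eqn{1/se_i}; the intercept estimates the
#' asymmetry and is tested with a t statistic on k - 2 degrees of freedom.
#' The weighted variant replaces OLS with a \eqn{1/v_i}-weighted
#' meta-regression of \eqn{z_i} on \eqn{se_i}.
#'
#' @param studies Study-level data frame with \code{z} and \code{var_z}.
#' @param weighted Use the weighted meta-regression variant (default FALSE,
#'   i.e. the classical unweighted test).
#' @return An object of class \code{ppi_egger}: list with \code{intercept},
#'   \code{slope}, \code{se_intercept}, \code{t_stat}, \code{df}, \code{p}.
#' @export
egger_test <- function(studies, weighted = FALSE) {
  .check_studies(studies, k_min = 3L)
  y <- studies$z; se <- sqrt(studies$var_z); k <- length(y)
  if (!weighted) {
    fit <- stats::lm(I(y / se) ~ I(1 / se))
    cf <- summary(fit)$coefficients
    int <- cf[1, 1]; se_int <- cf[1, 2]; slope <- cf[2, 1]
  } else {
    fit <- stats::lm(y ~ se, weights = 1 / se^2)
    cf <- summary(fit)$coefficients
    int <- cf[2, 1]; se_int <- cf[2, 2]; slope <- cf[1, 1]
  }
  tval <- int / se_int
  structure(list(intercept = int, slope = slope, se_intercept = se_int,
                 t_stat = tval, df = k - 2,
                 p = 2 * stats::pt(-abs(tval), k - 2),
                 weighted = weighted),
            class = "ppi_egger")
}

#' @export
print.ppi_egger <- function(x, digits = 3, ...) {
  cat(sprintf("Egger regression test of funnel asymmetry (%s)\n",
              if (x$weighted) "weighted" else "classical"))
  cat(sprintf("  intercept = %.*f (se %.3f), slope = %.*f\n",
              digits, x$intercept, x$se_intercept, digits, x$slope))
  cat(sprintf("  t(%d) = %.2f, p = %s\n", x$df, x$t_stat,
              format.pval(x$p)))
  invisible(x)
}

#' Duval-Tweedie trim-and-fill
#'
#' Iteratively estimates the number \eqn{k_0} of studies suppressed on one
#' side of the funnel (rank-based L0 or R0 estimator), trims the \eqn{k_0}
#' most extreme studies on the opposite side, re-estimates the center, and
#' on convergence fills in mirror images of the trimmed studies.  The
#' adjusted estimate is the random-effects pool of observed plus filled
#' studies; observed studies are never removed from the final pooled set.
#'
#' @param studies Study-level data frame with \code{z} and \code{var_z}.
#' @param side Side on which studies are presumed missing: \code{"left"},
#'   \code{"right"}, or \code{"auto"} (from the sign of the Egger slope
#'   relationship: a positive effect-size/standard-error association implies
#'   missing small studies on the left).
#' @param estimator \code{"L0"} (default) or \code{"R0"}.
#' @param max_iter Iteration cap; non-convergence is an error with a trace.
#' @return An object of class \code{ppi_trimfill}: list with \code{k0},
#'   \code{side}, \code{r_adjusted}, \code{ci_low}, \code{ci_high},
#'   \code{pooled} (the adjusted \code{ppi_pooled}), and \code{filled}
#'   (data frame of observed + imputed studies with a \code{filled} flag).
#' @export
trim_and_fill <- function(studies, side = c("auto", "left", "right"),
                          estimator = c("L0", "R0"), max_iter = 50L) {
  side <- match.arg(side); estimator <- match.arg(estimator)
  .check_studies(studies, k_min = 3L)
  y <- studies$z; v <- studies$var_z; k <- length(y)
  if (side == "auto") {
    eg <- egger_test(studies)
    side <- if (eg$intercept >= 0) "left" else "right"
  }
  # reflect so that missing studies are always on the left
  flip <- if (side == "left") 1 else -1
  yy <- flip * y

  k0 <- 0L; trace <- integer(0)
  for (it in seq_len(max_iter)) {
    keep <- seq_len(k)
    if (k0 > 0) keep <- order(yy)[seq_len(k - k0)]  # trim k0 largest
    mu <- sum(yy[keep] / v[keep]) / sum(1 / v[keep])
    dev <- yy - mu
    rnk <- rank(abs(dev), ties.method = "first")
    tn <- sum(rnk[dev > 0])
    k0_new <- switch(estimator,
      L0 = max(0, round((4 * tn - k * (k + 1)) / (2 * k - 1))),
      R0 = max(0, round(k - 0.5 - sqrt(2 * k^2 - 4 * tn + 0.25))))
    k0_new <- min(k0_new, k - 1L)
    trace <- c(trace, k0_new)
    if (k0_new == k0) break
    k0 <- k0_new
    if (it == max_iter)
      stop("trim-and-fill failed to converge; k0 trace: ",
           paste(trace, collapse = " "))
  }

  filled <- data.frame(study_id = if (!is.null(studies$study_id))
                         studies$study_id else paste0("study_", seq_len(k)),
                       z = y, var_z = v, filled = FALSE,
                       stringsAsFactors = FALSE)
  if (k0 > 0) {
    keep <- order(yy)[seq_len(k - k0)]
    mu <- sum(yy[keep] / v[keep]) / sum(1 / v[keep])
    ext <- order(yy, decreasing = TRUE)[seq_len(k0)]
    mirror <- data.frame(study_id = paste0("filled_", seq_len(k0)),
                         z = flip * (2 * mu - yy[ext]), var_z = v[ext],
                         filled = TRUE, stringsAsFactors = FALSE)
    filled <- rbind(filled, mirror)
  }
  pooled <- pool_random_effects(filled)
  structure(list(k0 = k0, side = side, estimator = estimator,
                 r_adjusted = pooled$r_pooled,
                 ci_low = pooled$ci_low, ci_high = pooled$ci_high,
                 pooled = pooled, filled = filled),
            class = "ppi_trimfill")
}

#' @export
print.ppi_trimfill <- function(x, digits = 3, ...) {
  cat(sprintf("Trim-and-fill (%s, missing on the %s): k0 = %d imputed\n",
              x$estimator, x$side, x$k0))
  cat(sprintf("  adjusted r = %.*f  [%.*f, %.*f]\n", digits, x$r_adjusted,
              digits, x$ci_low, digits, x$ci_high))
  invisible(x)
}

#' Cumulative meta-analysis by precision
#'
#' Re-pools nested subsets of studies ordered from most to least precise,
#' showing how much adding the small studies moves the estimate.  The final
#' row equals the full random-effects pool.
#'
#' @param studies Study-level data frame with \code{z} and \code{var_z}.
#' @param tau2_method Passed to \code{\link{pool_random_effects}}.
#' @return Data frame with one row per prefix: \code{k}, \code{study_id}
#'   (study added), \code{r_pooled}, \code{ci_low}, \code{ci_high},
#'   \code{I2}.
#' @export
cumulative_meta <- function(studies, tau2_method = "DL") {
  .check_studies(studies)
  ord <- order(studies$var_z,
               if (!is.null(studies$study_id)) studies$study_id else
                 seq_len(nrow(studies)))
  s <- studies[ord, , drop = FALSE]
  out <- lapply(seq_len(nrow(s)), function(i) {
    if (i == 1L) {
      zq <- stats::qnorm(0.975)
      data.frame(k = 1L, r_pooled = tanh(s$z[1]),
                 ci_low = tanh(s$z[1] - zq * sqrt(s$var_z[1])),
                 ci_high = tanh(s$z[1] + zq * sqrt(s$var_z[1])),
                 I2 = 0)
    } else {
      p <- pool_random_effects(s[seq_len(i), , drop = FALSE], tau2_method)
      data.frame(k = i, r_pooled = p$r_pooled, ci_low = p$ci_low,
                 ci_high = p$ci_high, I2 = p$I2)
    }
  })
  out <- do.call(rbind, out)
  out$study_id <- if (!is.null(s$study_id)) s$study_id else NA_character_
  out[c("k", "study_id", "r_pooled", "ci_low", "ci_high", "I2")]
}

#' TOP10 estimator
#'
#' Fixed-effect pool of the top 10 percent most precise studies
#' (\eqn{\lceil k/10 \rceil} of them), a simple but well-performing
#' estimator under small-study bias.  Ties in precision are broken by
#' \code{study_id} order, deterministically.  With fewer than 10 studies a
#' warning is issued and the single most precise study is used.
#'
#' @param studies Study-level data frame with \code{z} and \code{var_z}.
#' @return A \code{ppi_pooled} object (fixed-effect) over the selected
#'   studies; for a single study, a degenerate one-study summary.
#' @export
top10 <- function(studies) {
  .check_studies(studies, k_min = 1L)
  k <- nrow(studies)
  if (k < 10) warning("fewer than 10 studies; TOP10 uses the single most ",
                      "precise study")
  m <- max(1L, ceiling(k / 10))
  ord <- order(studies$var_z,
               if (!is.null(studies$study_id)) studies$study_id else
                 seq_len(k))
  sel <- studies[ord[seq_len(m)], , drop = FALSE]
  if (m == 1L) {
    zq <- stats::qnorm(0.975)
    structure(list(k = 1L, r_pooled = tanh(sel$z), se_z = sqrt(sel$var_z),
                   z_pooled = sel$z,
                   ci_low = tanh(sel$z - zq * sqrt(sel$var_z)),
                   ci_high = tanh(sel$z + zq * sqrt(sel$var_z)),
                   tau2 = 0, Q = 0, df = 0, p_q = NA_real_, I2 = 0,
                   p = 2 * stats::pnorm(-abs(sel$z / sqrt(sel$var_z))),
                   model = "fixed", tau2_method = "none", level = 0.95,
                   studies = sel), class = "ppi_pooled")
  } else {
    pool_fixed_effects(sel)
  }
}

#' Limit meta-analysis
#'
#' Fits the extended random-effects model with a small-study term on the
#' Fisher-z scale,
#' \deqn{z_i = \beta_0 + \beta_1 \sqrt{v_i + \tau^2} + \sqrt{v_i + \tau^2}\,
#'   \epsilon_i,}
#' a weighted regression of the study effects on their total standard error
#' (the generalized radial plot).  Because \eqn{\sqrt{v_i + \tau^2}}
#' approaches \eqn{\tau} (not zero) as a study's precision grows, the
#' bias-adjusted estimate is the model expectation in that limit,
#' \eqn{\beta_0 + \beta_1 \hat\tau} (the "expectation" adjustment; the raw
#' intercept and a pooled-shrunken-estimate variant are available).  The
#' fit also yields per-study shrinkage factors
#' \eqn{G_i = \sqrt{\hat\tau^2/(v_i + \hat\tau^2)}} and the decomposition of
#' Cochran's Q into a 1-df small-study-effect component \eqn{Q - Q'} and a
#' (k-2)-df residual-heterogeneity component \eqn{Q'}.
#'
#' @param studies Study-level data frame with \code{z} and \code{var_z}.
#' @param tau2_method Between-study variance estimator (as in pooling).
#' @param adjust \code{"expectation"} (default), \code{"intercept"}, or
#'   \code{"shrunken-pool"}.
#' @param level Confidence level.
#' @return An object of class \code{ppi_limitmeta}: list with
#'   \code{r_limit}, \code{ci_low}, \code{ci_high}, \code{z_limit},
#'   \code{se_limit}, \code{p}, \code{beta0}, \code{beta1}, \code{tau2},
#'   \code{Q}, \code{Q_small}, \code{p_small}, \code{Q_resid},
#'   \code{df_resid}, \code{p_resid}, \code{shrinkage} (the \eqn{G_i}),
#'   \code{shrunken} (per-study shrunken estimates on z), \code{note}.
#' @export
limit_meta <- function(studies, tau2_method = "DL",
                       adjust = c("expectation", "intercept",
                                  "shrunken-pool"),
                       level = 0.95) {
  adjust <- match.arg(adjust)
  .check_studies(studies, k_min = 3L)
  y <- studies$z; v <- studies$var_z; k <- length(y)
  re <- pool_random_effects(studies, tau2_method)
  tau2 <- re$tau2
  q <- .cochran_q(y, v)

  note <- NULL
  gshr <- sqrt(tau2 / (v + tau2))
  shrunken <- re$z_pooled + gshr * (y - re$z_pooled)

  if (tau2 <= 0) {
    # no between-study variance: nothing to shrink; the limit coincides
    # with the fixed-effect estimate
    fe <- pool_fixed_effects(studies, level = level)
    note <- "tau2 = 0: shrinkage is zero; limit equals fixed-effect estimate"
    return(structure(list(
      r_limit = fe$r_pooled, ci_low = fe$ci_low, ci_high = fe$ci_high,
      z_limit = fe$z_pooled, se_limit = fe$se_z, p = fe$p,
      beta0 = fe$z_pooled, beta1 = 0, tau2 = 0,
      Q = q$Q, Q_small = 0, p_small = 1,
      Q_resid = q$Q, df_resid = k - 2,
      p_resid = stats::pchisq(q$Q, k - 2, lower.tail = FALSE),
      shrinkage = rep(0, k), shrunken = rep(fe$z_pooled, k),
      adjust = adjust, level = level, note = note),
      class = "ppi_limitmeta"))
  }

  # weighted least squares of y on x = sqrt(v + tau2), weights 1/(v + tau2),
  # via explicit normal equations (equivalent to OLS on the radial plot)
  x <- sqrt(v + tau2)
  w <- 1 / (v + tau2)
  sw <- sum(w); swx <- sum(w * x); swx2 <- sum(w * x^2)
  swy <- sum(w * y); swxy <- sum(w * x * y)
  det <- sw * swx2 - swx^2
  beta0 <- (swx2 * swy - swx * swxy) / det
  beta1 <- (sw * swxy - swx * swy) / det
  # unscaled coefficient covariance (unit radial-error theory)
  v00 <- swx2 / det; v11 <- sw / det; v01 <- -swx / det

  fitted <- beta0 + beta1 * x
  q_resid <- sum(w * (y - fitted)^2)
  q_small <- max(0, q$Q - q_resid)

  tau <- sqrt(tau2)
  est <- switch(adjust,
    expectation = beta0 + beta1 * tau,
    intercept = beta0,
    `shrunken-pool` = sum((1 / v) * shrunken) / sum(1 / v))
  se <- switch(adjust,
    expectation = sqrt(v00 + tau2 * v11 + 2 * tau * v01),
    intercept = sqrt(v00),
    `shrunken-pool` = sqrt(1 / sum(1 / v)))

  zq <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(
    r_limit = tanh(est), ci_low = tanh(est - zq * se),
    ci_high = tanh(est + zq * se),
    z_limit = est, se_limit = se, p = 2 * stats::pnorm(-abs(est / se)),
    beta0 = beta0, beta1 = beta1, tau2 = tau2,
    Q = q$Q, Q_small = q_small,
    p_small = stats::pchisq(q_small, 1, lower.tail = FALSE),
    Q_resid = q_resid, df_resid = k - 2,
    p_resid = stats::pchisq(q_resid, k - 2, lower.tail = FALSE),
    shrinkage = gshr, shrunken = shrunken,
    adjust = adjust, level = level, note = note),
    class = "ppi_limitmeta")
}

#' @export
print.ppi_limitmeta <- function(x, digits = 3, ...) {
  cat("Limit meta-analysis (adjusted for small-study effects)\n")
  cat(sprintf("  adjusted r = %.*f  [%d%% CI %.*f, %.*f]   p = %s\n",
              digits, x$r_limit, round(100 * x$level), digits, x$ci_low,
              digits, x$ci_high, format.pval(x$p)))
  cat(sprintf("  small-study effects: Q-Q'(1) = %.2f, p = %s\n",
              x$Q_small, format.pval(x$p_small)))
  cat(sprintf("  residual heterogeneity: Q'(%d) = %.2f, p = %s\n",
              x$df_resid, x$Q_resid, format.pval(x$p_resid)))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Tidy funnel/forest plot data
#'
#' Emits one row per study (plus trim-and-fill imputations when requested)
#' with everything a plotting layer needs: effect and standard error on both
#' scales, shrunken limit-meta-analysis effects, and a filled flag.
#'
#' @param studies Study-level data frame with \code{z} and \code{var_z}.
#' @param trimfill Optional \code{ppi_trimfill} object; its imputed mirror
#'   studies are appended with \code{filled = TRUE}.
#' @param limit Optional \code{ppi_limitmeta} object; adds the
#'   \code{z_shrunken}/\code{r_shrunken} columns.
#' @return Data frame with columns \code{study_id}, \code{r}, \code{z},
#'   \code{se_z}, \code{precision}, \code{r_shrunken}, \code{z_shrunken},
#'   \code{filled}.
#' @export
funnel_data <- function(studies, trimfill = NULL, limit = NULL) {
  .check_studies(studies, k_min = 1L)
  out <- data.frame(
    study_id = if (!is.null(studies$study_id)) studies$study_id else
      paste0("study_", seq_len(nrow(studies))),
    r = tanh(studies$z), z = studies$z, se_z = sqrt(studies$var_z),
    precision = 1 / sqrt(studies$var_z),
    r_shrunken = NA_real_, z_shrunken = NA_real_,
    filled = FALSE, stringsAsFactors = FALSE)
  if (!is.null(limit)) {
    out$z_shrunken <- limit$shrunken
    out$r_shrunken <- tanh(limit$shrunken)
  }
  if (!is.null(trimfill) && trimfill$k0 > 0) {
    f <- trimfill$filled[trimfill$filled$filled, , drop = FALSE]
    out <- rbind(out, data.frame(
      study_id = f$study_id, r = tanh(f$z), z = f$z, se_z = sqrt(f$var_z),
      precision = 1 / sqrt(f$var_z), r_shrunken = NA_real_,
      z_shrunken = NA_real_, filled = TRUE, stringsAsFactors = FALSE))
  }
  out
}
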
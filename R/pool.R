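#' @title Random-effects and fixed-effect pooling on the Fisher-z scale
#'
#' @description
#' Study effects are pooled on the Fisher-z scale with inverse-variance
#' weights.  The random-effects model adds the DerSimonian-Laird (default)
#' moment estimate of the between-study variance \eqn{\tau^2}; Paule-Mandel
#' and REML are available.  Heterogeneity is summarized by Cochran's Q (from
#' fixed-effect weights, df = k - 1) and
#' \eqn{I^2 = \max(0, (Q - df)/Q) \cdot 100}.  Estimates, Wald confidence
#' limits and bounds are back-transformed to the correlation scale.
#'
#' @name pooling
NULL

.check_studies <- function(studies, k_min = 2L) {
  stopifnot(is.data.frame(studies),
            all(c("z", "var_z") %in% names(studies)))
  if (nrow(studies) < k_min)
    stop("need at least ", k_min, " studies, got ", nrow(studies))
  if (any(studies$var_z <= 0)) stop("non-positive study variance")
  if (anyNA(studies$z) || anyNA(studies$var_z))
    stop("missing study effect or variance")
  invisible(studies)
}

.cochran_q <- function(y, v) {
  w <- 1 / v
  mu <- sum(w * y) / sum(w)
  list(Q = sum(w * (y - mu)^2), mu = mu, w = w)
}

.tau2_dl <- function(y, v) {
  k <- length(y)
  q <- .cochran_q(y, v)
  c2 <- sum(q$w) - sum(q$w^2) / sum(q$w)
  max(0, (q$Q - (k - 1)) / c2)
}

.tau2_pm <- function(y, v, tol = 1e-10) {
  k <- length(y)
  gen_q <- function(t2) {
    w <- 1 / (v + t2)
    mu <- sum(w * y) / sum(w)
    sum(w * (y - mu)^2) - (k - 1)
  }
  if (gen_q(0) <= 0) return(0)
  hi <- 1
  while (gen_q(hi) > 0 && hi < 1e4) hi <- hi * 2
  stats::uniroot(gen_q, c(0, hi), tol = tol)$root
}

.tau2_reml <- function(y, v, tol = 1e-10) {
  ll <- function(t2) {
    w <- 1 / (v + t2)
    mu <- sum(w * y) / sum(w)
    -0.5 * (sum(log(v + t2)) + log(sum(w)) + sum(w * (y - mu)^2))
  }
  stats::optimize(ll, c(0, max(1, 10 * stats::var(y))),
                  maximum = TRUE, tol = tol)$maximum
}

#' Pool study effects with a random-effects model
#'
#' DerSimonian-Laird (or Paule-Mandel / REML) random-effects pooling on the
#' Fisher-z scale with plain Wald confidence limits, back-transformed to r.
#'
#' @param studies A \code{ppi_studies} data frame (or any data frame with
#'   \code{z} and \code{var_z} columns; a \code{study_id} column is carried
#'   along when present).
#' @param tau2_method \code{"DL"} (default), \code{"PM"} or \code{"REML"}.
#' @param level Confidence level (default 0.95).
#' @return An object of class \code{ppi_pooled}: a list with \code{k},
#'   \code{r_pooled}, \code{ci_low}, \code{ci_high}, \code{z_pooled},
#'   \code{se_z}, \code{tau2}, \code{Q}, \code{df}, \code{p_q}, \code{I2},
#'   \code{p}, \code{model}, \code{tau2_method}, \code{level},
#'   \code{studies}.
#' @export
pool_random_effects <- function(studies, tau2_method = c("DL", "PM", "REML"),
                                level = 0.95) {
  tau2_method <- match.arg(tau2_method)
  .check_studies(studies)
  y <- studies$z; v <- studies$var_z; k <- length(y)
  tau2 <- switch(tau2_method,
                 DL = .tau2_dl(y, v),
                 PM = .tau2_pm(y, v),
                 REML = .tau2_reml(y, v))
  .pool(y, v, tau2, studies, model = "random", tau2_method, level)
}

#' Pool study effects with a fixed-effect model
#'
#' Inverse-variance pooling with \eqn{\tau^2} forced to zero.  Used
#' internally by trim-and-fill and TOP10.
#'
#' @inheritParams pool_random_effects
#' @return A \code{ppi_pooled} object with \code{tau2 = 0}.
#' @export
pool_fixed_effects <- function(studies, level = 0.95) {
  .check_studies(studies)
  .pool(studies$z, studies$var_z, 0, studies, model = "fixed", "none", level)
}

.pool <- function(y, v, tau2, studies, model, tau2_method, level) {
  k <- length(y)
  q <- .cochran_q(y, v)
  df <- k - 1
  i2 <- max(0, (q$Q - df) / q$Q) * 100
  w <- 1 / (v + tau2)
  mu <- sum(w * y) / sum(w)
  se <- 1 / sqrt(sum(w))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(
    k = k,
    r_pooled = tanh(mu),
    ci_low = tanh(mu - zq * se),
    ci_high = tanh(mu + zq * se),
    z_pooled = mu, se_z = se,
    tau2 = tau2,
    Q = q$Q, df = df, p_q = stats::pchisq(q$Q, df, lower.tail = FALSE),
    I2 = i2,
    p = 2 * stats::pnorm(-abs(mu / se)),
    model = model, tau2_method = tau2_method, level = level,
    studies = studies), class = "ppi_pooled")
}

#' @export
print.ppi_pooled <- function(x, digits = 3, ...) {
  cat(sprintf("%s-effect%s meta-analysis of k = %d studies (Fisher-z scale)\n",
              if (x$model == "random") "Random" else "Fixed",
              if (x$model == "random")
                paste0("s (tau2: ", x$tau2_method, ")") else "", x$k))
  cat(sprintf("  r = %.*f  [%d%% CI %.*f, %.*f]   p = %s\n",
              digits, x$r_pooled, round(100 * x$level),
              digits, x$ci_low, digits, x$ci_high, format.pval(x$p)))
  cat(sprintf("  tau2 = %.4f   Q(%d) = %.2f (p = %s)   I2 = %.1f%%\n",
              x$tau2, x$df, x$Q, format.pval(x$p_q), x$I2))
  invisible(x)
}
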
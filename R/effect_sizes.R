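#' @title Effect-size conversions
#'
#' @description
#' Convert reported summary statistics into standardized mean differences
#' (Cohen's d) and correlation-scale effect sizes (r, Fisher z), following
#' the usual order of preference for two-group intervention studies:
#' (1) post-intervention means and SDs, (2) a two-group ANOVA F,
#' (3) a reported Cohen's d, (4) a t statistic or two-sided p value,
#' (5) pre-post change-score means and SDs.
#'
#' The sign convention throughout is that a positive effect means the
#' intervention group did better; outcome scales where lower scores are
#' better (e.g. depression inventories) must be sign-flipped upstream.
#'
#' @name effect_sizes
NULL

#' Cohen's d from post-intervention means and standard deviations
#'
#' Standardized mean difference with the pooled within-group SD,
#' \eqn{d = (m_t - m_c)/s_p} where
#' \eqn{s_p^2 = ((n_t-1) sd_t^2 + (n_c-1) sd_c^2)/(n_t+n_c-2)}.
#'
#' @param m_t,m_c Group means (treatment, control).
#' @param sd_t,sd_c Group standard deviations; must be positive.
#' @param n_t,n_c Group sizes; must be at least 2.
#' @return Cohen's d (numeric, vectorized).
#' @export
#' @examples
#' d_from_post_means(12.4, 10.1, 3.2, 2.8, 20, 18)
d_from_post_means <- function(m_t, m_c, sd_t, sd_c, n_t, n_c) {
  stopifnot(all(sd_t > 0), all(sd_c > 0), all(n_t >= 2), all(n_c >= 2))
  sp2 <- ((n_t - 1) * sd_t^2 + (n_c - 1) * sd_c^2) / (n_t + n_c - 2)
  if (any(sp2 <= 0))
    stop("degenerate input: pooled standard deviation is zero")
  (m_t - m_c) / sqrt(sp2)
}

#' Cohen's d from a two-group one-way ANOVA F statistic
#'
#' Uses the two-group equivalence \eqn{t = \sqrt{F}}, so
#' \eqn{d = sign \cdot \sqrt{F (n_t + n_c) / (n_t n_c)}}.  F carries no
#' direction; the sign must be supplied from the reported means or narrative.
#'
#' @param f F statistic (non-negative).
#' @param n_t,n_c Group sizes.
#' @param sign Direction of the effect, +1 or -1.
#' @return Cohen's d.
#' @export
d_from_f <- function(f, n_t, n_c, sign = 1) {
  stopifnot(all(f >= 0), all(sign %in% c(-1, 1)))
  sign * sqrt(f * (n_t + n_c) / (n_t * n_c))
}

#' Cohen's d from a two-sample t statistic
#'
#' \eqn{d = t \sqrt{1/n_t + 1/n_c}}.
#'
#' @param t t statistic (signed).
#' @param n_t,n_c Group sizes.
#' @return Cohen's d.
#' @export
d_from_t <- function(t, n_t, n_c) {
  t * sqrt(1 / n_t + 1 / n_c)
}

#' Cohen's d from a two-sided p value
#'
#' Inverts the central t distribution with \eqn{n_t + n_c - 2} degrees of
#' freedom at \eqn{p/2} (two-sided), then applies the t conversion with the
#' supplied sign.
#'
#' @param p Two-sided p value in (0, 1].
#' @param n_t,n_c Group sizes.
#' @param sign Direction of the effect, +1 or -1.
#' @return Cohen's d.
#' @export
d_from_p <- function(p, n_t, n_c, sign = 1) {
  stopifnot(all(p > 0), all(p <= 1), all(sign %in% c(-1, 1)))
  tq <- stats::qt(1 - p / 2, df = n_t + n_c - 2)
  sign * d_from_t(tq, n_t, n_c)
}

#' Cohen's d from pre-post change-score means and SDs
#'
#' Standardized mean difference of the change scores,
#' pooled-SD denominator as in \code{\link{d_from_post_means}}.
#'
#' @param diff_m_t,diff_m_c Mean pre-post change per group.
#' @param diff_sd_t,diff_sd_c SD of the change scores per group; positive.
#' @param n_t,n_c Group sizes.
#' @return Cohen's d.
#' @export
d_from_change_scores <- function(diff_m_t, diff_m_c, diff_sd_t, diff_sd_c,
                                 n_t, n_c) {
  d_from_post_means(diff_m_t, diff_m_c, diff_sd_t, diff_sd_c, n_t, n_c)
}

#' Morris pre-post-control effect size (d_ppc2)
#'
#' Pre-post-control design effect size standardized by the pooled
#' \emph{pre-test} SD, with Morris's small-sample correction
#' \eqn{c_p = 1 - 3/(4(n_t+n_c-2)-1)}:
#' \deqn{d = c_p \frac{(M_{post,t}-M_{pre,t}) - (M_{post,c}-M_{pre,c})}
#'   {SD_{pre,pooled}}.}
#' The sampling variance requires the pre-post correlation \eqn{\rho}; since
#' primary studies almost never report it, it must be supplied explicitly
#' (imputed from elsewhere if need be) -- there is no silent default.
#'
#' @param m_pre_t,m_post_t,m_pre_c,m_post_c Pre/post means per group.
#' @param sd_pre_t,sd_pre_c Pre-test SDs per group; positive.
#' @param n_t,n_c Group sizes.
#' @param rho_prepost Pre-post correlation in (-1, 1); required for the
#'   variance, and must be given -- a missing value is an error.
#' @return A list with components \code{d} and \code{var_d}.
#' @export
d_ppc2 <- function(m_pre_t, m_post_t, m_pre_c, m_post_c,
                   sd_pre_t, sd_pre_c, n_t, n_c, rho_prepost) {
  if (missing(rho_prepost) || is.null(rho_prepost) || anyNA(rho_prepost))
    stop("rho_prepost is required for d_ppc2; supply or impute it explicitly")
  stopifnot(all(abs(rho_prepost) < 1), all(sd_pre_t > 0), all(sd_pre_c > 0))
  df <- n_t + n_c - 2
  cp <- 1 - 3 / (4 * df - 1)
  sp <- sqrt(((n_t - 1) * sd_pre_t^2 + (n_c - 1) * sd_pre_c^2) / df)
  d <- cp * ((m_post_t - m_pre_t) - (m_post_c - m_pre_c)) / sp
  # Morris (2008): V = cp^2 (df/(df-2)) (A + d^2) - d^2,
  # A = 2(1-rho)(1/n_t + 1/n_c) is the variance of the unstandardized
  # change-score contrast in pre-SD units
  a <- 2 * (1 - rho_prepost) * (1 / n_t + 1 / n_c)
  var_d <- cp^2 * (df / (df - 2)) * (a + d^2) - d^2
  list(d = d, var_d = var_d)
}

#' Convert between d, r and Fisher z
#'
#' Standard Borenstein conversions for two-group designs with possibly
#' unequal group sizes: \eqn{r = d/\sqrt{d^2 + a}} with
#' \eqn{a = (n_t+n_c)^2/(n_t n_c)} (\eqn{a = 4} when groups are equal), and
#' the inverse \eqn{d = \sqrt{a}\, r/\sqrt{1-r^2}}.  \code{z_from_r} and
#' \code{r_from_z} are the Fisher transform pair; \code{var_z_n} is the
#' large-sample variance \eqn{1/(n-3)} of z.
#'
#' @param d Cohen's d.
#' @param r Correlation, strictly inside (-1, 1).
#' @param z Fisher z.
#' @param n Total sample size (at least 4 for \code{var_z_n}).
#' @param n_t,n_c Group sizes.
#' @return Numeric vector of the converted quantity.
#' @export
r_from_d <- function(d, n_t, n_c) {
  a <- (n_t + n_c)^2 / (n_t * n_c)
  d / sqrt(d^2 + a)
}

#' @rdname r_from_d
#' @export
d_from_r <- function(r, n_t = 1, n_c = 1) {
  stopifnot(all(abs(r) < 1))
  a <- (n_t + n_c)^2 / (n_t * n_c)
  sqrt(a) * r / sqrt(1 - r^2)
}

#' @rdname r_from_d
#' @export
z_from_r <- function(r) {
  stopifnot(all(abs(r) < 1))
  atanh(r)
}

#' @rdname r_from_d
#' @export
r_from_z <- function(z) tanh(z)

#' @rdname r_from_d
#' @export
var_z_n <- function(n) {
  stopifnot(all(n >= 4))
  1 / (n - 3)
}

#' Sampling variance of d and of a converted r
#'
#' \code{var_d_two_group} is the usual large-sample variance of Cohen's d,
#' \eqn{(n_t+n_c)/(n_t n_c) + d^2/(2(n_t+n_c))}.  \code{var_r_conversion}
#' propagates it through the d-to-r conversion,
#' \eqn{V_r = a^2 V_d / (d^2 + a)^3}; \code{var_z_conversion} further maps it
#' to the Fisher-z scale by the delta method, \eqn{V_z = V_r/(1-r^2)^2}.
#' On the z scale the chain collapses to the closed form
#' \eqn{V_z = (1 - r^2/2)/(n_t + n_c)}: near the Fisher \eqn{1/(n-3)} for
#' small effects, but smaller for large ones.
#'
#' @param d Cohen's d.
#' @param r Correlation in (-1, 1).
#' @param n_t,n_c Group sizes.
#' @param hedges_g Apply the Hedges small-sample correction to d before
#'   computing the variance (default \code{FALSE}).
#' @return Sampling variance (numeric, vectorized).
#' @export
var_d_two_group <- function(d, n_t, n_c) {
  (n_t + n_c) / (n_t * n_c) + d^2 / (2 * (n_t + n_c))
}

#' @rdname var_d_two_group
#' @export
var_r_conversion <- function(r, n_t, n_c, hedges_g = FALSE) {
  stopifnot(all(abs(r) < 1))
  a <- (n_t + n_c)^2 / (n_t * n_c)
  d <- d_from_r(r, n_t, n_c)
  if (hedges_g) d <- d * (1 - 3 / (4 * (n_t + n_c - 2) - 1))
  vd <- var_d_two_group(d, n_t, n_c)
  a^2 * vd / (d^2 + a)^3
}

#' @rdname var_d_two_group
#' @export
var_z_conversion <- function(r, n_t, n_c, hedges_g = FALSE) {
  var_r_conversion(r, n_t, n_c, hedges_g = hedges_g) / (1 - r^2)^2
}
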
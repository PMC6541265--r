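#' @title Outlier identification and sensitivity re-analysis
#' @name outliers
NULL

#' Interquartile-range outlier rule
#'
#' Flags study effects (on the correlation scale) lying more than 1.5 times
#' the interquartile range above the upper quartile or below the lower
#' quartile.  Quartiles use the linear-interpolation convention
#' (\code{quantile} type 7).
#'
#' @param studies Study-level data frame with \code{z} and \code{var_z}
#'   (and ideally \code{study_id}).
#' @param k_iqr Multiplier of the IQR (default 1.5).
#' @return Character vector of flagged study ids (possibly empty).
#' @export
detect_outliers_iqr <- function(studies, k_iqr = 1.5) {
  .check_studies(studies, k_min = 4L)
  r <- tanh(studies$z)
  q <- stats::quantile(r, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  flag <- r < q[1] - k_iqr * iqr | r > q[2] + k_iqr * iqr
  ids <- if (!is.null(studies$study_id)) studies$study_id else
    paste0("study_", seq_len(nrow(studies)))
  ids[flag]
}

#' Externally studentized deleted-residual outlier rule
#'
#' For each study, refits the random-effects model without it and
#' studentizes the deviation of the left-out effect from the leave-one-out
#' pooled estimate: \eqn{t_i = (z_i - \hat\mu_{(-i)}) /
#' \sqrt{v_i + \hat\tau^2_{(-i)} + se(\hat\mu_{(-i)})^2}}.  Studies with
#' \eqn{|t_i|} above \code{z_crit} are flagged.
#'
#' @param studies Study-level data frame with \code{z} and \code{var_z}.
#' @param z_crit Flagging threshold (default 1.96).
#' @param tau2_method Between-study variance estimator for the
#'   leave-one-out fits.
#' @return Character vector of flagged study ids; the residuals are
#'   attached as the \code{"residuals"} attribute.
#' @export
detect_outliers_deleted_residuals <- function(studies, z_crit = 1.96,
                                              tau2_method = "DL") {
  .check_studies(studies, k_min = 4L)
  k <- nrow(studies)
  tt <- vapply(seq_len(k), function(i) {
    fit <- pool_random_effects(studies[-i, , drop = FALSE], tau2_method)
    (studies$z[i] - fit$z_pooled) /
      sqrt(studies$var_z[i] + fit$tau2 + fit$se_z^2)
  }, numeric(1))
  ids <- if (!is.null(studies$study_id)) studies$study_id else
    paste0("study_", seq_len(k))
  out <- ids[abs(tt) > z_crit]
  attr(out, "residuals") <- stats::setNames(tt, ids)
  out
}

#' Sensitivity re-analysis with and without outliers
#'
#' Deterministically re-runs pooling and the full battery of small-study
#' diagnostics on the complete study set and on the set with the given
#' studies removed, as done when outliers are flagged.
#'
#' @param studies Study-level data frame (\code{ppi_studies}).
#' @param exclude Character vector of study ids to remove; excluding
#'   everything (or an unknown id) is an error.
#' @param tau2_method Between-study variance estimator.
#' @return List with components \code{full} and \code{reduced}, each a list
#'   with \code{pooled}, \code{egger}, \code{trimfill}, \code{top10},
#'   \code{limit}; plus \code{excluded}.
#' @export
sensitivity_rerun <- function(studies, exclude = character(0),
                              tau2_method = "DL") {
  .check_studies(studies)
  ids <- studies$study_id
  if (length(exclude)) {
    unknown <- setdiff(exclude, ids)
    if (length(unknown))
      stop("unknown study id(s): ", paste(unknown, collapse = ", "))
  }
  reduced <- studies[!(ids %in% exclude), , drop = FALSE]
  if (nrow(reduced) == 0) stop("cannot exclude every study")
  battery <- function(s) list(
    pooled = pool_random_effects(s, tau2_method),
    egger = egger_test(s),
    trimfill = trim_and_fill(s),
    top10 = suppressWarnings(top10(s)),
    limit = limit_meta(s, tau2_method))
  list(full = battery(studies),
       reduced = if (length(exclude)) battery(reduced) else NULL,
       excluded = exclude)
}
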
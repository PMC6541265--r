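#' @title Within-study aggregation of correlated effect sizes
#'
#' @description
#' Primary studies contribute several effect sizes: multiple outcome
#' measures per intervention arm, and multiple arms sharing one control
#' group.  Each study must enter the meta-analysis exactly once, so effects
#' are collapsed with the Schmidt-Hunter composite: the point estimate is the
#' arithmetic mean of the component effects and the sampling variance of the
#' composite is that of a mean of correlated estimates,
#' \deqn{V = \frac{1}{m^2} \sum_{i,j} \rho_{ij} \sqrt{V_i V_j},}
#' with the within-study correlation \eqn{\rho_{ij}} imputed at a default of
#' .50 for distinct effects (primary studies essentially never report it).
#'
#' @name aggregation
NULL

#' Composite of correlated effect estimates
#'
#' Mean of \code{es} with the correlated-composite variance.  With
#' \code{within_r = 1} and identical variances the composite variance equals
#' the single-effect variance (perfectly redundant outcomes); with
#' \code{within_r = 0} it is the variance of a mean of independent
#' estimates.
#'
#' @param es Effect estimates (any scale).
#' @param var Their sampling variances.
#' @param within_r Correlation imputed between distinct effects, in [0, 1].
#' @return List with \code{es}, \code{var} and \code{m} (component count).
#' @export
composite_effect <- function(es, var, within_r = 0.5) {
  m <- length(es)
  if (m == 0L) stop("empty effect list")
  stopifnot(length(var) == m, all(var > 0),
            within_r >= 0, within_r <= 1)
  if (m == 1L) return(list(es = es, var = var, m = 1L))
  s <- sqrt(var)
  cov_sum <- sum(outer(s, s)) - sum(var)   # off-diagonal sqrt(Vi Vj)
  list(es = mean(es),
       var = (sum(var) + within_r * cov_sum) / m^2,
       m = m)
}

#' Aggregate multiple outcome measures of one comparison
#'
#' Collapses the outcome measures of a single intervention-control
#' comparison into one correlation with its Fisher-z variance.  Averaging is
#' done on the Fisher-z scale; variances come from the d-to-r conversion
#' chain (\code{\link{var_z_conversion}}) by default.
#'
#' @param r Per-outcome correlations.
#' @param n_t,n_c Group sizes per outcome (recycled if scalar).  Outcomes of
#'   one comparison usually share them; a warning is issued otherwise and the
#'   row-level values are used.
#' @param within_r Imputed correlation between outcome measures.
#' @param var_method \code{"conversion"} (default) for the d-to-r chain, or
#'   \code{"fisher"} for the \eqn{1/(n-3)} shortcut.
#' @return List with \code{r}, \code{z}, \code{var_z}, \code{m}.
#' @export
aggregate_outcomes <- function(r, n_t, n_c, within_r = 0.5,
                               var_method = c("conversion", "fisher")) {
  var_method <- match.arg(var_method)
  m <- length(r)
  if (m == 0L) stop("empty effect list")
  n_t <- rep_len(n_t, m); n_c <- rep_len(n_c, m)
  if (length(unique(n_t + n_c)) > 1L)
    warning("outcomes with differing group sizes; using row-level n")
  v <- switch(var_method,
              conversion = var_z_conversion(r, n_t, n_c),
              fisher = var_z_n(n_t + n_c))
  cc <- composite_effect(atanh(r), v, within_r)
  list(r = tanh(cc$es), z = cc$es, var_z = cc$var, m = cc$m)
}

#' Aggregate intervention arms sharing one control group
#'
#' Collapses already outcome-aggregated arm effects into a single study
#' effect: the point estimate is the mean of the arm effects (on the z
#' scale) and the variance is the Schmidt-Hunter composite with the same
#' imputed correlation.  The reported \code{n_total} counts each treatment
#' group once and the shared control group once.
#'
#' @param z Arm effects on the Fisher-z scale.
#' @param var_z Arm variances.
#' @param n_t Treatment group size per arm.
#' @param n_c Control group size (shared; scalar or per-arm, counted once).
#' @param within_r Imputed correlation between arm effects.
#' @return List with \code{r}, \code{z}, \code{var_z}, \code{n_total}.
#' @export
aggregate_interventions <- function(z, var_z, n_t, n_c, within_r = 0.5) {
  cc <- composite_effect(z, var_z, within_r)
  list(r = tanh(cc$es), z = cc$es, var_z = cc$var,
       n_total = sum(n_t) + max(n_c))
}

#' Aggregate effect rows to one effect per study
#'
#' The full study-level reduction used by the replication pipeline.  Within
#' each study (after any merging done by \code{\link{apply_coding_rules}})
#' all effect rows are combined in a single Schmidt-Hunter composite with
#' imputed correlation \code{within_r} between every pair of distinct
#' effects.  Per-row Fisher-z variances come, by default, from the d-to-r
#' conversion chain with a shared-control correction: in a multi-arm study
#' the printed per-row totals count the common control group once per arm,
#' so the control size entering a row's variance is divided by the number of
#' arms of its article (the standard unit-of-analysis remedy for shared
#' groups).
#'
#' @param rows Effect rows, ideally after \code{\link{apply_coding_rules}}
#'   (an \code{article_id} column is respected; otherwise \code{study_id}
#'   is used as the article).
#' @param within_r Imputed within-study correlation (default .50).
#' @param var_method \code{"conversion"} (default) or \code{"fisher"}.
#' @param split_shared_control Divide each article's control group across
#'   its intervention arms when computing per-row variances (default TRUE).
#' @param hedges_g Apply the Hedges small-sample correction inside the
#'   conversion variance (default FALSE).
#' @return A \code{data.frame} of class \code{ppi_studies} with columns
#'   \code{study_id}, \code{r}, \code{z}, \code{var_z}, \code{n_eff}
#'   (variance-equivalent N, \eqn{3 + 1/var_z}), \code{n_total}
#'   (participants, shared controls counted once), \code{n_rows},
#'   \code{n_arms}; sorted by \code{study_id}.
#' @export
aggregate_studies <- function(rows, within_r = 0.5,
                              var_method = c("conversion", "fisher"),
                              split_shared_control = TRUE,
                              hedges_g = FALSE) {
  var_method <- match.arg(var_method)
  stopifnot(is.data.frame(rows), nrow(rows) > 0)
  if (anyNA(rows$r))
    stop("rows with missing r; run apply_coding_rules() first")
  if (is.null(rows$article_id)) rows$article_id <- rows$study_id

  # arms per article (distinct interventions sharing that article's control)
  arm_key <- paste(rows$article_id, rows$intervention, sep = "\r")
  n_arms_article <- tapply(rows$intervention, rows$article_id,
                           function(x) length(unique(x)))
  rows$.arms <- as.numeric(n_arms_article[rows$article_id])
  rows$.nce <- if (split_shared_control) rows$n_c / rows$.arms else rows$n_c

  out <- lapply(split(rows, rows$study_id), function(ds) {
    v <- switch(var_method,
                conversion = var_z_conversion(ds$r, ds$n_t, ds$.nce,
                                              hedges_g = hedges_g),
                fisher = var_z_n(ds$n_t + ds$.nce))
    cc <- composite_effect(atanh(ds$r), v, within_r)
    # participants: every treatment group once, each article's control once
    akey <- !duplicated(paste(ds$article_id, ds$intervention, sep = "\r"))
    ctrl <- tapply(ds$n_c, ds$article_id, max)
    data.frame(study_id = ds$study_id[1],
               r = tanh(cc$es), z = cc$es, var_z = cc$var,
               n_eff = 3 + 1 / cc$var,
               n_total = sum(ds$n_t[akey]) + sum(ctrl),
               n_rows = nrow(ds),
               n_arms = length(unique(arm_key[rows$study_id == ds$study_id[1]])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$study_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ppi_studies", "data.frame")
  out
}
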
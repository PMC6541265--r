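#' @title One-command replication of the five PPI meta-analyses
#' @name pipeline
NULL

#' Run one replication meta-analysis end to end
#'
#' Executes the full pipeline for one of the five bundled study sets (or any
#' effect-row table): coding rules (merging, exclusion of rows with no
#' computable effect), study-level aggregation, random-effects pooling,
#' small-study diagnostics (Egger, trim-and-fill, cumulative, TOP10, limit
#' meta-analysis), IQR outlier identification, and -- when outliers are
#' flagged -- the sensitivity re-run without them.
#'
#' @param dataset_id One of the ids in \code{\link{ppi_datasets}}, or a
#'   data frame of effect rows, or a path to an effect-table CSV.
#' @param within_r Imputed within-study correlation (default .50).
#' @param tau2_method Between-study variance estimator (default "DL").
#' @param var_method Per-row variance convention for aggregation
#'   (default "conversion").
#' @param split_shared_control,hedges_g Passed to
#'   \code{\link{aggregate_studies}}.
#' @param egger_weighted Use the weighted Egger variant (default FALSE).
#' @param limit_adjust Limit-meta adjustment variant
#'   (default "expectation").
#' @param rules Coding rules (default \code{\link{coding_rules}()}).
#' @param quiet Suppress coding-rule log messages (default TRUE).
#' @return An object of class \code{ppi_replication}: list with
#'   \code{dataset_id}, \code{rows}, \code{studies}, \code{pooled},
#'   \code{egger}, \code{trimfill}, \code{cumulative}, \code{top10},
#'   \code{limit}, \code{outliers}, \code{sensitivity}, \code{summary}
#'   (a one/two-row data frame in the layout of the published summary
#'   table: k, RE r with CI, funnel-asymmetry p, limit r with CI, limit d).
#' @export
run_replication <- function(dataset_id,
                            within_r = 0.5,
                            tau2_method = "DL",
                            var_method = "conversion",
                            split_shared_control = TRUE,
                            hedges_g = FALSE,
                            egger_weighted = FALSE,
                            limit_adjust = "expectation",
                            rules = coding_rules(),
                            quiet = TRUE) {
  if (is.data.frame(dataset_id)) {
    rows <- dataset_id; id <- "user_data"
  } else if (file.exists(dataset_id)) {
    rows <- read_effect_table(dataset_id); id <- basename(dataset_id)
  } else {
    rows <- read_effect_table(ppi_datasets(dataset_id)); id <- dataset_id
  }
  rows <- apply_coding_rules(rows, rules, quiet = quiet)
  studies <- aggregate_studies(rows, within_r = within_r,
                               var_method = var_method,
                               split_shared_control = split_shared_control,
                               hedges_g = hedges_g)
  pooled <- pool_random_effects(studies, tau2_method)
  egger <- egger_test(studies, weighted = egger_weighted)
  tf <- trim_and_fill(studies)
  cum <- cumulative_meta(studies, tau2_method)
  t10 <- suppressWarnings(top10(studies))
  lim <- limit_meta(studies, tau2_method, adjust = limit_adjust)
  outl <- detect_outliers_iqr(studies)
  sens <- if (length(outl))
    sensitivity_rerun(studies, exclude = outl, tau2_method) else NULL

  row_of <- function(p, e, l, k, label) data.frame(
    dataset = label, k = k,
    re_r = p$r_pooled, re_ci_low = p$ci_low, re_ci_high = p$ci_high,
    i2 = p$I2, egger_t = e$t_stat, egger_df = e$df, fat_p = e$p,
    lmt_r = l$r_limit, lmt_ci_low = l$ci_low, lmt_ci_high = l$ci_high,
    lmt_d = d_from_r(l$r_limit),
    stringsAsFactors = FALSE)
  summ <- row_of(pooled, egger, lim, nrow(studies), id)
  if (!is.null(sens)) {
    rp <- sens$reduced
    summ <- rbind(summ, row_of(rp$pooled, rp$egger, rp$limit,
                               nrow(studies) - length(outl),
                               paste0(id, " (w/o outliers)")))
  }
  structure(list(dataset_id = id, rows = rows, studies = studies,
                 pooled = pooled, egger = egger, trimfill = tf,
                 cumulative = cum, top10 = t10, limit = lim,
                 outliers = outl, sensitivity = sens, summary = summ,
                 options = list(within_r = within_r,
                                tau2_method = tau2_method,
                                var_method = var_method,
                                split_shared_control = split_shared_control,
                                hedges_g = hedges_g,
                                egger_weighted = egger_weighted,
                                limit_adjust = limit_adjust)),
            class = "ppi_replication")
}

#' @export
print.ppi_replication <- function(x, digits = 3, ...) {
  cat("Replication meta-analysis:", x$dataset_id, "\n\n")
  print(x$pooled, digits = digits)
  cat("\n"); print(x$egger, digits = digits)
  cat("\n"); print(x$trimfill, digits = digits)
  cat("\n"); print(x$limit, digits = digits)
  if (length(x$outliers))
    cat("\nIQR outliers:", paste(x$outliers, collapse = ", "), "\n")
  invisible(x)
}

#' Run all five replication meta-analyses
#'
#' @param ... Options passed to \code{\link{run_replication}}.
#' @return An object of class \code{ppi_report}: list of the five
#'   \code{ppi_replication} objects plus a \code{summary} data frame (one
#'   row per dataset, plus without-outlier rows where the IQR rule flags
#'   studies).
#' @export
run_all <- function(...) {
  reg <- ppi_datasets()
  runs <- lapply(reg$dataset_id, run_replication, ...)
  names(runs) <- reg$dataset_id
  summ <- do.call(rbind, lapply(runs, `[[`, "summary"))
  rownames(summ) <- NULL
  structure(list(runs = runs, summary = summ), class = "ppi_report")
}

#' @export
print.ppi_report <- function(x, digits = 2, ...) {
  s <- x$summary
  cat("Summary of replication meta-analyses\n")
  out <- data.frame(dataset = s$dataset, k = s$k,
                    `RE r (CI)` = sprintf("%.2f (%.2f, %.2f)", s$re_r,
                                          s$re_ci_low, s$re_ci_high),
                    `I2` = sprintf("%.1f%%", s$i2),
                    `FAT p` = sprintf("%.3f", s$fat_p),
                    `LMT r (CI)` = sprintf("%.2f (%.2f, %.2f)", s$lmt_r,
                                           s$lmt_ci_low, s$lmt_ci_high),
                    `LMT d` = sprintf("%.2f", s$lmt_d),
                    check.names = FALSE)
  print(out, row.names = FALSE)
  invisible(x)
}

#' Serialize a report to JSON and CSV
#'
#' Writes \code{summary.csv}, \code{summary.json} (with full option
#' provenance) and per-dataset tidy funnel/forest data
#' (\code{funnel_<id>.csv}) into a directory.  Outputs are byte-stable
#' across repeated runs on the same inputs.
#'
#' @param report A \code{ppi_report} or \code{ppi_replication}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  runs <- if (inherits(report, "ppi_report")) report$runs else
    stats::setNames(list(report), report$dataset_id)
  summ <- do.call(rbind, lapply(runs, `[[`, "summary"))
  rownames(summ) <- NULL
  utils::write.csv(summ, file.path(dir, "summary.csv"), row.names = FALSE)
  payload <- list(
    summary = summ,
    options = lapply(runs, `[[`, "options"),
    outliers = lapply(runs, `[[`, "outliers"))
  jsonlite::write_json(payload, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (id in names(runs)) {
    fd <- funnel_data(runs[[id]]$studies, trimfill = runs[[id]]$trimfill,
                      limit = runs[[id]]$limit)
    utils::write.csv(fd, file.path(dir, paste0("funnel_", id, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Sweep estimator variants against one dataset
#'
#' Documents how the pooled and bias-adjusted estimates change across the
#' analysis choices the source analyses leave unstated: the tau-squared
#' estimator, the per-row variance convention, the shared-control
#' correction, the Hedges correction, and the Egger variant.
#'
#' @param dataset_id As in \code{\link{run_replication}}.
#' @param tau2_methods,var_methods,split_options,hedges_options Vectors of
#'   variants to cross.
#' @return Data frame with one row per variant combination: the options and
#'   the resulting k, RE r, CI, I2, Egger t, limit r.
#' @export
estimator_sweep <- function(dataset_id,
                            tau2_methods = c("DL", "PM", "REML"),
                            var_methods = c("conversion", "fisher"),
                            split_options = c(TRUE, FALSE),
                            hedges_options = FALSE) {
  grid <- expand.grid(tau2_method = tau2_methods, var_method = var_methods,
                      split = split_options, hedges = hedges_options,
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    r <- run_replication(dataset_id, tau2_method = g$tau2_method,
                         var_method = g$var_method,
                         split_shared_control = g$split,
                         hedges_g = g$hedges)
    cbind(g, r$summary[1, c("k", "re_r", "re_ci_low", "re_ci_high", "i2",
                            "egger_t", "lmt_r")],
          row.names = NULL)
  })
  do.call(rbind, out)
}
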
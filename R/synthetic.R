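#' @title Synthetic meta-analytic data with the structure the pipeline
#'   assumes
#'
#' @description
#' Generates per-outcome effect tables (the same CSV schema as the bundled
#' fixtures, so synthetic data flows through the identical pipeline) from a
#' known truth: study-specific true effects on the Fisher-z scale with
#' between-study SD \eqn{\tau}, skewed (log-normal) group sizes so that most
#' studies are small and a few are large, multiple correlated outcomes per
#' study, multiple intervention arms sharing one control group, and an
#' optional selection-for-significance mechanism that induces funnel
#' asymmetry by re-drawing non-significant studies (censor-and-redraw, so k
#' stays fixed; truncation mode drops them instead).
#'
#' @name synthetic_data
NULL

#' Configuration for the synthetic-data generator
#'
#' @param k Number of studies.
#' @param mu_z True mean effect on the Fisher-z scale.
#' @param tau Between-study SD of true effects on the z scale.
#' @param n_meanlog,n_sdlog Log-normal parameters of the per-group size
#'   distribution.  The defaults (median 25 per group, sdlog 0.9) are
#'   calibrated to the group sizes observed across the bundled PPI study
#'   sets (median 26, sdlog 0.92): many small studies, a few large ones.
#'   Sizes are rounded and floored at \code{n_min}.
#' @param n_min Minimum group size (default 5).
#' @param m_outcomes Outcome measures per arm.
#' @param within_r True correlation between outcome estimates within a
#'   study (default .50).
#' @param n_arms Intervention arms sharing one control group.
#' @param selection Strength in [0, 1] of one-sided
#'   publish-if-significant censoring: a study whose two-sided p exceeds
#'   .05 (or whose effect is negative) is re-drawn with this probability.
#' @param selection_mode \code{"redraw"} (default; keeps k fixed) or
#'   \code{"truncate"} (drops censored studies, variable k).
#' @param seed Integer seed; the same seed yields a bit-identical dataset.
#' @return A list of class \code{ppi_synth_config}.
#' @export
synthetic_config <- function(k = 40, mu_z = 0.15, tau = 0.10,
                             n_meanlog = log(25), n_sdlog = 0.9, n_min = 5,
                             m_outcomes = 1, within_r = 0.5, n_arms = 1,
                             selection = 0,
                             selection_mode = c("redraw", "truncate"),
                             seed = 1L) {
  selection_mode <- match.arg(selection_mode)
  stopifnot(k >= 1, tau >= 0, is.finite(mu_z), is.finite(tau),
            m_outcomes >= 1, n_arms >= 1,
            within_r >= 0, within_r < 1,
            selection >= 0, selection <= 1)
  structure(as.list(environment()), class = "ppi_synth_config")
}

# draw one study (all arms x outcomes) given its true effect; returns
# parallel vectors, assembled into a data frame only once per dataset
.draw_study <- function(cfg, theta) {
  n_c <- max(cfg$n_min, round(stats::rlnorm(1, cfg$n_meanlog, cfg$n_sdlog)))
  n_t <- pmax(cfg$n_min,
              round(stats::rlnorm(cfg$n_arms, cfg$n_meanlog, cfg$n_sdlog)))
  m <- cfg$m_outcomes
  arm <- rep(seq_len(cfg$n_arms), each = m)
  n_tot <- n_t[arm] + n_c
  v <- 1 / (n_tot - 3)
  # equicorrelated deviates per arm: z_j = theta + sqrt(v) e_j,
  # cor(e_j, e_l) = within_r within an arm
  shared <- stats::rnorm(cfg$n_arms)[arm]
  eps <- sqrt(cfg$within_r) * shared +
    sqrt(1 - cfg$within_r) * stats::rnorm(length(arm))
  list(arm = arm, outcome = rep(seq_len(m), cfg$n_arms),
       n_t = n_t[arm], n_c = n_c, n_total = n_tot,
       r = tanh(theta + sqrt(v) * eps))
}

# two-sided p of the study's composite effect
.study_p <- function(cfg, st) {
  v <- 1 / (st$n_total - 3)
  cc <- composite_effect(atanh(st$r), v, cfg$within_r)
  2 * stats::pnorm(-abs(cc$es / sqrt(cc$var)))
}

#' Generate a synthetic per-outcome effect table
#'
#' @param config A \code{\link{synthetic_config}}.
#' @return Effect rows in the standard schema (validating under
#'   \code{\link{validate_effect_rows}}), with the per-study true effects
#'   attached as attribute \code{"theta"} and the config as attribute
#'   \code{"config"}.
#' @export
generate_meta_dataset <- function(config) {
  stopifnot(inherits(config, "ppi_synth_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  kept <- vector("list", config$k); thetas <- numeric(0)
  for (i in seq_len(config$k)) {
    for (attempt in seq_len(1000)) {
      theta <- stats::rnorm(1, config$mu_z, config$tau)
      st <- .draw_study(config, theta)
      if (config$selection == 0) break
      sig <- .study_p(config, st) < 0.05 && mean(atanh(st$r)) > 0
      if (sig) break
      if (stats::runif(1) > config$selection) break   # slips through
      if (config$selection_mode == "truncate") { st <- NULL; break }
    }
    if (!is.null(st)) {
      st$study_id <- sprintf("Synth.%04d.1", i)
      kept[[i]] <- st
      thetas <- c(thetas, theta)
    }
  }
  kept <- kept[!vapply(kept, is.null, logical(1))]
  pull <- function(f) unlist(lapply(kept, `[[`, f), use.names = FALSE)
  rows <- data.frame(
    study_id = rep(vapply(kept, `[[`, "", "study_id"),
                   vapply(kept, function(s) length(s$r), integer(1))),
    available_data = "post-msds",
    measure = paste0("outcome_", pull("outcome")),
    intervention = paste0("arm_", pull("arm")),
    n_t = pull("n_t"),
    n_c = rep(vapply(kept, `[[`, 0, "n_c"),
              vapply(kept, function(s) length(s$r), integer(1))),
    n_total = pull("n_total"),
    r = pull("r"), stringsAsFactors = FALSE)
  validate_effect_rows(rows)
  attr(rows, "theta") <- thetas
  attr(rows, "config") <- config
  rows
}
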
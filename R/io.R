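#' @title Effect tables: schema, readers, writers, coding rules
#'
#' @description
#' The unit record of the pipeline is one outcome measure of one intervention
#' arm of one primary study ("effect row").  The CSV schema is
#' \code{study_id, available_data, measure, intervention, n_t, n_c, n_total, r}
#' where \code{available_data} codes what the primary study reported (e.g.
#' \code{post-msds}, \code{post-anovaF}, \code{prepost-difmsds}) and \code{r}
#' is the correlation-scale effect size, \code{NA} when the study reported
#' too little to compute one.
#'
#' @name effect_tables
NULL

.effect_cols <- c("study_id", "available_data", "measure", "intervention",
                  "n_t", "n_c", "n_total", "r")

.available_data_levels <- c(
  "post-msds", "post-anovaF", "post-tpvalue", "post-cohend",
  "prepost-msds", "prepost-difmsds", "prepost-ancovaF", "prepost-nomsnosds")

#' Read a per-outcome effect table
#'
#' Reads and validates a CSV of effect rows.  \code{NA} cells are parsed as
#' missing; rows violating \code{n_total == n_t + n_c} or with malformed
#' numeric cells raise an error naming the offending row.
#'
#' @param path Path to a CSV file with the effect-row header.
#' @return A \code{data.frame} of effect rows, in file order.
#' @export
read_effect_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(study_id = "character",
                                      available_data = "character",
                                      measure = "character",
                                      intervention = "character",
                                      n_t = "character", n_c = "character",
                                      n_total = "character", r = "character"))
  if (!identical(names(d), .effect_cols))
    stop("unexpected header in ", path, ": need ",
         paste(.effect_cols, collapse = ","))
  for (col in c("n_t", "n_c", "n_total", "r")) {
    raw <- trimws(d[[col]])
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "NA" & raw != "" & is.na(num))
    if (length(bad))
      stop("malformed numeric cell in column '", col, "', row ", bad[1],
           " (", d$study_id[bad[1]], "): '", raw[bad[1]], "'")
    d[[col]] <- num
  }
  validate_effect_rows(d)
  d
}

#' Validate a set of effect rows
#'
#' Checks the schema, the \code{n_total = n_t + n_c} identity, the range of
#' \code{r}, and uniqueness of (study_id, measure, intervention) triples.
#'
#' @param rows Effect-row data frame.
#' @return The rows, invisibly, if valid; otherwise an error.
#' @export
validate_effect_rows <- function(rows) {
  stopifnot(is.data.frame(rows))
  miss <- setdiff(.effect_cols, names(rows))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  ok <- is.na(rows$n_total) | is.na(rows$n_t) | is.na(rows$n_c) |
    rows$n_total == rows$n_t + rows$n_c
  if (!all(ok))
    stop("n_t + n_c != n_total in row ", which(!ok)[1],
         " (", rows$study_id[which(!ok)[1]], ")")
  if (any(abs(rows$r) >= 1, na.rm = TRUE))
    stop("effect size r outside (-1, 1) in row ",
         which(abs(rows$r) >= 1)[1])
  key <- paste(rows$study_id, rows$measure, rows$intervention, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (study_id, measure, intervention) triple in row ",
         anyDuplicated(key))
  invisible(rows)
}

#' Write a per-outcome effect table
#'
#' Inverse of \code{\link{read_effect_table}}; \code{read(write(x))} returns
#' the same rows.
#'
#' @param rows Effect-row data frame.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_effect_table <- function(rows, path) {
  validate_effect_rows(rows)
  utils::write.csv(rows[.effect_cols], path, row.names = FALSE, na = "NA",
                   quote = which(.effect_cols %in%
                                   c("measure", "intervention")))
  invisible(path)
}

#' Coding rules for effect rows
#'
#' A coding configuration bundles (a) a study-merging map for articles that
#' report different arms of one underlying study under different ids, (b)
#' whether to impute group sizes by equal split when only \code{n_total}
#' is reported, and (c) whether to drop rows whose effect size could not be
#' computed (\code{r} missing).
#'
#' The default merging map joins the four Mongrain-family articles, which
#' report on conditions of a single study, under one id.
#'
#' @param merge Named character vector mapping article ids to a common
#'   study id.
#' @param impute_group_sizes Impute \code{n_t}/\code{n_c} by equal split of
#'   \code{n_total} (odd participant to the treatment group).
#' @param drop_missing_r Drop (and log) rows with missing \code{r}.
#' @return An object of class \code{ppi_coding_rules}.
#' @export
coding_rules <- function(merge = mongrain_merge_map(),
                         impute_group_sizes = TRUE,
                         drop_missing_r = TRUE) {
  stopifnot(is.null(merge) ||
              (is.character(merge) && !is.null(names(merge))))
  structure(list(merge = merge,
                 impute_group_sizes = impute_group_sizes,
                 drop_missing_r = drop_missing_r),
            class = "ppi_coding_rules")
}

#' @rdname coding_rules
#' @export
mongrain_merge_map <- function() {
  c(Mongrain.2011.1 = "Mongrain.combined",
    Mongrain.2012.1 = "Mongrain.combined",
    Shapira.2010.1  = "Mongrain.combined",
    Sergeant.2011.1 = "Mongrain.combined")
}

#' Read coding rules from a JSON file
#'
#' JSON object with optional fields \code{merge} (object of
#' article-id/study-id pairs), \code{impute_group_sizes}, and
#' \code{drop_missing_r}.
#'
#' @param path Path to a JSON file.
#' @return A \code{ppi_coding_rules} object.
#' @export
read_coding_rules <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  coding_rules(
    merge = if (is.null(x$merge)) NULL else unlist(x$merge),
    impute_group_sizes = isTRUE(x$impute_group_sizes %||% TRUE),
    drop_missing_r = isTRUE(x$drop_missing_r %||% TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply coding rules to effect rows
#'
#' Imputes missing group sizes by equal split of the overall sample size
#' (remainder to the treatment group), relabels merged studies while keeping
#' the original article id in an \code{article_id} column (so that a shared
#' control group is still attributed to its own article), and removes rows
#' whose effect size is missing and cannot be recovered.  Every imputation
#' and exclusion is logged via \code{message()} and recorded in the
#' \code{"exclusions"} / \code{"imputations"} attributes of the result.
#'
#' @param rows Effect-row data frame.
#' @param rules A \code{\link{coding_rules}} object.
#' @param quiet Suppress log messages.
#' @return The recoded rows with an added \code{article_id} column.
#' @export
apply_coding_rules <- function(rows, rules = coding_rules(), quiet = FALSE) {
  stopifnot(inherits(rules, "ppi_coding_rules"))
  validate_effect_rows(rows)
  out <- rows
  out$article_id <- out$study_id
  log1 <- character(0)

  if (isTRUE(rules$impute_group_sizes)) {
    idx <- which(is.na(out$n_t) & is.na(out$n_c) & !is.na(out$n_total))
    if (length(idx)) {
      out$n_t[idx] <- ceiling(out$n_total[idx] / 2)
      out$n_c[idx] <- out$n_total[idx] - out$n_t[idx]
      log1 <- sprintf("imputed equal-split group sizes for %s (%s)",
                      out$study_id[idx], out$measure[idx])
    }
  }

  if (!is.null(rules$merge)) {
    # map entries naming studies absent from this table are ignored: one
    # merging map serves all five study sets
    hit <- out$study_id %in% names(rules$merge)
    out$study_id[hit] <- unname(rules$merge[out$study_id[hit]])
  }

  excl <- character(0)
  if (isTRUE(rules$drop_missing_r)) {
    drop <- is.na(out$r)
    if (any(drop)) {
      excl <- sprintf("excluded %s / %s / %s: no computable effect size (%s)",
                      out$article_id[drop], out$intervention[drop],
                      out$measure[drop], out$available_data[drop])
      out <- out[!drop, , drop = FALSE]
    }
  }
  if (!quiet) for (m in c(log1, excl)) message(m)
  rownames(out) <- NULL
  attr(out, "imputations") <- log1
  attr(out, "exclusions") <- excl
  out
}

#' Bundled replication datasets
#'
#' The five per-outcome effect tables shipped with the package, transcribed
#' from the replication study's printed tables: the Sin & Lyubomirsky (2009)
#' well-being and depression study sets and the Bolier et al. (2013)
#' subjective well-being, psychological well-being and depression study sets.
#'
#' @param dataset_id One of \code{"SL2009_wb"}, \code{"SL2009_dep"},
#'   \code{"B2013_swb"}, \code{"B2013_pwb"}, \code{"B2013_dep"}; if missing,
#'   the registry of all five is returned.
#' @return For a given id, the path to the fixture CSV; otherwise a
#'   data.frame registry with the expected study count per dataset.
#' @export
ppi_datasets <- function(dataset_id) {
  reg <- data.frame(
    dataset_id = c("SL2009_wb", "SL2009_dep", "B2013_swb", "B2013_pwb",
                   "B2013_dep"),
    label = c("Sin & Lyubomirsky 2009: well-being",
              "Sin & Lyubomirsky 2009: depression",
              "Bolier et al. 2013: subjective well-being",
              "Bolier et al. 2013: psychological well-being",
              "Bolier et al. 2013: depression"),
    file = c("sl2009_wellbeing.csv", "sl2009_depression.csv",
             "b2013_swb.csv", "b2013_pwb.csv", "b2013_depression.csv"),
    k_expected = c(40L, 21L, 25L, 17L, 14L),
    stringsAsFactors = FALSE)
  if (missing(dataset_id)) return(reg)
  i <- match(dataset_id, reg$dataset_id)
  if (is.na(i)) stop("unknown dataset_id: ", dataset_id)
  path <- system.file("extdata", reg$file[i], package = "ppimeta")
  if (!nzchar(path)) stop("fixture not found: ", reg$file[i])
  path
}
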
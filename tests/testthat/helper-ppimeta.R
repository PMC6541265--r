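# small builders used across the suite

toy_studies <- function(z, n, ids = sprintf("Toy.%02d.1", seq_along(z))) {
  data.frame(study_id = ids, r = tanh(z), z = z, var_z = 1 / (n - 3),
             stringsAsFactors = FALSE)
}

# funnel symmetric by construction: mirrored effect pairs at equal precision
mirrored_studies <- function(center = 0.2, spread = c(.05, .1, .2, .3),
                             n = c(200, 100, 50, 20)) {
  z <- c(center + spread, center - spread)
  toy_studies(z, rep(n, 2))
}

# aggregate a bundled dataset with the package defaults
aggregate_fixture <- function(dataset_id, ...) {
  rows <- read_effect_table(ppi_datasets(dataset_id))
  rows <- apply_coding_rules(rows, quiet = TRUE)
  aggregate_studies(rows, ...)
}
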
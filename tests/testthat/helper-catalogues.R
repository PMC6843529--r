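# Shared fixtures: the bundled published catalogues, loaded once per run.
drugs_fx <- load_drug_catalog()
fees_fx <- load_fee_schedule()
regimens_fx <- load_regimens(drugs = drugs_fx)
published_fx <- load_published_options()

regimen_by_label <- function(label) {
  regimens_fx[regimens_fx$label == label, , drop = FALSE]
}

published_cell <- function(label, duration) {
  o <- published_fx$options
  o[o$regimen_label == label & o$duration_months == duration, , drop = FALSE]
}

# Independent weighted-moment oracle: plain arithmetic on the raw fixture
# CSV, bypassing the option_set/analytic_moments path entirely.
oracle_moments <- function(values, weights) {
  m <- sum(weights * values)
  list(mean = m, variance = sum(weights * values^2) - m^2)
}

raw_published <- utils::read.csv(macpd_extdata("options_published.csv"))

# Writes a tiny catalogue CSV for parse-error tests.
write_temp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
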
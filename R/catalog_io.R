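# Frequency-role tags a fee item may carry; each maps to exactly one counter
# produced by build_schedule() (or to the constant 1 / the unbilled ECG).
FREQUENCY_ROLES <- c(
  "per_quarter_gp", "per_quarter_pneumo", "once", "per_sputum_sample",
  "per_xray", "per_ophtha_visit", "per_ct", "per_lab_visit",
  "per_audiometry", "per_amk_level", "zero_billable"
)

PAYER_GROUPS <- c(
  "general_practitioner", "pneumologist", "methods", "microbiology",
  "laboratory"
)

REGIMEN_CATEGORIES <- c("macrolide_susceptible", "macrolide_resistant", "severe")

#' Path to a bundled catalogue fixture
#'
#' The package ships the published price, fee, regimen and option catalogues
#' as plain CSV under `extdata`.
#'
#' @param file file name, e.g. `"drugs.csv"`, `"fees.csv"`, `"regimens.csv"`,
#'   `"options_published.csv"`.
#' @return absolute path to the installed fixture.
#' @export
macpd_extdata <- function(file) {
  path <- system.file("extdata", file, package = "macpdcost")
  if (!nzchar(path)) stop("no bundled fixture named '", file, "'", call. = FALSE)
  path
}

read_catalog_csv <- function(path, required, numeric_cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                         strip.white = TRUE, fileEncoding = "UTF-8")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("schema error in ", basename(path), ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in numeric_cols) {
    parsed <- parse_euro(raw[[col]])
    bad <- which(is.na(parsed) & !is.na(raw[[col]]) & raw[[col]] != "" &
                   toupper(raw[[col]]) != "NA")
    if (length(bad)) {
      stop("parse error in ", basename(path), ", column '", col, "', line ",
           bad[1] + 1L, ": '", raw[[col]][bad[1]], "' is not numeric",
           call. = FALSE)
    }
    raw[[col]] <- parsed
  }
  raw
}

#' Load a drug price catalogue
#'
#' Reads a CSV with columns `name`, `abbreviation`, `pack_price`,
#' `pack_quantity`, `daily_intake` (pharmacy retail pack price in EUR, units
#' per pack, units taken per day). Validates positivity and uniqueness of the
#' abbreviation.
#'
#' @param path CSV path; defaults to the bundled published catalogue.
#' @return a `drug_catalog` data frame, one row per purchasable product.
#' @examples
#' drugs <- load_drug_catalog()
#' drugs[drugs$abbreviation == "AMK", ]
#' @export
load_drug_catalog <- function(path = macpd_extdata("drugs.csv")) {
  d <- read_catalog_csv(
    path,
    required = c("name", "abbreviation", "pack_price", "pack_quantity",
                 "daily_intake"),
    numeric_cols = c("pack_price", "pack_quantity", "daily_intake")
  )
  dup <- d$abbreviation[duplicated(d$abbreviation)]
  if (length(dup)) {
    stop("schema error: duplicated drug abbreviation(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (any(d$pack_price < 0)) stop("parse error: negative pack_price", call. = FALSE)
  if (nrow(d) && any(d$pack_quantity <= 0 | d$daily_intake <= 0)) {
    stop("schema error: pack_quantity and daily_intake must be > 0", call. = FALSE)
  }
  class(d) <- c("drug_catalog", "data.frame")
  d
}

#' Load an outpatient fee schedule
#'
#' Reads a CSV of fee-schedule lines (`service_name`, `code`, `payer_group`,
#' `points`, `unit_price`, `frequency_role`). The `frequency_role` tag links
#' each item to the schedule counter that drives how often it is billed;
#' `zero_billable` marks services that cannot be charged separately (billed
#' at EUR 0.00 regardless of count).
#'
#' @param path CSV path; defaults to the bundled published fee schedule.
#' @return a `fee_schedule` data frame.
#' @export
load_fee_schedule <- function(path = macpd_extdata("fees.csv")) {
  d <- read_catalog_csv(
    path,
    required = c("service_name", "code", "payer_group", "points", "unit_price",
                 "frequency_role"),
    numeric_cols = c("points", "unit_price")
  )
  unknown <- setdiff(unique(d$frequency_role), FREQUENCY_ROLES)
  if (length(unknown)) {
    stop("schema error: unknown frequency_role tag(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  unknown_payer <- setdiff(unique(d$payer_group), PAYER_GROUPS)
  if (length(unknown_payer)) {
    stop("schema error: unknown payer_group(s): ",
         paste(unknown_payer, collapse = ", "), call. = FALSE)
  }
  if (any(d$unit_price < 0)) stop("parse error: negative unit_price", call. = FALSE)
  class(d) <- c("fee_schedule", "data.frame")
  d
}

#' Load the regimen definitions
#'
#' Ten regimens: four macrolide-susceptible triples (no IV component), two
#' macrolide-resistant and four severe regimens, each with a 60-day IV
#' amikacin component. Oral drugs are referenced by catalogue abbreviation,
#' separated by `;`.
#'
#' @param path CSV path; defaults to the bundled definitions.
#' @param drugs drug catalogue the oral/IV references must resolve against.
#' @return a `regimen_table` data frame with list-column `oral`.
#' @export
load_regimens <- function(path = macpd_extdata("regimens.csv"),
                          drugs = load_drug_catalog()) {
  d <- read_catalog_csv(
    path,
    required = c("label", "category", "oral_drugs", "iv_drug", "iv_days"),
    numeric_cols = "iv_days"
  )
  bad_cat <- setdiff(unique(d$category), REGIMEN_CATEGORIES)
  if (length(bad_cat)) {
    stop("schema error: unknown regimen category: ",
         paste(bad_cat, collapse = ", "), call. = FALSE)
  }
  d$oral <- strsplit(d$oral_drugs, ";", fixed = TRUE)
  d$iv_drug[is.na(d$iv_drug) | d$iv_drug == ""] <- NA_character_
  d$iv_days[is.na(d$iv_days)] <- 0
  refs <- unique(c(unlist(d$oral), d$iv_drug[!is.na(d$iv_drug)]))
  unresolved <- setdiff(refs, drugs$abbreviation)
  if (length(unresolved)) {
    stop("schema error: regimen references unknown drug(s): ",
         paste(unresolved, collapse = ", "), call. = FALSE)
  }
  susceptible <- d$category == "macrolide_susceptible"
  if (any(susceptible & !is.na(d$iv_drug))) {
    stop("schema error: macrolide-susceptible regimens must not carry an IV component",
         call. = FALSE)
  }
  if (any(!susceptible & is.na(d$iv_drug))) {
    stop("schema error: macrolide-resistant and severe regimens require an IV component",
         call. = FALSE)
  }
  class(d) <- c("regimen_table", "data.frame")
  d
}

#' Probability weights over the treatment-option space
#'
#' 84% of patients are assumed treatable without IV amikacin; that mass is
#' split evenly over the 8 macrolide-susceptible regimen-by-duration cells
#' (0.84/8 = 0.105 each). The remaining 16% is split evenly over the 12
#' amikacin cells (0.16/12 each).
#'
#' @param p_no_amk probability of treatment without amikacin (default 0.84).
#' @param p_amk complement (default 0.16).
#' @param n_susceptible_options number of macrolide-susceptible cells (8).
#' @param n_amk_options number of amikacin cells (12).
#' @return a `weight_config` list.
#' @export
weight_config <- function(p_no_amk = 0.84, p_amk = 0.16,
                          n_susceptible_options = 8L, n_amk_options = 12L) {
  if (abs(p_no_amk + p_amk - 1) > 1e-12) {
    stop("p_no_amk + p_amk must equal 1 (got ", p_no_amk + p_amk, ")",
         call. = FALSE)
  }
  if (p_no_amk < 0 || p_amk < 0) stop("probabilities must be non-negative", call. = FALSE)
  structure(
    list(p_no_amk = p_no_amk, p_amk = p_amk,
         n_susceptible_options = as.integer(n_susceptible_options),
         n_amk_options = as.integer(n_amk_options)),
    class = "weight_config"
  )
}

#' Load the published 20-option cost table
#'
#' Reads the as-published option table verbatim: 10 regimens at two treatment
#' durations with their printed per-day, per-course drug, monitoring and total
#' costs plus probability weights. The published table contains internal
#' arithmetic inconsistencies which are preserved deliberately, so
#' `total_cost == drug_cost + monitoring_cost` is NOT enforced here; only the
#' weight-sum invariant is.
#'
#' @param path CSV path; defaults to the bundled published table.
#' @param weights `weight_config` the table is validated against.
#' @return an `option_set` (see [enumerate_options()]) with mode
#'   `"as_published"`.
#' @export
load_published_options <- function(path = macpd_extdata("options_published.csv"),
                                   weights = weight_config()) {
  d <- read_catalog_csv(
    path,
    required = c("regimen_label", "category", "duration_months",
                 "daily_drug_cost", "drug_cost", "monitoring_cost",
                 "total_cost", "weight"),
    numeric_cols = c("duration_months", "daily_drug_cost", "drug_cost",
                     "monitoring_cost", "total_cost", "weight")
  )
  if (abs(sum(d$weight) - 1) > 1e-9) {
    stop("validation error: option weights sum to ", sum(d$weight),
         ", expected 1 within 1e-9", call. = FALSE)
  }
  new_option_set(d, mode = "as_published", weights = weights)
}

#' Default DRG parameters for the non-surgical NTM hospital stay
#'
#' The national base rate and the cost weight of DRG E76C (tuberculosis/NTM
#' without severe complications), the group's mean length of stay, and the
#' 14-day cap up to which the flat case payment applies.
#'
#' @param base_rate national base rate, EUR per case.
#' @param cost_weight dimensionless relative weight of the DRG.
#' @param mean_length_of_stay mean stay in days.
#' @param cap_days stay cap in days for the flat payment.
#' @return a `drg_parameters` list.
#' @export
drg_parameters <- function(base_rate = 3544.97, cost_weight = 0.937,
                           mean_length_of_stay = 6.4, cap_days = 14L) {
  vals <- c(base_rate, cost_weight, mean_length_of_stay, cap_days)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all DRG parameters must be strictly positive", call. = FALSE)
  }
  structure(
    list(base_rate = base_rate, cost_weight = cost_weight,
         mean_length_of_stay = mean_length_of_stay,
         cap_days = as.integer(cap_days)),
    class = "drg_parameters"
  )
}

#' Write a report object to disk
#'
#' Serializes a summary object (simulation result, intersectoral report, or
#' any flat named list / data frame) as delimited CSV or structured JSON.
#' Round-trips to the cent: [read_report()] on the output reproduces the
#' values exactly. Non-finite fields are refused rather than silently coerced.
#'
#' @param result object to serialize.
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, format = c("csv", "json")) {
  format <- match.arg(format)
  flat <- if (is.data.frame(result)) result else as_report_list(result)
  nums <- unlist(Filter(is.numeric, if (is.data.frame(flat)) as.list(flat) else flat))
  if (length(nums) && any(!is.finite(nums))) {
    stop("serialization error: report contains non-finite numeric field(s)",
         call. = FALSE)
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("I/O error: directory does not exist: ", dir, call. = FALSE)
  if (format == "csv") {
    df <- if (is.data.frame(flat)) flat else
      data.frame(field = names(flat),
                 value = vapply(flat, function(v) as.character(v)[1], ""),
                 stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read back a report written by [write_report()]
#'
#' @param path file path.
#' @param format `"csv"` or `"json"`.
#' @return for CSV, a data frame; for JSON, a named list with numeric fields
#'   restored.
#' @export
read_report <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("I/O error: file not found: ", path, call. = FALSE)
  if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

as_report_list <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    x[vapply(x, function(v) is.atomic(v) && length(v) >= 1, NA)]
  } else if (is.atomic(x) && !is.null(names(x))) {
    as.list(x)
  } else {
    stop("serialization error: cannot flatten object of class ",
         paste(class(x), collapse = "/"), call. = FALSE)
  }
}
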
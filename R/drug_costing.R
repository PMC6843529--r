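#' Per-day cost of a drug product
#'
#' Daily therapy cost from the pack: pack price divided by pack quantity,
#' times the number of units taken per day, rounded half-up to the cent.
#' This is the only formula that reproduces the published per-day rates
#' (e.g. rifampicin 271.46/100 x 1 = 2.71, rifabutin 489.19/90 x 2 = 10.87).
#'
#' @param product one or more rows of a [load_drug_catalog()] catalogue.
#' @return EUR/day, one value per row, rounded to the cent.
#' @export
daily_cost <- function(product) {
  if (any(product$pack_quantity <= 0)) {
    stop("domain error: pack_quantity must be > 0", call. = FALSE)
  }
  round_cents(product$pack_price / product$pack_quantity * product$daily_intake)
}

drug_row <- function(drugs, abbreviation) {
  i <- match(abbreviation, drugs$abbreviation)
  if (anyNA(i)) {
    stop("unknown drug abbreviation: ",
         paste(abbreviation[is.na(i)], collapse = ", "), call. = FALSE)
  }
  drugs[i, , drop = FALSE]
}

#' Per-day cost of a regimen's oral drugs
#'
#' Sums the per-day costs of the oral components (the IV component is costed
#' separately, see [iv_addon_cost()]). Two summation conventions are
#' supported: `"per_drug"` (default) sums component costs each already
#' rounded to the cent; `"after_sum"` rounds the exact sum once. The default
#' reproduces most published per-day rates (5.91, 7.42, 5.96, 7.93); the
#' alternative reproduces 14.08 for rifabutin-based triples instead.
#'
#' @param regimen one row of a [load_regimens()] table.
#' @param drugs drug catalogue.
#' @param rounding summation convention.
#' @return EUR/day for the oral drugs, rounded to the cent.
#' @export
regimen_daily_cost <- function(regimen, drugs = load_drug_catalog(),
                               rounding = c("per_drug", "after_sum")) {
  rounding <- match.arg(rounding)
  oral <- regimen$oral[[1]]
  if (length(oral) < 1) stop("domain error: regimen has no oral drugs", call. = FALSE)
  rows <- drug_row(drugs, oral)
  if (rounding == "per_drug") {
    round_cents(sum(daily_cost(rows)))
  } else {
    round_cents(sum(rows$pack_price / rows$pack_quantity * rows$daily_intake))
  }
}

#' Cost of the intravenous add-on
#'
#' Daily cost of the IV drug times the number of IV days (60 days of amikacin
#' in the default configuration: 71.40 x 60 = 4284.00).
#'
#' @param iv_drug a drug-catalogue row (the IV product), or `NULL`/empty for
#'   no IV component.
#' @param course_days IV course length in days; 0 means no IV.
#' @return EUR, rounded to the cent.
#' @export
iv_addon_cost <- function(iv_drug, course_days) {
  if (is.null(iv_drug) || nrow(iv_drug) == 0 || course_days == 0) return(0)
  if (course_days < 0) stop("domain error: negative IV course length", call. = FALSE)
  round_cents(daily_cost(iv_drug) * course_days)
}

#' Drug cost of a full treatment course
#'
#' Oral cost is the regimen's per-day rate times 30 days per month times the
#' treatment duration (14 months = 420 days, 18 months = 540 days); the IV
#' add-on is costed over its own course length. Total = oral + IV.
#'
#' @param regimen one row of a regimen table.
#' @param duration_months treatment duration in months.
#' @param drugs drug catalogue.
#' @param days_per_month days per model month (30 by construction).
#' @param rounding summation convention passed to [regimen_daily_cost()].
#' @return a `course_cost` list: `regimen_label`, `duration_months`,
#'   `daily_cost`, `oral_cost`, `iv_cost`, `total_drug_cost` (EUR).
#' @examples
#' drugs <- load_drug_catalog()
#' reg <- load_regimens(drugs = drugs)
#' course_cost(reg[reg$label == "R-E-CLAM", ], 14, drugs)$total_drug_cost  # 2482.2
#' @export
course_cost <- function(regimen, duration_months, drugs = load_drug_catalog(),
                        days_per_month = 30, rounding = "per_drug") {
  if (duration_months < 0) stop("domain error: negative duration", call. = FALSE)
  per_day <- regimen_daily_cost(regimen, drugs, rounding)
  oral <- round_cents(per_day * duration_months * days_per_month)
  iv <- if (!is.na(regimen$iv_drug) && regimen$iv_days > 0) {
    iv_addon_cost(drug_row(drugs, regimen$iv_drug), regimen$iv_days)
  } else 0
  structure(
    list(regimen_label = regimen$label, duration_months = duration_months,
         daily_cost = per_day, oral_cost = oral, iv_cost = iv,
         total_drug_cost = round_cents(oral + iv)),
    class = "course_cost"
  )
}
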
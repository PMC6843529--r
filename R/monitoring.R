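#' Parameters of a diagnostic/monitoring course
#'
#' @param treatment_months treatment duration, months (14 or 18 in the
#'   published scenarios).
#' @param post_monitoring_months post-treatment monitoring, months (12).
#' @param conversion_months months until presumed culture conversion: 2 for
#'   conversion within eight weeks, 6 for conversion within six months.
#' @param amk_given whether IV amikacin is part of the regimen (adds
#'   audiometry and serum-level monitoring).
#' @return a `schedule_parameters` list.
#' @export
schedule_parameters <- function(treatment_months = 14L,
                                post_monitoring_months = 12L,
                                conversion_months = 2L,
                                amk_given = FALSE) {
  if (any(c(treatment_months, post_monitoring_months, conversion_months) < 0)) {
    stop("domain error: months must be non-negative", call. = FALSE)
  }
  if (conversion_months > treatment_months) {
    stop("domain error: conversion_months exceeds treatment_months", call. = FALSE)
  }
  structure(
    list(treatment_months = as.integer(treatment_months),
         post_monitoring_months = as.integer(post_monitoring_months),
         conversion_months = as.integer(conversion_months),
         amk_given = isTRUE(amk_given)),
    class = "schedule_parameters"
  )
}

# Chest X-ray films: baseline, weeks 4 and 8, months 4 and 6, every 3 months
# thereafter including an end-of-treatment film, plus follow-ups 6, 12 and 24
# months after treatment end. Slow conversion uses the published count of 15
# because the guideline text does not state which extra films occur.
count_xrays <- function(treatment_months, conversion_months) {
  if (conversion_months >= 6) return(15L)
  during <- if (treatment_months >= 9) seq(9, treatment_months, by = 3) else integer(0)
  if (!(treatment_months %in% during)) {
    during <- unique(c(during, treatment_months))
  }
  5L + length(during) + 3L  # baseline/wk4/wk8/m4/m6 + q3 films + 3 post
}

#' Build the guideline monitoring schedule
#'
#' Turns course parameters into per-service billable event counts:
#' \describe{
#'   \item{sputum_samples}{3 baseline samples, one set per month until
#'     conversion, then one every 3 months over the 12-month continuation and
#'     12-month post-treatment periods (8 sets): `3 + conversion_months + 8`,
#'     i.e. 13 with fast and 17 with slow conversion.}
#'   \item{lab_visits}{biweekly for the first 2 months (4 visits), then
#'     monthly to treatment end: `4 + (treatment_months - 2)`.}
#'   \item{ophtha_visits}{monthly under ethambutol: one per treatment month.}
#'   \item{ct_scans}{baseline plus every 6 months during treatment.}
#'   \item{xrays}{see source; 11 films for a 14-month fast-conversion course.}
#'   \item{ecg}{4 (weeks 0, 2, 12, 24); not separately billable.}
#'   \item{audiometry, amk_levels}{3 each, only when amikacin is given.}
#'   \item{quarters}{physician billing quarters,
#'     `ceiling((treatment + post-monitoring)/3)`.}
#'   \item{once}{one-off work-up: NAAT, differentiation, resistance testing,
#'     bronchoscopy with lavage, hepatitis serology.}
#' }
#'
#' @param params a [schedule_parameters()] object.
#' @return a `monitoring_schedule`: named integer vector of counts.
#' @examples
#' build_schedule(schedule_parameters(14, 12, 2))[["sputum_samples"]]  # 13
#' @export
build_schedule <- function(params = schedule_parameters()) {
  tm <- params$treatment_months
  counts <- c(
    sputum_samples = 3L + params$conversion_months + 8L,
    xrays          = count_xrays(tm, params$conversion_months),
    ophtha_visits  = tm,
    ct_scans       = 1L + tm %/% 6L,
    lab_visits     = 4L + (tm - 2L),
    ecg            = 4L,
    audiometry     = if (params$amk_given) 3L else 0L,
    amk_levels     = if (params$amk_given) 3L else 0L,
    quarters       = as.integer(ceiling((tm + params$post_monitoring_months) / 3)),
    once           = 1L
  )
  structure(as.integer(counts), names = names(counts),
            class = "monitoring_schedule")
}

schedule_count_for_role <- function(schedule, role) {
  switch(role,
    per_quarter_gp     = schedule[["quarters"]],
    per_quarter_pneumo = schedule[["quarters"]],
    once               = schedule[["once"]],
    per_sputum_sample  = schedule[["sputum_samples"]],
    per_xray           = schedule[["xrays"]],
    per_ophtha_visit   = schedule[["ophtha_visits"]],
    per_ct             = schedule[["ct_scans"]],
    per_lab_visit      = schedule[["lab_visits"]],
    per_audiometry     = schedule[["audiometry"]],
    per_amk_level      = schedule[["amk_levels"]],
    zero_billable      = schedule[["ecg"]],
    stop("configuration error: no schedule counter for frequency role '",
         role, "'", call. = FALSE)
  )
}

#' Bill a monitoring schedule against the fee schedule
#'
#' Each fee line is billed `count x unit price` where the count comes from the
#' schedule counter its `frequency_role` points at; `zero_billable` lines
#' (ECG) are carried with a line total of EUR 0.00. In `"as_published"` mode
#' the single known anomaly of the printed fee table is honoured: the blood
#' count at 20 lab visits is billed at the printed 22.20 rather than
#' 20 x 1.10 = 22.00.
#'
#' @param schedule a [build_schedule()] result.
#' @param fees a [load_fee_schedule()] catalogue.
#' @param mode `"as_published"` or `"recomputed"`.
#' @return a `monitoring_cost` list: `lines` (itemized invoice data frame:
#'   service, code, payer group, count, unit price, line total) and `summary`
#'   (EUR by payer group: `gp_revenue`, `pneumologist_revenue`,
#'   `methods_cost`, `microbiology_cost`, `laboratory_cost`, `total`).
#' @export
cost_schedule <- function(schedule, fees = load_fee_schedule(),
                          mode = c("as_published", "recomputed")) {
  mode <- match.arg(mode)
  counts <- vapply(fees$frequency_role, function(r)
    schedule_count_for_role(schedule, r), integer(1))
  totals <- round_cents(ifelse(fees$frequency_role == "zero_billable",
                               0, fees$unit_price * counts))
  if (mode == "as_published") {
    bc <- fees$code == "EBM 32122" & counts == 20L
    totals[bc] <- 22.20
  }
  lines <- data.frame(
    service_name = fees$service_name, code = fees$code,
    payer_group = fees$payer_group, count = counts,
    unit_price = fees$unit_price, line_total = totals,
    stringsAsFactors = FALSE, row.names = NULL
  )
  by_payer <- vapply(PAYER_GROUPS, function(g)
    round_cents(sum(totals[fees$payer_group == g])), numeric(1))
  summary <- list(
    gp_revenue           = by_payer[["general_practitioner"]],
    pneumologist_revenue = by_payer[["pneumologist"]],
    methods_cost         = by_payer[["methods"]],
    microbiology_cost    = by_payer[["microbiology"]],
    laboratory_cost      = by_payer[["laboratory"]],
    total                = round_cents(sum(by_payer))
  )
  structure(list(lines = lines, summary = summary, mode = mode),
            class = "monitoring_cost")
}

#' Quarterly physician revenue
#'
#' Outpatient physicians are paid flat quarterly fees: the general
#' practitioner bills five per-quarter items (57.46 EUR/quarter in the
#' published fee table), the pulmonologist two per-quarter items plus a
#' one-off bronchoscopy with bronchoalveolar lavage.
#'
#' @param quarters number of billing quarters spanned by treatment plus
#'   post-treatment monitoring.
#' @param fees fee schedule.
#' @return named numeric: `gp` and `pneumologist` revenue in EUR.
#' @examples
#' physician_revenue(9)   # c(gp = 517.14, pneumologist = 377.65)
#' @export
physician_revenue <- function(quarters, fees = load_fee_schedule()) {
  if (quarters < 0) stop("domain error: negative quarter count", call. = FALSE)
  gp_rate <- sum(fees$unit_price[fees$frequency_role == "per_quarter_gp"])
  pn_rate <- sum(fees$unit_price[fees$frequency_role == "per_quarter_pneumo"])
  pn_once <- sum(fees$unit_price[fees$frequency_role == "once" &
                                   fees$payer_group == "pneumologist"])
  c(gp = round_cents(quarters * gp_rate),
    pneumologist = round_cents(quarters * pn_rate + pn_once))
}

#' Monitoring add-on for intravenous amikacin
#'
#' Three audiometry examinations plus three serum-level determinations
#' (3 x 15.91 + 3 x 17.70 = 100.83 EUR with the published fees).
#'
#' @param fees fee schedule containing the audiometry and serum-level items.
#' @return EUR.
#' @export
amk_monitoring_addon <- function(fees = load_fee_schedule()) {
  audio <- fees$unit_price[fees$frequency_role == "per_audiometry"]
  level <- fees$unit_price[fees$frequency_role == "per_amk_level"]
  if (!length(audio) || !length(level)) {
    stop("configuration error: audiometry or serum-level fee item missing",
         call. = FALSE)
  }
  round_cents(3 * sum(audio) + 3 * sum(level))
}

#' Average monthly physician revenue
#'
#' Combined GP and pulmonologist revenue divided by the number of months the
#' published analysis uses as divisor (26 for the short course, 30 for the
#' long one).
#'
#' @param gp GP revenue, EUR.
#' @param pneumologist pulmonologist revenue, EUR.
#' @param months divisor in months.
#' @return EUR/month, rounded to the cent.
#' @export
monthly_physician_revenue <- function(gp, pneumologist, months) {
  if (months <= 0) stop("domain error: months must be > 0", call. = FALSE)
  round_cents((gp + pneumologist) / months)
}

#' Published monitoring cost constants
#'
#' The per-course diagnostics/monitoring totals as published: 2162.47 EUR for
#' a 14-month and 2895.75 EUR for an 18-month course, raised by the amikacin
#' add-on (100.83 EUR) to 2263.30 / 2996.58 for the IV regimens. These
#' constants do not equal the sum of the fee-table line items (2389.29 /
#' 2895.35); both figures are exposed, see [cost_schedule()].
#'
#' @param duration_months 14 or 18.
#' @param amk_given whether the amikacin monitoring add-on applies.
#' @return EUR.
#' @export
published_monitoring_cost <- function(duration_months, amk_given = FALSE) {
  base <- c(`14` = 2162.47, `18` = 2895.75)[as.character(duration_months)]
  if (anyNA(base)) {
    stop("no published monitoring constant for duration ",
         duration_months, " months", call. = FALSE)
  }
  unname(round_cents(base + if (amk_given) 100.83 else 0))
}
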
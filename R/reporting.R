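round_pct <- function(x) round_cents(x, digits = 1)

#' Intersectoral comparison report
#'
#' Combines the Monte-Carlo outpatient summaries, the quarterly physician
#' revenues and the hospital DRG payment into the headline comparison
#' figures: the share of total outpatient cost going to physicians (by
#' course length), to medication, and the DRG payment as a share of the mean
#' outpatient total. Shares are computed from unrounded cent-level values and
#' rounded once to one decimal for display.
#'
#' @param total_result `simulation_result` for total outpatient costs.
#' @param drug_result `simulation_result` for drug costs.
#' @param revenue_short named revenue vector ([physician_revenue()]) for the
#'   short course (9 quarters).
#' @param revenue_long revenue vector for the long course (10 quarters).
#' @param drg_payment DRG case payment, EUR.
#' @param months_short,months_long month divisors for the average monthly
#'   physician revenue (26 and 30 as published).
#' @param n_runs,seed,mode provenance fields recorded in the report.
#' @return an `intersectoral_report` list.
#' @export
build_report <- function(total_result, drug_result,
                         revenue_short = physician_revenue(9),
                         revenue_long = physician_revenue(10),
                         drg_payment = drg_case_payment(),
                         months_short = 26L, months_long = 30L,
                         n_runs = total_result$n, seed = total_result$seed,
                         mode = "as_published") {
  if (total_result$mean <= 0) {
    stop("domain error: zero or negative outpatient mean", call. = FALSE)
  }
  doc_short <- round_cents(sum(revenue_short))
  doc_long <- round_cents(sum(revenue_long))
  structure(
    list(
      outpatient_mean_total = total_result$mean,
      outpatient_mean_drug = drug_result$mean,
      doctor_revenue_26 = doc_short,
      doctor_revenue_30 = doc_long,
      doctor_share_26 = round_pct(100 * doc_short / total_result$mean),
      doctor_share_30 = round_pct(100 * doc_long / total_result$mean),
      drug_share = round_pct(100 * drug_result$mean / total_result$mean),
      drg_payment = drg_payment,
      drg_vs_outpatient_share = round_pct(100 * drg_payment / total_result$mean),
      monthly_doctor_revenue_26 = monthly_physician_revenue(
        revenue_short[["gp"]], revenue_short[["pneumologist"]], months_short),
      monthly_doctor_revenue_30 = monthly_physician_revenue(
        revenue_long[["gp"]], revenue_long[["pneumologist"]], months_long),
      seed = seed, n_runs = n_runs, mode = mode
    ),
    class = "intersectoral_report"
  )
}

#' @export
print.intersectoral_report <- function(x, ...) {
  fmt <- function(v) formatC(v, format = "f", digits = 2, big.mark = ",")
  cat("Intersectoral cost comparison (mode: ", x$mode, ", n = ", x$n_runs,
      ", seed = ", x$seed, ")\n", sep = "")
  cat("  Outpatient mean total cost   EUR ", fmt(x$outpatient_mean_total), "\n", sep = "")
  cat("  Outpatient mean drug cost    EUR ", fmt(x$outpatient_mean_drug),
      "  (", x$drug_share, "% of total)\n", sep = "")
  cat("  Physician revenue, 26 mo     EUR ", fmt(x$doctor_revenue_26),
      "  (", x$doctor_share_26, "%)  -> EUR ",
      fmt(x$monthly_doctor_revenue_26), "/month\n", sep = "")
  cat("  Physician revenue, 30 mo     EUR ", fmt(x$doctor_revenue_30),
      "  (", x$doctor_share_30, "%)  -> EUR ",
      fmt(x$monthly_doctor_revenue_30), "/month\n", sep = "")
  cat("  Hospital DRG case payment    EUR ", fmt(x$drg_payment),
      "  (", x$drg_vs_outpatient_share, "% of outpatient total)\n", sep = "")
  invisible(x)
}
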
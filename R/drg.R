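#' Flat DRG case payment for the NTM hospital stay
#'
#' National base rate times the DRG cost weight, rounded to the cent. The
#' payment is a flat case rate: it does not vary with the actual stay up to
#' the cap (it is fully paid even for a 2-day stay) and is unaffected by
#' coded secondary diagnoses.
#'
#' @param params a [drg_parameters()] object.
#' @return EUR per case.
#' @examples
#' drg_case_payment()  # 3321.64
#' @export
drg_case_payment <- function(params = drg_parameters()) {
  round_cents(params$base_rate * params$cost_weight)
}

#' Average reimbursement per hospital bed-day
#'
#' The unrounded case payment divided by the DRG's mean length of stay,
#' reported at one decimal (519.0 EUR/day with the published parameters).
#'
#' @param params a [drg_parameters()] object.
#' @param digits decimals for the reported rate (1 as published).
#' @return EUR per bed-day.
#' @examples
#' per_bed_day_rate()  # 519.0
#' @export
per_bed_day_rate <- function(params = drg_parameters(), digits = 1) {
  if (params$mean_length_of_stay <= 0) {
    stop("domain error: mean length of stay must be > 0", call. = FALSE)
  }
  round_cents(params$base_rate * params$cost_weight / params$mean_length_of_stay,
              digits = digits)
}
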
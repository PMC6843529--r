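new_option_set <- function(options, mode, weights = weight_config()) {
  structure(list(options = as.data.frame(options), mode = mode,
                 weight_config = weights),
            class = "option_set")
}

#' Enumerate the weighted treatment-option space
#'
#' Builds the 20-cell option space (10 regimens x 2 treatment durations),
#' each cell carrying drug cost, monitoring cost, total cost and probability
#' weight. In `"as_published"` mode the published cost table is loaded
#' verbatim (including its internal inconsistencies); in `"recomputed"` mode
#' every cost is rebuilt from the drug and fee catalogues. Monitoring costs
#' default to the published per-course constants in both modes;
#' `monitoring = "line_items"` bills the full fee table instead.
#'
#' Weights: the no-amikacin mass (0.84) is spread evenly over the
#' macrolide-susceptible cells, the amikacin mass (0.16) over the remaining
#' cells; the two durations are equiprobable.
#'
#' @param drugs drug catalogue (recomputed mode).
#' @param fees fee schedule (recomputed mode with line-item monitoring).
#' @param regimens regimen table (recomputed mode).
#' @param weights a [weight_config()].
#' @param mode `"as_published"` or `"recomputed"`.
#' @param monitoring `"published"` constants or `"line_items"` billing.
#' @param durations treatment durations in months.
#' @param rounding summation convention for [regimen_daily_cost()].
#' @return an `option_set`: list with `options` data frame (one row per
#'   regimen-duration cell), `mode`, and `weight_config`.
#' @examples
#' opts <- enumerate_options(mode = "as_published")
#' min(opts$options$total_cost)  # 4644.67
#' @export
enumerate_options <- function(drugs = load_drug_catalog(),
                              fees = load_fee_schedule(),
                              regimens = load_regimens(drugs = drugs),
                              weights = weight_config(),
                              mode = c("as_published", "recomputed"),
                              monitoring = c("published", "line_items"),
                              durations = c(14L, 18L),
                              rounding = "per_drug") {
  mode <- match.arg(mode)
  monitoring <- match.arg(monitoring)
  if (mode == "as_published") {
    return(load_published_options(weights = weights))
  }
  cells <- expand.grid(i = seq_len(nrow(regimens)), duration = durations,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(k) {
    reg <- regimens[cells$i[k], , drop = FALSE]
    dur <- cells$duration[k]
    amk <- !is.na(reg$iv_drug)
    cc <- course_cost(reg, dur, drugs, rounding = rounding)
    mon <- if (monitoring == "published") {
      published_monitoring_cost(dur, amk_given = amk)
    } else {
      sched <- build_schedule(schedule_parameters(
        treatment_months = dur, conversion_months = if (dur >= 18) 6L else 2L,
        amk_given = amk))
      cost_schedule(sched, fees, mode = "recomputed")$summary$total
    }
    data.frame(regimen_label = reg$label, category = reg$category,
               duration_months = dur, daily_drug_cost = cc$daily_cost,
               drug_cost = cc$total_drug_cost, monitoring_cost = mon,
               total_cost = round_cents(cc$total_drug_cost + mon),
               stringsAsFactors = FALSE)
  })
  opts <- do.call(rbind, rows)
  susceptible <- opts$category == "macrolide_susceptible"
  n_s <- sum(susceptible); n_a <- sum(!susceptible)
  if (n_s != weights$n_susceptible_options || n_a != weights$n_amk_options) {
    stop("configuration error: option space has ", n_s, "+", n_a,
         " cells; weight config expects ", weights$n_susceptible_options,
         "+", weights$n_amk_options, call. = FALSE)
  }
  opts$weight <- ifelse(susceptible, weights$p_no_amk / n_s, weights$p_amk / n_a)
  new_option_set(opts, mode = "recomputed", weights = weights)
}

option_values <- function(option_set, value = c("total", "drug")) {
  value <- match.arg(value)
  switch(value, total = option_set$options$total_cost,
         drug = option_set$options$drug_cost)
}

#' Exact moments of the weighted option distribution
#'
#' Closed-form mean, variance, and extremes of the discrete cost
#' distribution; the exact counterpart the Monte-Carlo summary converges to.
#'
#' @param option_set an `option_set`.
#' @param value `"total"` for total outpatient cost, `"drug"` for drug cost.
#' @return list with `mean`, `variance`, `sd`, `min`, `max` (EUR, EUR^2).
#' @examples
#' analytic_moments(enumerate_options(mode = "as_published"))$mean  # 8715.80
#' @export
analytic_moments <- function(option_set, value = c("total", "drug")) {
  opts <- option_set$options
  if (is.null(opts) || nrow(opts) == 0) {
    stop("domain error: empty option set", call. = FALSE)
  }
  w <- opts$weight
  if (abs(sum(w) - 1) > 1e-9) {
    stop("validation error: weights sum to ", sum(w), call. = FALSE)
  }
  x <- option_values(option_set, value)
  m <- sum(w * x)
  v <- sum(w * x^2) - m^2
  list(mean = m, variance = v, sd = sqrt(max(v, 0)), min = min(x), max = max(x))
}

#' @export
print.option_set <- function(x, ...) {
  cat("Treatment option space (", x$mode, " mode): ", nrow(x$options),
      " options\n", sep = "")
  cat("  weight mass: ", x$weight_config$p_no_amk, " no-AMK / ",
      x$weight_config$p_amk, " AMK\n", sep = "")
  print(utils::head(x$options, 4), ...)
  if (nrow(x$options) > 4) cat("  ...\n")
  invisible(x)
}
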
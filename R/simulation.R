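#' Monte-Carlo configuration
#'
#' @param n_runs number of simulation draws (10,000 in the published
#'   analysis).
#' @param seed integer seed; recorded in every result for reproducibility.
#' @param confidence_level CI coverage (0.95).
#' @param z_value normal quantile used for the CI (fixed at 1.96, matching
#'   the published interval arithmetic).
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_runs = 10000L, seed = 1L,
                              confidence_level = 0.95, z_value = 1.96) {
  if (n_runs < 1) stop("domain error: n_runs must be >= 1", call. = FALSE)
  if (confidence_level <= 0 || confidence_level >= 1) {
    stop("domain error: confidence_level must be in (0, 1)", call. = FALSE)
  }
  structure(list(n_runs = as.integer(n_runs), seed = as.integer(seed),
                 confidence_level = confidence_level, z_value = z_value),
            class = "simulation_config")
}

#' Draw costs from the weighted option space
#'
#' The "random walk" through the treatment options: `n_runs` independent
#' categorical draws of one option cost each, with the configured
#' probability weights. Reproducible given the seed.
#'
#' @param option_set an `option_set`.
#' @param config a [simulation_config()].
#' @param value `"total"` or `"drug"` cost.
#' @return numeric vector of `n_runs` EUR draws.
#' @export
sample_options <- function(option_set, config = simulation_config(),
                           value = c("total", "drug")) {
  x <- option_values(option_set, value)
  w <- option_set$options$weight
  if (length(x) == 0) stop("domain error: empty option set", call. = FALSE)
  set.seed(config$seed)
  draw_options(x, w, config$n_runs)
}

# Draw from the current RNG stream (no reseeding); used when several stages
# share one seeded stream.
draw_options <- function(x, w, n) {
  x[sample.int(length(x), size = n, replace = TRUE, prob = w)]
}

#' Summarize Monte-Carlo draws
#'
#' Sample mean, standard deviation (n-1 denominator), normal-approximation
#' confidence interval `mean +/- z * sd / sqrt(n)`, and empirical median,
#' minimum and maximum — the summary layout of the published results table.
#'
#' @param draws numeric vector of cost draws, EUR.
#' @param config a [simulation_config()] (supplies `z_value` and the recorded
#'   seed).
#' @return a `simulation_result` list: `mean`, `sd`, `variance`, `ci_low`,
#'   `ci_high`, `median`, `min`, `max`, `n`, `standard_error`, `seed`.
#' @export
summarize_draws <- function(draws, config = simulation_config()) {
  if (length(draws) == 0) stop("domain error: empty draw sequence", call. = FALSE)
  n <- length(draws)
  m <- mean(draws)
  s <- if (n > 1) stats::sd(draws) else 0
  se <- s / sqrt(n)
  structure(
    list(mean = m, sd = s, variance = s^2,
         ci_low = m - config$z_value * se, ci_high = m + config$z_value * se,
         median = stats::median(draws), min = min(draws), max = max(draws),
         n = n, standard_error = se, seed = config$seed),
    class = "simulation_result"
  )
}

#' Two-stage Monte-Carlo over drug and total costs
#'
#' Stage 1 summarizes drug costs, stage 2 total outpatient costs, each with
#' `n_runs` draws over the same weighted regimen-by-duration cells. Both
#' stages run on one seeded stream so a single seed reproduces the pair.
#'
#' @param option_set an `option_set`.
#' @param config a [simulation_config()].
#' @return list with `drug_result` and `total_result`, both
#'   `simulation_result`s.
#' @export
run_two_stage <- function(option_set, config = simulation_config()) {
  w <- option_set$options$weight
  set.seed(config$seed)
  drug_draws <- draw_options(option_values(option_set, "drug"), w, config$n_runs)
  total_draws <- draw_options(option_values(option_set, "total"), w, config$n_runs)
  list(drug_result = summarize_draws(drug_draws, config),
       total_result = summarize_draws(total_draws, config))
}

#' @export
print.simulation_result <- function(x, ...) {
  fmt <- function(v) formatC(v, format = "f", digits = 2, big.mark = ",")
  cat("Weighted Monte-Carlo cost summary (n = ", x$n, ", seed = ", x$seed,
      ")\n", sep = "")
  cat("  Mean                     EUR ", fmt(x$mean), "\n", sep = "")
  cat("  Standard deviation       EUR ", fmt(x$sd), "\n", sep = "")
  cat("  95% confidence interval  EUR ", fmt(x$ci_low), " to ", fmt(x$ci_high),
      "\n", sep = "")
  cat("  Median                   EUR ", fmt(x$median), "\n", sep = "")
  cat("  Minimum / Maximum        EUR ", fmt(x$min), " / ", fmt(x$max), "\n",
      sep = "")
  cat("  Standard error           EUR ", fmt(x$standard_error), "\n", sep = "")
  invisible(x)
}
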
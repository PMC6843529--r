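#' Specification for synthetic catalogue perturbation
#'
#' Controls the generator used for property testing: multiplicative
#' log-normal noise on pack prices (keeps prices positive without
#' truncation) and symmetric Dirichlet-style option weights whose
#' concentration tunes how far from uniform they scatter.
#'
#' @param price_noise_sd standard deviation of the log-scale price noise
#'   (0 reproduces the input catalogue exactly).
#' @param weight_concentration symmetric Dirichlet concentration for option
#'   weights; `Inf` gives exactly equal weights.
#' @param n_regimens number of synthetic regimens.
#' @param durations treatment durations (months) crossed with the regimens.
#' @param seed generator seed, kept separate from any simulation seed.
#' @return a `perturbation_spec` list.
#' @export
perturbation_spec <- function(price_noise_sd = 0.1, weight_concentration = 1,
                              n_regimens = 10L, durations = c(14L, 18L),
                              seed = 1L) {
  if (price_noise_sd < 0) stop("domain error: negative noise sd", call. = FALSE)
  if (weight_concentration <= 0) {
    stop("domain error: weight_concentration must be > 0", call. = FALSE)
  }
  if (n_regimens < 1) stop("domain error: n_regimens must be >= 1", call. = FALSE)
  if (length(durations) == 0) stop("domain error: empty durations", call. = FALSE)
  structure(
    list(price_noise_sd = price_noise_sd,
         weight_concentration = weight_concentration,
         n_regimens = as.integer(n_regimens),
         durations = as.integer(durations), seed = as.integer(seed)),
    class = "perturbation_spec"
  )
}

#' Perturb a drug catalogue's pack prices
#'
#' Multiplies each pack price by `exp(noise)` with zero-mean normal noise on
#' the log scale; quantities and intakes are unchanged. Deterministic given
#' the spec's seed.
#'
#' @param base a [load_drug_catalog()] catalogue.
#' @param spec a [perturbation_spec()].
#' @return a perturbed `drug_catalog`.
#' @export
perturb_catalog <- function(base, spec = perturbation_spec()) {
  out <- base
  set.seed(spec$seed)
  noise <- stats::rnorm(nrow(base), mean = 0, sd = spec$price_noise_sd)
  out$pack_price <- base$pack_price * exp(noise)
  out
}

# Symmetric Dirichlet draw via normalized gamma variates; concentration Inf
# degenerates to the uniform vector.
rdirichlet_sym <- function(k, concentration) {
  if (!is.finite(concentration)) return(rep(1 / k, k))
  g <- stats::rgamma(k, shape = concentration, rate = 1)
  while (sum(g) == 0) g <- stats::rgamma(k, shape = concentration, rate = 1)
  g / sum(g)
}

#' Generate a random synthetic option space
#'
#' Builds `n_regimens` synthetic regimens (random oral subsets of the drug
#' catalogue, random categories with the matching IV component) crossed with
#' the spec's durations, costs them through the regular costing pipeline
#' against a perturbed catalogue, and assigns Dirichlet-distributed weights.
#' The result satisfies every option-set invariant, so the Monte-Carlo /
#' analytic-moment agreement property can be exercised on arbitrarily many
#' generated spaces.
#'
#' @param spec a [perturbation_spec()].
#' @param drugs base drug catalogue to perturb and sample oral subsets from.
#' @return an `option_set` with mode `"recomputed"`.
#' @export
random_option_space <- function(spec = perturbation_spec(),
                                drugs = load_drug_catalog()) {
  perturbed <- perturb_catalog(drugs, spec)
  set.seed(spec$seed + 1L)
  oral_pool <- setdiff(perturbed$abbreviation, "AMK")
  has_iv <- "AMK" %in% perturbed$abbreviation
  regs <- lapply(seq_len(spec$n_regimens), function(i) {
    n_oral <- sample(2:min(3, length(oral_pool)), 1)
    oral <- sample(oral_pool, n_oral)
    iv <- has_iv && stats::runif(1) < 0.5
    data.frame(label = paste0("SYN-", i, "-", paste(oral, collapse = "-"),
                              if (iv) "-AMK" else ""),
               category = if (iv) "severe" else "macrolide_susceptible",
               iv_drug = if (iv) "AMK" else NA_character_,
               iv_days = if (iv) 60L else 0L, stringsAsFactors = FALSE)
  })
  regimens <- do.call(rbind, regs)
  regimens$oral <- lapply(regs, function(r) {
    strsplit(sub("-AMK$", "", sub("^SYN-[0-9]+-", "", r$label)), "-")[[1]]
  })
  cells <- expand.grid(i = seq_len(nrow(regimens)), duration = spec$durations,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(k) {
    reg <- regimens[cells$i[k], , drop = FALSE]
    dur <- cells$duration[k]
    cc <- course_cost(reg, dur, perturbed)
    mon <- published_monitoring_cost(
      if (dur >= 18) 18L else 14L, amk_given = !is.na(reg$iv_drug))
    data.frame(regimen_label = reg$label, category = reg$category,
               duration_months = dur, daily_drug_cost = cc$daily_cost,
               drug_cost = cc$total_drug_cost, monitoring_cost = mon,
               total_cost = round_cents(cc$total_drug_cost + mon),
               stringsAsFactors = FALSE)
  })
  opts <- do.call(rbind, rows)
  opts$weight <- rdirichlet_sym(nrow(opts), spec$weight_concentration)
  n_s <- sum(opts$category == "macrolide_susceptible")
  wc <- weight_config(n_susceptible_options = n_s,
                      n_amk_options = nrow(opts) - n_s)
  new_option_set(opts, mode = "recomputed", weights = wc)
}
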
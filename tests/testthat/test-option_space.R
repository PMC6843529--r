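test_that("as-published option space carries the printed extremes and weights", {
  opts <- enumerate_options(mode = "as_published")
  expect_equal(nrow(opts$options), 20)
  expect_equal(min(opts$options$total_cost), 4644.67)
  expect_equal(max(opts$options$total_cost), 15806.78)
  susceptible <- opts$options$category == "macrolide_susceptible"
  expect_true(all(opts$options$weight[susceptible] == 0.105))
  expect_equal(unique(opts$options$weight[!susceptible]), 0.16 / 12,
               tolerance = 1e-12)
})

test_that("analytic moments match an independent brute-force oracle", {
  opts <- enumerate_options(mode = "as_published")
  for (value in c("total", "drug")) {
    col <- if (value == "total") "total_cost" else "drug_cost"
    oracle <- oracle_moments(raw_published[[col]], raw_published$weight)
    got <- analytic_moments(opts, value)
    expect_equal(got$mean, oracle$mean, tolerance = 1e-12)
    expect_equal(got$variance, oracle$variance, tolerance = 1e-9)
  }
  # frozen oracle values, computed by hand-weighting the printed columns
  expect_equal(analytic_moments(opts)$mean, 8715.80, tolerance = 0.005)
  expect_equal(analytic_moments(opts, "drug")$mean, 6170.01, tolerance = 0.005)
  # degenerate single option
  solo <- macpdcost:::new_option_set(
    data.frame(regimen_label = "X", category = "macrolide_susceptible",
               duration_months = 14, daily_drug_cost = 1, drug_cost = 420,
               monitoring_cost = 0, total_cost = 420, weight = 1),
    mode = "as_published")
  expect_equal(analytic_moments(solo)$mean, 420)
  expect_equal(analytic_moments(solo)$variance, 0)
})

test_that("analytic mean is invariant to permutation and weight splitting", {
  opts <- enumerate_options(mode = "as_published")
  base <- analytic_moments(opts)$mean
  shuffled <- opts
  set.seed(11)
  shuffled$options <- shuffled$options[sample(nrow(shuffled$options)), ]
  expect_equal(analytic_moments(shuffled)$mean, base, tolerance = 1e-12)
  split <- opts
  first <- split$options[1, ]
  first$weight <- first$weight / 2
  split$options$weight[1] <- split$options$weight[1] / 2
  split$options <- rbind(split$options, first)
  expect_equal(analytic_moments(split)$mean, base, tolerance = 1e-12)
})

test_that("recomputed totals agree with the published table on self-consistent rows", {
  rec <- enumerate_options(drugs_fx, fees_fx, regimens_fx, mode = "recomputed")
  consistent <- list(
    c("R-E-CLAM", 14), c("R-E-CLAM", 18), c("R-E-AZM", 18),
    c("R-E-CLO-AMK", 14), c("R-E-CLO-AMK", 18), c("R-E-MOX-AMK", 14),
    c("R-E-CLAM-AMX", 14), c("R-E-CLAM-AMX", 18),
    c("R-E-ATZ-AMX", 14), c("R-E-ATZ-AMX", 18)
  )
  for (row in consistent) {
    pub <- published_cell(row[1], as.integer(row[2]))$total_cost
    ro <- rec$options
    got <- ro$total_cost[ro$regimen_label == row[1] &
                           ro$duration_months == as.integer(row[2])]
    expect_equal(got, pub, info = paste(row, collapse = "/"))
  }
  # rifabutin triple agrees under the printed once-rounded daily rate
  expect_equal(14.08 * 420 + 2162.47, published_cell("RBT-E-CLAM", 14)$total_cost)
  expect_equal(14.08 * 540 + 2895.75, published_cell("RBT-E-CLAM", 18)$total_cost)
})

test_that("recomputed mode with zeroed prices leaves only the monitoring constants", {
  free <- drugs_fx
  free$pack_price <- 0
  rec <- enumerate_options(free, fees_fx, regimens_fx, mode = "recomputed")
  expect_true(all(rec$options$drug_cost == 0))
  amk <- rec$options$category != "macrolide_susceptible"
  expect_true(all(rec$options$total_cost[!amk] %in% c(2162.47, 2895.75)))
  expect_true(all(rec$options$total_cost[amk] %in% c(2263.30, 2996.58)))
})

test_that("line-item monitoring mode bills the fee table instead of the constants", {
  rec <- enumerate_options(drugs_fx, fees_fx, regimens_fx, mode = "recomputed",
                           monitoring = "line_items")
  m14 <- rec$options$monitoring_cost[rec$options$duration_months == 14 &
                                       rec$options$category == "macrolide_susceptible"]
  expect_true(all(m14 == 2389.29))
})

test_that("empty or unnormalized option sets are rejected", {
  empty <- macpdcost:::new_option_set(
    data.frame(total_cost = numeric(0), drug_cost = numeric(0),
               weight = numeric(0)), mode = "as_published")
  expect_error(analytic_moments(empty), "empty")
  bad <- enumerate_options(mode = "as_published")
  bad$options$weight <- bad$options$weight * 2
  expect_error(analytic_moments(bad), "weights sum")
})
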
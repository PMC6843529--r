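test_that("schedule counts follow the guideline rules for both course lengths", {
  fast <- build_schedule(schedule_parameters(14, 12, 2))
  expect_equal(fast[["sputum_samples"]], 13)
  expect_equal(fast[["xrays"]], 11)
  expect_equal(fast[["ophtha_visits"]], 14)
  expect_equal(fast[["ct_scans"]], 3)
  expect_equal(fast[["lab_visits"]], 16)
  expect_equal(fast[["quarters"]], 9)
  expect_equal(fast[["ecg"]], 4)
  expect_equal(fast[["audiometry"]], 0)

  slow <- build_schedule(schedule_parameters(18, 12, 6))
  expect_equal(slow[["sputum_samples"]], 17)
  expect_equal(slow[["xrays"]], 15)
  expect_equal(slow[["ophtha_visits"]], 18)
  expect_equal(slow[["ct_scans"]], 4)
  expect_equal(slow[["lab_visits"]], 20)
  expect_equal(slow[["quarters"]], 10)

  # sputum formula: 3 baseline + monthly until conversion + 8 post-conversion
  immediate <- build_schedule(schedule_parameters(14, 12, 0))
  expect_equal(immediate[["sputum_samples"]], 11)
  expect_equal(slow[["sputum_samples"]] - fast[["sputum_samples"]], 4)

  amk <- build_schedule(schedule_parameters(14, 12, 2, amk_given = TRUE))
  expect_equal(amk[["audiometry"]], 3)
  expect_equal(amk[["amk_levels"]], 3)

  expect_error(schedule_parameters(14, 12, 15), "conversion_months")
})

test_that("schedule construction is a deterministic integer-valued function", {
  for (tm in c(6L, 12L, 14L, 18L, 24L)) {
    for (cm in c(0L, 2L, 6L)) {
      p <- schedule_parameters(tm, 12L, cm)
      s1 <- build_schedule(p); s2 <- build_schedule(p)
      expect_identical(s1, s2)
      expect_true(all(s1 >= 0))
      expect_equal(s1[["sputum_samples"]], 3 + cm + 8)
      expect_equal(s1[["lab_visits"]], 4 + (tm - 2))
      expect_equal(s1[["quarters"]], ceiling((tm + 12) / 3))
    }
  }
})

test_that("billing reproduces published line items and payer subtotals", {
  mc <- cost_schedule(build_schedule(schedule_parameters(14, 12, 2)), fees_fx)
  lines <- mc$lines
  expect_equal(lines$line_total[lines$code == "EBM 32747"], 13 * 34.90)  # 453.70
  expect_equal(lines$line_total[lines$code == "EBM 06212"], 227.22)
  expect_equal(lines$line_total[lines$code == "EBM 27320"], 0)  # ECG unbilled
  expect_equal(mc$summary$gp_revenue, 517.14)
  expect_equal(mc$summary$pneumologist_revenue, 377.65)
  expect_equal(mc$summary$total, 2389.29)  # line-item sum, not the published constant
  expect_equal(mc$summary$total,
               with(mc$summary, gp_revenue + pneumologist_revenue + methods_cost +
                      microbiology_cost + laboratory_cost))

  mc18 <- cost_schedule(build_schedule(schedule_parameters(18, 12, 6)), fees_fx)
  expect_equal(mc18$lines$line_total[mc18$lines$code == "EBM 06212"], 292.14)
  # published blood-count anomaly: 22.20 as printed vs 20 x 1.10 recomputed
  expect_equal(mc18$lines$line_total[mc18$lines$code == "EBM 32122"], 22.20)
  expect_equal(mc18$summary$total, 2895.35)
  mc18r <- cost_schedule(build_schedule(schedule_parameters(18, 12, 6)), fees_fx,
                         mode = "recomputed")
  expect_equal(mc18r$lines$line_total[mc18r$lines$code == "EBM 32122"], 22.00)
})

test_that("an all-zero schedule bills nothing", {
  zero <- build_schedule(schedule_parameters(2, 0, 0))
  zero[] <- 0L
  mc <- cost_schedule(zero, fees_fx)
  expect_equal(mc$summary$total, 0)
  expect_true(all(mc$lines$line_total == 0))
})

test_that("billing is weakly monotone in counts and unit prices", {
  base <- cost_schedule(build_schedule(schedule_parameters(14, 12, 2)), fees_fx)
  bigger <- build_schedule(schedule_parameters(18, 12, 6, amk_given = TRUE))
  expect_gte(cost_schedule(bigger, fees_fx)$summary$total, base$summary$total)
  pricier <- fees_fx
  pricier$unit_price <- pricier$unit_price * 1.2
  expect_gte(cost_schedule(build_schedule(schedule_parameters(14, 12, 2)),
                           pricier, mode = "recomputed")$summary$total,
             base$summary$total)
})

test_that("physician quarterly revenues match the published totals", {
  expect_equal(physician_revenue(9, fees_fx),
               c(gp = 517.14, pneumologist = 377.65))
  expect_equal(physician_revenue(10, fees_fx),
               c(gp = 574.60, pneumologist = 404.82))
  # zero quarters: only the one-off bronchoscopy + lavage remain
  expect_equal(physician_revenue(0, fees_fx),
               c(gp = 0, pneumologist = 133.12))
  expect_error(physician_revenue(-1, fees_fx), "negative")
})

test_that("amikacin monitoring add-on is 100.83 and closes the published constants", {
  expect_equal(amk_monitoring_addon(fees_fx), 100.83)
  expect_equal(published_monitoring_cost(14), 2162.47)
  expect_equal(published_monitoring_cost(18), 2895.75)
  expect_equal(published_monitoring_cost(14, amk_given = TRUE), 2263.30)
  expect_equal(published_monitoring_cost(18, amk_given = TRUE), 2996.58)
  no_audio <- fees_fx[fees_fx$frequency_role != "per_audiometry", ]
  expect_error(amk_monitoring_addon(no_audio), "configuration error")
})

test_that("AMK add-on equals the with/without billing difference", {
  for (tm in c(14L, 18L)) {
    cm <- if (tm == 18L) 6L else 2L
    with_amk <- cost_schedule(
      build_schedule(schedule_parameters(tm, 12, cm, amk_given = TRUE)), fees_fx)
    without <- cost_schedule(
      build_schedule(schedule_parameters(tm, 12, cm, amk_given = FALSE)), fees_fx)
    expect_equal(with_amk$summary$total - without$summary$total,
                 amk_monitoring_addon(fees_fx))
  }
})

test_that("average monthly physician revenue uses the published divisors", {
  expect_equal(monthly_physician_revenue(517.14, 377.65, 26), 34.42)
  expect_equal(monthly_physician_revenue(574.60, 404.82, 30), 32.65)
  expect_equal(monthly_physician_revenue(0, 0, 12), 0)
  expect_error(monthly_physician_revenue(1, 1, 0), "months")
})
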
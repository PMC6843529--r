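#!/usr/bin/env Rscript
# Step 4 — intersectoral comparison.
# Combines the Monte-Carlo outpatient summaries with physician revenues and
# the hospital DRG payment into the headline comparison. Writes:
#   results/intersectoral_report.json
# Usage: Rscript analysis/04_intersectoral.R [seed]
suppressPackageStartupMessages(library(macpdcost))
dir.create("results", showWarnings = FALSE)

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 20191009L

opts <- enumerate_options(mode = "as_published")
res <- run_two_stage(opts, simulation_config(n_runs = 10000, seed = seed))
report <- build_report(res$total_result, res$drug_result,
                       revenue_short = physician_revenue(9),
                       revenue_long = physician_revenue(10),
                       drg_payment = drg_case_payment())
write_report(report, "results/intersectoral_report.json", format = "json")

print(report)
cat("\nHospital per-bed-day rate: EUR", per_bed_day_rate(), "\n")
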
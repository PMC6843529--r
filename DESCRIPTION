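Package: macpdcost
Title: Intersectoral Cost Analysis of Pulmonary Mycobacterium avium Complex Disease
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cost-of-illness toolkit for guideline-based treatment of pulmonary
    Mycobacterium avium complex disease (MAC-PD) in the German statutory health
    insurance system. Computes per-day and per-course antimicrobial drug costs
    from a pack-price catalogue, builds the guideline-driven diagnostic and
    monitoring schedule and bills it against the outpatient fee schedule (EBM),
    enumerates the weighted space of treatment options (regimen by duration),
    summarises it by weighted Monte-Carlo simulation, and contrasts the
    outpatient totals with hospital DRG reimbursement. Ships the published
    price, fee, and option catalogues as plain-text fixtures and a synthetic
    perturbation generator for property testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
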
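Package: labetapbpk
Title: Whole-Body Physiologically Based Pharmacokinetic Modeling of Labetalol
Version: 0.1.0
Authors@R:
    person("PBPK", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: A whole-body physiologically based pharmacokinetic (PBPK) pipeline
    for labetalol after intravenous and oral administration. Builds reference
    adult physiologies and virtual populations, computes tissue:plasma partition
    coefficients from tissue composition with a global calibration to the
    clinical steady-state volume of distribution, splits total body clearance
    into renal filtration and well-stirred hepatic components, integrates the
    linear organ-level mass-balance system exactly by matrix exponentials,
    extrapolates to liver cirrhosis (Child-Pugh A/B/C) and chronic kidney
    disease populations through published physiological modifiers, performs
    non-compartmental analysis of concentration-time profiles, and evaluates
    predictions with observed/predicted fold ratios, average fold error,
    two-fold flags, percentile bands and box-whisker severity summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
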
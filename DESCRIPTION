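Package: alupbtk
Title: Age-Dependent Toxicokinetic Modelling of Aluminium Exposure from
    Diet and Subcutaneous Allergen Immunotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Physiologically based toxicokinetic (PBTK) simulation of
    aluminium (Al) body burden from birth to age 50. Implements an
    age-dependent multi-compartment model (plasma, bone, brain, liver,
    kidney, rest of body) with renal elimination driven by maturing
    glomerular filtration, a bone submodel coupled to age-dependent
    calcium turnover, continuous dietary intake, and zero-order release
    from subcutaneous adjuvant depots as used in allergen immunotherapy
    (SCIT). Includes virtual-population Monte Carlo with lognormal
    inter-individual variability and common random numbers across
    scenarios, a named scenario registry (dietary background and SCIT
    treatment schedules), and an assessment layer with percentile
    summaries, bootstrap confidence intervals for upper percentiles,
    percentile ratios, dry-to-wet-weight conversion and threshold
    exceedance statistics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
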
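Package: kaspcr
Title: KASP Genotype Calling and Chilling Requirement Prediction for Peach
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for endpoint KASP (Kompetitive Allele-Specific PCR)
    genotyping and DNA-test based prediction of chilling requirement (CR)
    in peach.  Converts raw two-channel FAM/HEX fluorescence into genotype
    calls with the delta method, infers four-SNP haplotype pairs
    (diplotypes) against the built-in Ppe.CR.1 marker panel, predicts CR
    classes and expected chill-hour ranges, and scores predictions against
    observed chill hours.  Also accumulates Weinberger chill hours from
    hourly temperature records, determines CR from budbreak forcing
    observations, screens KASP primer sets against standard design
    criteria, and simulates fluorescence plates and breeding cohorts with
    known truth so the whole pipeline can be validated without laboratory
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
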
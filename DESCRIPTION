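Package: plastinorm
Title: Enviromic and Genomic Dissection of Phenotypic Plasticity in
    Multi-Environment Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for dissecting crop phenotypic plasticity from
    multi-environment trial data. Derives environmental parameters
    (thermal time, photothermal time, diurnal range and related indices)
    from daily weather, searches growth-period windows for the
    environmental index most correlated with environmental trait means
    (the CERIS scan), fits per-accession linear reaction norms (intercept
    and slope), partitions variance and estimates heritability, predicts
    performance of untested genotypes and environments via
    ridge-regression BLUP, characterizes per-environment allelic effect
    dynamics and haplotypes, and classifies modes of plasticity change
    between accession groups such as landraces and cultivars. A seeded
    synthetic-data generator with known ground truth exercises the whole
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
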
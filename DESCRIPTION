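Package: heteropool
Title: Identifying Seeds of Heterotic Pools from Sparse Hybrid Testcross Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative-genetics workflow for identifying candidate heterotic
    pools among inbred parents of F1 test hybrids evaluated in sparse
    multi-environment yield trials. Provides a synthetic-data generator with
    known ground truth (Balding-Nichols founder panels, genetic maps, partially
    replicated multi-site trial designs), marker quality control, Rogers'
    genetic distance, principal coordinate analysis, a cross-validated
    admixture estimator of population structure, single-trial linear mixed
    models fitted by average-information REML with additive/non-additive
    partitioning and optional separable AR1 spatial residuals, factor-analytic
    modelling of additive genetic covariance across trial sites with
    hierarchical environment clustering, genomic BLUP with marker-effect
    backsolving, Shukla's stability variance with mean-versus-stability
    quadrant classification, and doubled-haploid progeny simulation with the
    usefulness criterion for comparing inter- and intra-population crosses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
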
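Package: rbgadapt
Title: Adaptive Recall-by-Genotype Study Design and Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design engine for adaptive recall-by-genotype (RbG) studies with
    a quantitative sensory testing endpoint. Provides exact noncentral-t power,
    sample-size and minimum-detectable-effect calculations for two-sample
    t-tests; O'Brien-Fleming alpha-spending and two-look group-sequential
    boundary computation; a sequential allele-group budget planner that turns a
    participant budget into per-stage futility cutoffs and interim efficacy
    thresholds; the pre-specified interim futility/efficacy decision rule;
    a Monte-Carlo simulator of the interim rule's operating characteristics
    with bootstrap confidence intervals; and a synthetic genotype-plus-phenotype
    cohort generator (Hardy-Weinberg genotypes under pairwise linkage
    disequilibrium, genotype-driven recall sampling, heat-pain-threshold
    phenotypes) so every stage of the design can be exercised end to end
    without access to cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    vcfR
Config/testthat/edition: 3
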
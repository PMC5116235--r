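Package: geneburden
Title: Rare-Variant Burden Testing and Etiological Fractions for Mendelian Disease Gene Panels
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Case-control rare-variant burden analysis for multigenic Mendelian
    diseases sequenced on clinical gene panels. Compares carrier frequencies of
    rare protein-altering variants between disease cohorts and a large reference
    population with coverage-adjusted denominators, computes per-gene case
    excess, Fisher's exact tests with Bonferroni family-wise control, odds
    ratios and etiological fractions with confidence intervals, refines
    missense interpretation with a beta order-statistic mutation-clustering
    scan over protein residues, audits previously reported pathogenic variants
    against reference allele frequencies, and simulates cohorts with known
    ground truth for calibration and power studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, graphics, grDevices, jsonlite
Suggests: testthat (>= 3.0.0), vcfR, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
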
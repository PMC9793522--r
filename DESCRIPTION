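Package: methylRF
Title: Random-Forest Comparative Analysis of DNA Methylome Risk Groups in Neuroblastoma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A workflow for comparative analysis of Illumina 450K-style DNA
    methylation beta-value matrices in neuroblastoma cohorts. Assigns clinical
    risk groups from INSS stage and MYCN amplification status, runs repeated
    hold-out random-forest classification with per-sample prediction tallies,
    discovers intermediate-risk subgroups by confusion-based relabeling,
    scores annotation-defined probe groups against random and
    select-percentile baselines, computes a per-probe Gini-split statistic
    with classifying-methylation-site (CMS) calls, and screens probes by
    delta-beta contrasts and per-probe log-rank survival tests with FDR
    control. Includes a synthetic 450K-like cohort generator so the full
    pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ranger,
    survival,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
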
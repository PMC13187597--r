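Package: topartr
Title: Composite Homologous Recombination Deficiency Scoring and
    Molecularly Guided Therapy Analytics for Cancer Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for precision-oncology cohort analysis of biliary tract
    and other solid tumors: composite homologous recombination deficiency
    (HRD) assessment with the TOP-ART scoring schema (germline and bi-allelic
    somatic lesions in homologous recombination repair genes, genomic scar
    scores HRD-LOH and LST, and SBS3 mutational-signature exposure),
    non-negative least squares decomposition of 96-channel mutation catalogs
    with bootstrap confidence calls, co-occurrence and mutual-exclusivity
    testing of alterations under a Poisson-binomial null with
    Benjamini-Hochberg correction, tumor mutational burden and cohort flow
    accounting, and outcome analytics for molecularly guided therapy
    including Kaplan-Meier estimation, log-rank tests, response rates, and
    the kernel-based Kaplan-Meier PFS2/PFS1 ratio benefit rate. A seeded
    synthetic-cohort generator reproduces the statistical structure the
    analysis assumes so the full pipeline runs without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
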
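Package: rorscan
Title: Cluster-Region Scans, Penetrance and Founder-Mutation Dating for
    BRCA1/2 Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Locates breast and ovarian cancer cluster regions (BCCR/OCCR)
    along the BRCA1/2 coding sequences from carrier case-control data using
    a ratio-of-odds-ratios (ROR) scan over near-equal-carrier bins with
    Benjamini-Hochberg correction; estimates per-mutation lifetime breast
    cancer risk with a Bayes allelic model against a population baseline;
    dates founder mutations by combining historical population growth rates
    with a best-correlation selection over externally estimated ages; and
    summarises STR founder haplotypes and geographic carrier distributions.
    Includes a seed-deterministic synthetic cohort generator so every stage
    is testable without protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
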
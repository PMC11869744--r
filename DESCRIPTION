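Package: strainshare
Title: Strain-Resolved Metagenomic Strain Sharing and Transmission Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Microdiversity-aware strain comparison from per-site allele count
    profiles (population and consensus average nucleotide identity), strain
    sharing networks over host dyads, a cumulative filter cascade that upgrades
    strain sharing events to putative transmission events, taxonomic and
    functional trait enrichment by permutation, and environmental covariate
    models of dyadic sharing rates. Includes a forward simulator of strain
    transmission through transplant and social cohorts with known ground
    truth, used to validate every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
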
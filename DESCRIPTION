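Package: idproteome
Title: Intrinsic Disorder Profiling and Comparison of Proteome Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing intrinsic protein disorder across proteome
    groups. Reads FASTA proteomes, per-residue disorder score tracks and
    expression tables; computes amino-acid composition enrichment profiles
    against a background set with bootstrap standard deviations and
    significance; summarises per-residue disorder tracks into per-protein
    average disorder scores (ADS), percentages of predicted disordered
    residues (PPDR) and mean disorder profiles (MDP); classifies proteins on
    an ADS/PPDR cutoff grid and in charge-hydropathy versus cumulative
    distribution function (CH-CDF) space; compares groups with one-way
    ANOVA, Tukey HSD and Pearson chi-squared tests; and computes
    expression-weighted normalized pool disorder scores. Includes a
    deterministic synthetic-data generator so every stage is testable
    without external predictor services.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
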
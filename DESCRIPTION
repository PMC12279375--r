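Package: p53dnx
Title: Dominant-Negative Analysis of N-Terminally Truncated p53 Isoforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative machinery for studying how the N-terminally
    truncated p53 isoforms Delta133p53 and Delta160p53 inhibit full-length
    p53. Provides C-alpha contact-map and Shrake-Rupley solvent-accessibility
    analysis of truncated DNA-binding domains, a binomial subunit-mixing
    model of tetramer assembly with inactivation-threshold hypotheses and
    theoretical inhibition curves, inference of the minimal number of
    isoform subunits needed to inactivate a tetramer from experimental
    inhibition curves, quantification of reporter, ChIP-qPCR, subcellular
    fractionation and caspase assays (including one-phase exponential-decay
    inhibition fits and p53 response-element consensus annotation), and
    seeded synthetic-data generators with exposed ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    bio3d,
    minpack.lm,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
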
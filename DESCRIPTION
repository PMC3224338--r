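Package: estsurvey
Title: Diagnostic Analysis of De Novo EST Survey Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the diagnostic analyses that accompany a de novo
    454-style EST (expressed sequence tag) survey of a species without a
    reference genome: clipping of primer-masked reads, best-hit gene
    tagging and per-library expression profiles, rarefaction of gene
    discovery with a hypergeometric closed form and hyperbolic
    saturation fits, per-position classification of unigene redundancy
    into putative biological variants versus putative sequencing errors
    from SAM pileups, pairwise assessment of cDNA library normalization
    by Spearman rank correlation, an annotation-retention proxy for
    assembly chimerism, and Fisher's-exact category enrichment with
    Benjamini-Hochberg correction and signed z-score matrices. A seeded
    synthetic 454 library generator with full ground truth (allelic and
    paralogous variants, skewed expression, partial normalization,
    homopolymer-biased errors, 3' positional bias) supports end-to-end
    validation of every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    IRanges,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
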
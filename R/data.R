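#' Published completeness-table statistics from a pea 454 EST survey
#'
#' Per-library saturation-fit parameters of the model `y = ax/(b+x)` (with
#' `a` the maximally detectable reference-gene count and `b` the
#' half-saturation read count), goodness of fit, total genes detected, the
#' printed slope at the final read count, and that final read count, for
#' the twelve libraries of a published 454 transcriptome survey of garden
#' pea plus their union (`"all"`). Shipped as a plain-text fixture so the
#' slope recomputation can be checked against the printed values.
#'
#' @return data frame, one row per library.
#' @export
pea_saturation_fits <- function() {
  read_tsv(system.file("extdata", "pea_saturation_fits.tsv",
                       package = "estsurvey"))
}

#' Published redundancy-classification counts for 14 pea reference cDNAs
#'
#' Per-reference position-class counts (identical / putative variant /
#' putative sequencing error) from the published unigene-versus-cDNA
#' alignment analysis of the same survey: reference name, GenBank
#' accession, length, unigenes mapped, and the three counts. One
#' reference (bHLH) received no alignments; its variant/error counts are
#' `NA`.
#'
#' @return data frame, one row per reference cDNA.
#' @export
pea_redundancy_counts <- function() {
  read_tsv(system.file("extdata", "pea_redundancy_counts.tsv",
                       package = "estsurvey"))
}
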
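#' Read a FASTA file preserving letter case
#'
#' Lowercase letters are the common soft-masking convention of screening
#' tools (dusted or vector-masked regions), so case must survive the round
#' trip into R. Returns a named character vector of sequences.
#'
#' @param path path to a FASTA file.
#' @return named character vector, one element per record.
#' @export
read_fasta <- function(path) {
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                             seqonly = FALSE)
  out <- vapply(recs, function(s) as.character(s)[1], character(1))
  names(out) <- vapply(recs, function(s) attr(s, "name"), character(1))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  seqinr::write.fasta(as.list(unname(seqs)), names = names(seqs),
                      file.out = path, nbchar = 70)
  invisible(path)
}

# Plain TSV helpers used by every stage; keep quoting off so outputs diff
# cleanly between runs.
#' @export
#' @rdname write_tsv
read_tsv <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "", stringsAsFactors = FALSE, ...)
}

#' Read/write tab-separated tables
#'
#' @param x data frame to write.
#' @param path file path.
#' @param ... passed to the underlying reader/writer.
#' @export
write_tsv <- function(x, path, ...) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     ...)
  invisible(path)
}
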
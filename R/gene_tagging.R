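blast_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                "bitscore")

#' Read a 12-column tabular homology-search hit file
#'
#' The standard BLAST tabular layout (outfmt 6): query, subject, percent
#' identity, alignment length, mismatches, gap opens, query start/end,
#' subject start/end, e-value, bit score. Subject coordinates on the minus
#' strand (start > end) are normalized by swapping, with the original
#' orientation kept in a `minus` column.
#'
#' @param path path to the hit file.
#' @return data frame with the 12 standard columns plus `minus`.
#' @export
read_hits <- function(path) {
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "#")
  bad <- which(nf != 12)
  if (length(bad))
    stop(sprintf("malformed hit row: expected 12 fields, got %d at line %d",
                 nf[bad[1]], bad[1]), call. = FALSE)
  h <- utils::read.table(path, sep = "\t", quote = "", comment.char = "#",
                         col.names = blast_cols, stringsAsFactors = FALSE)
  normalize_hits(h)
}

normalize_hits <- function(h) {
  stopifnot(all(blast_cols %in% names(h)))
  if (any(h$evalue < 0)) stop("negative e-value in hit table", call. = FALSE)
  h$minus <- h$sstart > h$send
  flip <- h$minus
  tmp <- h$sstart[flip]
  h$sstart[flip] <- h$send[flip]
  h$send[flip] <- tmp
  h
}

collapse_isoform <- function(id) sub("\\.[0-9]+$", "", id)

#' Assign each query its best reference-gene hit
#'
#' Keeps, per query, the passing hit (e-value <= `evalue_cutoff`) with the
#' highest bit score; ties are broken by lower e-value, then by the
#' lexicographically smallest subject id, so output is deterministic.
#' Subject ids of the form `GENE.n` are collapsed to the locus `GENE` by
#' default, so splice variants of one gene count as one tag.
#'
#' @param hits data frame as returned by [read_hits()] (or with the same
#'   columns).
#' @param evalue_cutoff maximum e-value for a hit to be considered
#'   (default `1e-4`).
#' @param collapse_isoforms collapse `GENE.n` subject ids to `GENE`
#'   (default `TRUE`).
#' @return data frame with one row per assigned query: `query_id`,
#'   `subject_id`, `evalue`, `bitscore`. Queries with no passing hit are
#'   absent.
#' @export
assign_best_hit <- function(hits, evalue_cutoff = 1e-4,
                            collapse_isoforms = TRUE) {
  if (!"minus" %in% names(hits)) hits <- normalize_hits(hits)
  h <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  if (!nrow(h)) {
    return(data.frame(query_id = character(0), subject_id = character(0),
                      evalue = numeric(0), bitscore = numeric(0)))
  }
  subj <- if (collapse_isoforms) collapse_isoform(h$sseqid) else h$sseqid
  o <- order(h$qseqid, -h$bitscore, h$evalue, subj, method = "radix")
  h <- h[o, ]; subj <- subj[o]
  first <- !duplicated(h$qseqid)
  data.frame(query_id = h$qseqid[first], subject_id = subj[first],
             evalue = h$evalue[first], bitscore = h$bitscore[first],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build a per-library expression profile from gene assignments
#'
#' Expression of a reference gene is simply the number of reads assigned to
#' it; genes never hit are implicitly zero.
#'
#' @param assignments data frame from [assign_best_hit()], or any data
#'   frame with a `subject_id` (or `gene_id`) column, one row per read.
#' @param library label for the profile.
#' @return data frame with `library`, `gene_id`, `count`, sorted by
#'   decreasing count; `sum(count)` equals `nrow(assignments)`.
#' @export
build_profile <- function(assignments, library = "lib1") {
  col <- intersect(c("subject_id", "gene_id"), names(assignments))[1]
  if (is.na(col)) stop("no subject_id/gene_id column", call. = FALSE)
  if (!nrow(assignments)) {
    return(data.frame(library = character(0), gene_id = character(0),
                      count = integer(0)))
  }
  tab <- sort(table(assignments[[col]]), decreasing = TRUE)
  data.frame(library = library, gene_id = names(tab),
             count = as.integer(tab), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Fraction of reference residues covered by at least one hit
#'
#' Unions the subject-coordinate intervals of all hits per subject
#' (after orientation normalization) and reports per-subject and aggregate
#' coverage over the subjects that received any hit.
#'
#' @param hits hit data frame ([read_hits()] layout).
#' @param subject_lengths named numeric vector of subject lengths
#'   (residues).
#' @return list with `per_subject` (data frame: `subject_id`, `length`,
#'   `covered`, `fraction`) and `aggregate` (covered residues over total
#'   residues of tagged subjects; 0 when there are no hits).
#' @export
proteome_coverage <- function(hits, subject_lengths) {
  if (!"minus" %in% names(hits)) hits <- normalize_hits(hits)
  if (!nrow(hits)) {
    return(list(per_subject = data.frame(subject_id = character(0),
                                         length = numeric(0),
                                         covered = integer(0),
                                         fraction = numeric(0)),
                aggregate = 0))
  }
  unknown <- setdiff(unique(hits$sseqid), names(subject_lengths))
  if (length(unknown))
    stop("missing subject lengths for: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  slen <- subject_lengths[hits$sseqid]
  if (any(hits$send > slen)) {
    warning("hit intervals exceeding subject length were clipped")
    hits$send <- pmin(hits$send, slen)
    hits$sstart <- pmin(hits$sstart, slen)
  }
  per <- lapply(split(hits, hits$sseqid), function(h) {
    ir <- IRanges::reduce(IRanges::IRanges(h$sstart, h$send))
    sum(IRanges::width(ir))
  })
  subj <- names(per)
  out <- data.frame(subject_id = subj,
                    length = as.numeric(subject_lengths[subj]),
                    covered = as.integer(unlist(per)),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$fraction <- out$covered / out$length
  list(per_subject = out,
       aggregate = sum(out$covered) / sum(out$length))
}

#' Count queries hitting reference termini versus anywhere
#'
#' For each subject, the 5' window is its first `window` residues and the
#' 3' window its last `window` residues (the whole subject when shorter).
#' A query counts for a window if any of its hit intervals overlaps it.
#' Under 3'-biased read sampling the 3'-window count exceeds the 5' one,
#' which is the diagnostic this summary exists for.
#'
#' @param hits hit data frame ([read_hits()] layout).
#' @param subject_lengths named numeric vector of subject lengths.
#' @param window terminal window size in residues (default 100).
#' @return one-row data frame: `n_queries`, `n_five_prime`, `n_three_prime`.
#' @export
terminal_window_bias <- function(hits, subject_lengths, window = 100) {
  if (!"minus" %in% names(hits)) hits <- normalize_hits(hits)
  if (!nrow(hits)) {
    return(data.frame(n_queries = 0L, n_five_prime = 0L, n_three_prime = 0L))
  }
  slen <- subject_lengths[hits$sseqid]
  five_end <- pmin(window, slen)
  three_start <- pmax(1, slen - window + 1)
  in5 <- hits$sstart <= five_end
  in3 <- hits$send >= three_start
  data.frame(n_queries = length(unique(hits$qseqid)),
             n_five_prime = length(unique(hits$qseqid[in5])),
             n_three_prime = length(unique(hits$qseqid[in3])))
}
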
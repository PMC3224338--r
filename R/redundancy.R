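#' Support thresholds separating biological variants from sequencing errors
#'
#' An alignment-column variant is called a putative biological variant
#' (allele or recent paralog) when it is shared widely enough that random
#' sequencing error is implausible: at least `snp_min_support` unigenes
#' carrying the identical point mutation, or at least `indel_min_support`
#' identical insertions/deletions whose length is divisible by three
#' (in-frame, hence tolerated in coding sequence). Any other observed
#' variant is a putative sequencing error.
#'
#' @param snp_min_support minimum identical-substitution support
#'   (default 25).
#' @param indel_min_support minimum identical in-frame indel support
#'   (default 4).
#' @param inframe_modulus indel length modulus defining "in-frame"
#'   (default 3).
#' @return list of class `classifier_thresholds`.
#' @export
classifier_thresholds <- function(snp_min_support = 25,
                                  indel_min_support = 4,
                                  inframe_modulus = 3) {
  stopifnot(snp_min_support >= 1, indel_min_support >= 1,
            inframe_modulus >= 1)
  structure(list(snp_min_support = as.integer(snp_min_support),
                 indel_min_support = as.integer(indel_min_support),
                 inframe_modulus = as.integer(inframe_modulus)),
            class = "classifier_thresholds")
}

#' Read mapped records from a SAM file
#'
#' Minimal reader for the eleven mandatory SAM columns; header lines and
#' unmapped records (`rname == "*"` or flag bit 0x4) are dropped.
#'
#' @param path path to a SAM file.
#' @return data frame: `qname`, `flag`, `rname`, `pos`, `mapq`, `cigar`,
#'   `seq`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) {
    return(data.frame(qname = character(0), flag = integer(0),
                      rname = character(0), pos = integer(0),
                      mapq = integer(0), cigar = character(0),
                      seq = character(0)))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) < 11)
  if (length(bad))
    stop("malformed SAM record at data line ", bad[1], call. = FALSE)
  d <- data.frame(
    qname = vapply(f, `[`, "", 1), flag = as.integer(vapply(f, `[`, "", 2)),
    rname = vapply(f, `[`, "", 3), pos = as.integer(vapply(f, `[`, "", 4)),
    mapq = as.integer(vapply(f, `[`, "", 5)),
    cigar = vapply(f, `[`, "", 6), seq = vapply(f, `[`, "", 10),
    stringsAsFactors = FALSE)
  d[d$rname != "*" & bitwAnd(d$flag, 4L) == 0L, , drop = FALSE]
}

parse_cigar <- function(cigar) {
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  if (m[1] == -1 ||
      sum(attr(m, "match.length")) != nchar(cigar))
    stop("invalid CIGAR: ", cigar, call. = FALSE)
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  list(len = as.integer(sub("[MIDNSHP=X]$", "", toks)),
       op = sub("^[0-9]+", "", toks))
}

#' Column-wise tallies of a unigene-versus-reference alignment
#'
#' Walks every alignment's CIGAR and accumulates, per reference position:
#' depth (number of covering queries, counting aligned and deleted
#' positions), substitution alleles with their support, insertion events
#' (anchored to the reference position immediately 5' of the inserted
#' bases, keyed by the inserted sequence), and deletion events (every
#' deleted position receives the event, keyed by deletion length). Records
#' whose CIGAR does not account for the full query sequence are skipped
#' with a warning and counted.
#'
#' @param sam data frame from [read_sam()] (or the same columns).
#' @param ref_name reference to tally; only records with this `rname` are
#'   used.
#' @param ref_seq reference sequence (character scalar).
#' @return list of class `pileup`: `reference`, `ref_length`, `depth`
#'   (integer vector over positions), `subs`/`ins`/`del` event data frames
#'   with support counts, `n_reads_mapped`, `n_skipped`.
#' @export
pileup_columns <- function(sam, ref_name, ref_seq) {
  sam <- sam[sam$rname == ref_name, , drop = FALSE]
  L <- nchar(ref_seq)
  ref_chars <- strsplit(toupper(ref_seq), "", fixed = TRUE)[[1]]
  depth <- integer(L)
  sub_key <- character(0); ins_key <- character(0); del_key <- character(0)
  n_skipped <- 0L

  for (i in seq_len(nrow(sam))) {
    cig <- tryCatch(parse_cigar(sam$cigar[i]), error = function(e) NULL)
    qseq <- toupper(sam$seq[i])
    qlen_cigar <- if (!is.null(cig))
      sum(cig$len[cig$op %in% c("M", "I", "S", "=", "X")])
    if (is.null(cig) || qlen_cigar != nchar(qseq)) {
      warning("skipping record with inconsistent CIGAR/sequence: ",
              sam$qname[i])
      n_skipped <- n_skipped + 1L
      next
    }
    rpos <- sam$pos[i]  # 1-based next reference position
    qpos <- 1L
    qchars <- strsplit(qseq, "", fixed = TRUE)[[1]]
    for (j in seq_along(cig$op)) {
      op <- cig$op[j]; len <- cig$len[j]
      if (op %in% c("M", "=", "X")) {
        span <- rpos:(rpos + len - 1L)
        ok <- span <= L
        depth[span[ok]] <- depth[span[ok]] + 1L
        qc <- qchars[qpos:(qpos + len - 1L)][ok]
        mism <- which(qc != ref_chars[span[ok]])
        if (length(mism)) {
          sub_key <- c(sub_key,
                       paste0(span[ok][mism], ":", qc[mism]))
        }
        rpos <- rpos + len; qpos <- qpos + len
      } else if (op == "I") {
        anchor <- rpos - 1L
        ins_key <- c(ins_key,
                     paste0(anchor, ":",
                            paste(qchars[qpos:(qpos + len - 1L)],
                                  collapse = "")))
        qpos <- qpos + len
      } else if (op == "D" || op == "N") {
        span <- rpos:(rpos + len - 1L)
        ok <- span <= L
        depth[span[ok]] <- depth[span[ok]] + 1L
        del_key <- c(del_key, paste0(span[ok], ":", len))
        rpos <- rpos + len
      } else if (op == "S") {
        qpos <- qpos + len
      }
      # H and P consume neither sequence we track
    }
  }

  tally <- function(keys, value_name) {
    if (!length(keys)) {
      return(stats::setNames(
        data.frame(pos = integer(0), v = character(0), support = integer(0),
                   stringsAsFactors = FALSE),
        c("pos", value_name, "support")))
    }
    tab <- table(keys)
    parts <- strsplit(names(tab), ":", fixed = TRUE)
    stats::setNames(
      data.frame(pos = as.integer(vapply(parts, `[`, "", 1)),
                 v = vapply(parts, `[`, "", 2),
                 support = as.integer(tab), row.names = NULL,
                 stringsAsFactors = FALSE),
      c("pos", value_name, "support"))
  }
  subs <- tally(sub_key, "base")
  ins <- tally(ins_key, "inserted")
  if (nrow(ins)) ins$len <- nchar(ins$inserted) else ins$len <- integer(0)
  del <- tally(del_key, "len")
  del$len <- as.integer(del$len)

  structure(list(reference = ref_name, ref_length = L, depth = depth,
                 subs = subs, ins = ins, del = del,
                 n_reads_mapped = nrow(sam) - n_skipped,
                 n_skipped = n_skipped),
            class = "pileup")
}

#' Classify alignment columns as identical, putative variant, or error
#'
#' Per covered reference position:
#' * identical — covered and carrying no variant event at all;
#' * putative variant — some substitution allele supported by at least
#'   `thr$snp_min_support` queries, or some identical in-frame indel event
#'   (length divisible by `thr$inframe_modulus`) supported by at least
#'   `thr$indel_min_support`;
#' * putative sequencing error — some substitution allele seen but below
#'   the support threshold, or any out-of-frame indel event.
#'
#' Variant and error flags can co-occur at one position (different alleles),
#' so the percentage columns of the summary may sum above 100. In-frame
#' indels below their support threshold contribute to neither class by
#' default; set `inframe_below_threshold_as_error = TRUE` to count them as
#' errors.
#'
#' @param pileup a [pileup_columns()] result.
#' @param thr a [classifier_thresholds()].
#' @param inframe_below_threshold_as_error see above.
#' @return list of class `position_classes`: `reference`, `ref_length`,
#'   `n_reads_mapped`, `n_identical`, `n_putative_variant`,
#'   `n_putative_error`, and a logical flag matrix `flags`
#'   (positions x identical/variant/error).
#' @export
classify_positions <- function(pileup, thr = classifier_thresholds(),
                               inframe_below_threshold_as_error = FALSE) {
  stopifnot(inherits(pileup, "pileup"),
            inherits(thr, "classifier_thresholds"))
  L <- pileup$ref_length
  covered <- pileup$depth >= 1L
  variant <- logical(L); error <- logical(L); any_event <- logical(L)

  s <- pileup$subs
  if (nrow(s)) {
    any_event[unique(s$pos)] <- TRUE
    variant[unique(s$pos[s$support >= thr$snp_min_support])] <- TRUE
    error[unique(s$pos[s$support < thr$snp_min_support])] <- TRUE
  }
  for (ev in list(pileup$ins, pileup$del)) {
    if (!nrow(ev)) next
    inframe <- ev$len %% thr$inframe_modulus == 0L
    anch <- ev$pos
    ok <- anch >= 1L & anch <= L
    any_event[unique(anch[ok])] <- TRUE
    variant[unique(anch[ok & inframe &
                          ev$support >= thr$indel_min_support])] <- TRUE
    error[unique(anch[ok & !inframe])] <- TRUE
    if (inframe_below_threshold_as_error)
      error[unique(anch[ok & inframe &
                          ev$support < thr$indel_min_support])] <- TRUE
  }

  identical_pos <- covered & !any_event
  flags <- cbind(identical = identical_pos,
                 variant = variant, error = error)
  structure(list(reference = pileup$reference, ref_length = L,
                 n_reads_mapped = pileup$n_reads_mapped,
                 n_identical = sum(identical_pos),
                 n_putative_variant = sum(variant),
                 n_putative_error = sum(error),
                 flags = flags),
            class = "position_classes")
}

#' Summarize per-reference position classes as a report table
#'
#' One row per reference: length, reads mapped, and the three class counts
#' with percentages of the reference length rounded to one decimal place.
#' References with zero mapped reads get `NA` percentages (printed as
#' dashes in the original report layout). Because variant and error flags
#' can co-occur, percentages may sum above 100.
#'
#' @param x a list of [classify_positions()] results, or a data frame with
#'   columns `reference`, `ref_length`, `n_reads_mapped`, `n_identical`,
#'   `n_putative_variant`, `n_putative_error` (e.g. externally published
#'   counts).
#' @return data frame with counts plus `pct_identical`, `pct_variant`,
#'   `pct_error`.
#' @export
summarize_table <- function(x) {
  if (is.data.frame(x)) {
    d <- x
  } else {
    d <- do.call(rbind, lapply(x, function(r) {
      data.frame(reference = r$reference, ref_length = r$ref_length,
                 n_reads_mapped = r$n_reads_mapped,
                 n_identical = r$n_identical,
                 n_putative_variant = r$n_putative_variant,
                 n_putative_error = r$n_putative_error,
                 stringsAsFactors = FALSE)
    }))
  }
  pct <- function(cnt) round(100 * cnt / d$ref_length, 1)
  d$pct_identical <- pct(d$n_identical)
  d$pct_variant <- pct(d$n_putative_variant)
  d$pct_error <- pct(d$n_putative_error)
  none <- d$n_reads_mapped == 0
  d[none, c("pct_identical", "pct_variant", "pct_error")] <- NA_real_
  rownames(d) <- NULL
  d
}

#' Spearman correlation between read counts and unigene counts per gene
#'
#' A conservative assembly should turn many reads of one transcript into
#' few unigenes, so a strong positive correlation between the number of
#' reads and the number of unigenes matching a reference gene is the
#' signature of under-assembly of abundant transcripts.
#'
#' @param reads_per_gene named numeric vector: reference gene -> number of
#'   reads.
#' @param unigenes_per_gene named numeric vector: reference gene -> number
#'   of unigenes.
#' @return Spearman rho (average ranks for ties), over the shared genes.
#' @export
reads_vs_unigenes_correlation <- function(reads_per_gene,
                                          unigenes_per_gene) {
  shared <- intersect(names(reads_per_gene), names(unigenes_per_gene))
  if (length(shared) < 3)
    stop("need at least 3 shared genes", call. = FALSE)
  stats::cor(reads_per_gene[shared], unigenes_per_gene[shared],
             method = "spearman")
}
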
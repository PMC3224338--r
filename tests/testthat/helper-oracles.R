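# Independent oracles used across the suite. These deliberately take a
# different route than the package code: the alignment oracle works on a
# materialized query-by-position matrix, the Fisher oracle enumerates
# hypergeometric tables directly.

# --- toy alignment generator -------------------------------------------
# Builds the alignment matrix FIRST (the truth representation) and only
# then serializes each query to SAM pos/CIGAR/seq, so the matrix is
# independent of the package's CIGAR walker.
#
# Matrix cells: NA = not covered, "-" = deleted, otherwise the query base.
# Insertions are kept as (query, anchor_pos, seq) records.
random_toy_alignment <- function(n_queries = 3, ref_len = 15,
                                 p_sub = 0.15, p_del = 0.08, p_ins = 0.08) {
  ref <- sample(c("A", "C", "G", "T"), ref_len, replace = TRUE)
  mat <- matrix(NA_character_, n_queries, ref_len)
  ins <- list()
  sam_rows <- list()
  for (q in seq_len(n_queries)) {
    s <- sample.int(ref_len - 4L, 1)
    e <- sample(min(s + 3L, ref_len):ref_len, 1)
    p <- s
    just_deleted <- FALSE
    while (p <= e) {
      u <- runif(1)
      if (u < p_del && p > s && p < e) {
        dl <- min(sample.int(3, 1), e - p)  # never delete the last column
        mat[q, p:(p + dl - 1)] <- "-"
        p <- p + dl
        just_deleted <- TRUE
      } else if (u < p_del + p_sub) {
        mat[q, p] <- sample(setdiff(c("A", "C", "G", "T"), ref[p]), 1)
        p <- p + 1L
        just_deleted <- FALSE
      } else {
        mat[q, p] <- ref[p]
        p <- p + 1L
        just_deleted <- FALSE
      }
      # no insertion directly after a deletion: aligners never emit
      # adjacent D and I ops, and the matrix view would merge the
      # deletion runs flanking such an insertion
      if (p <= e && !just_deleted && runif(1) < p_ins) {
        iseq <- paste(sample(c("A", "C", "G", "T"), sample.int(3, 1),
                             replace = TRUE), collapse = "")
        ins[[length(ins) + 1]] <- list(q = q, pos = p - 1L, seq = iseq)
      }
    }
    sam_rows[[q]] <- serialize_query(mat[q, ], ins, q, s)
  }
  list(ref = paste(ref, collapse = ""), mat = mat, ins = ins,
       sam = do.call(rbind, sam_rows))
}

# Turn one matrix row (plus its insertions) into SAM fields.
serialize_query <- function(row, ins, q, start) {
  covered <- which(!is.na(row))
  s <- min(covered); e <- max(covered)
  my_ins <- Filter(function(x) x$q == q, ins)
  ops <- character(0); lens <- integer(0); seq <- character(0)
  push <- function(op, len) {
    if (length(ops) && ops[length(ops)] == op) {
      lens[length(lens)] <<- lens[length(lens)] + len
    } else {
      ops[length(ops) + 1] <<- op; lens[length(lens) + 1] <<- len
    }
  }
  for (p in s:e) {
    if (row[p] == "-") {
      push("D", 1L)
    } else {
      push("M", 1L)
      seq <- c(seq, row[p])
    }
    hit <- Filter(function(x) x$pos == p, my_ins)
    for (h in hit) {
      push("I", nchar(h$seq))
      seq <- c(seq, h$seq)
    }
  }
  data.frame(qname = sprintf("q%d", q), flag = 0L, rname = "ref",
             pos = s, mapq = 60L,
             cigar = paste0(lens, ops, collapse = ""),
             seq = paste(seq, collapse = ""), stringsAsFactors = FALSE)
}

# Brute-force position classifier over the materialized matrix.
oracle_classify <- function(toy, thr = classifier_thresholds(),
                            inframe_below_threshold_as_error = FALSE) {
  ref <- strsplit(toy$ref, "")[[1]]
  L <- length(ref)
  nq <- nrow(toy$mat)
  depth <- colSums(!is.na(toy$mat))
  variant <- logical(L); error <- logical(L); any_event <- logical(L)

  # substitutions keyed by (pos, base)
  for (p in seq_len(L)) {
    cells <- toy$mat[, p]
    subs <- cells[!is.na(cells) & cells != "-" & cells != ref[p]]
    if (length(subs)) {
      any_event[p] <- TRUE
      supp <- table(subs)
      if (any(supp >= thr$snp_min_support)) variant[p] <- TRUE
      if (any(supp < thr$snp_min_support)) error[p] <- TRUE
    }
  }
  # deletions: contiguous "-" runs per query; every deleted position gets
  # the event keyed by run length
  del_keys <- character(0)
  for (q in seq_len(nq)) {
    r <- rle(ifelse(is.na(toy$mat[q, ]), "NA", toy$mat[q, ]) == "-")
    endp <- cumsum(r$lengths)
    for (j in which(r$values)) {
      len <- r$lengths[j]
      pos <- (endp[j] - len + 1):endp[j]
      del_keys <- c(del_keys, paste0(pos, ":", len))
    }
  }
  # insertions keyed by (anchor, seq)
  ins_keys <- vapply(toy$ins, function(x) paste0(x$pos, ":", x$seq), "")
  for (keys in list(del_keys, ins_keys)) {
    if (!length(keys)) next
    tab <- table(keys)
    parts <- strsplit(names(tab), ":", fixed = TRUE)
    pos <- as.integer(vapply(parts, `[`, "", 1))
    len <- vapply(seq_along(parts), function(i) {
      v <- parts[[i]][2]
      if (grepl("^[0-9]+$", v)) as.integer(v) else nchar(v)
    }, integer(1))
    supp <- as.integer(tab)
    inframe <- len %% thr$inframe_modulus == 0
    any_event[pos] <- TRUE
    variant[unique(pos[inframe & supp >= thr$indel_min_support])] <- TRUE
    error[unique(pos[!inframe])] <- TRUE
    if (inframe_below_threshold_as_error)
      error[unique(pos[inframe & supp < thr$indel_min_support])] <- TRUE
  }
  ident <- depth >= 1 & !any_event
  list(n_identical = sum(ident), n_putative_variant = sum(variant),
       n_putative_error = sum(error), depth = depth)
}

# Two-sided Fisher p by exhaustive hypergeometric enumeration.
oracle_fisher_p <- function(k, n, K, N) {
  lo <- max(0, K + n - N); hi <- min(n, K)
  probs <- dhyper(lo:hi, K, N - K, n)
  p_obs <- dhyper(k, K, N - K, n)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Small default simulation shared by several tests.
tiny_sim <- function(seed = 1, n_genes = 50, n_reads = 1500, ...) {
  cfg <- sim_config(n_genes = n_genes, n_reads = n_reads, seed = seed, ...)
  tx <- build_transcriptome(cfg)
  w <- draw_weights(tx, cfg)
  list(cfg = cfg, tx = tx, w = w,
       raw = stats::setNames(w$raw_weight, w$gene_id),
       norm = stats::setNames(w$norm_weight, w$gene_id))
}
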
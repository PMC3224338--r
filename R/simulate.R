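#' Configuration for the synthetic 454 EST library generator
#'
#' Bundles every knob of the simulator with defaults chosen to emulate a
#' pyrosequencing EST survey: a Zipf-skewed expression profile, partial
#' normalization modelled as exponentiation of the sampling weights,
#' GS20-like (~100 nt) or GS FLX-like (~230 nt) read lengths, a total
#' per-base error rate of about 1\% concentrated at homopolymer runs, and a
#' mild 3' positional bias from poly-dT priming.
#'
#' @param n_genes number of base genes in the transcriptome.
#' @param length_range transcript length range in nt (uniform draw).
#' @param expression_model `"zipf"` (discrete power law over gene ranks,
#'   default) or `"lognormal"`.
#' @param expression_shape power-law exponent (Zipf) or log-sd (log-normal).
#' @param gamma normalization flattening exponent in `[0, 1]`: sampling
#'   weights of a normalized library are proportional to `raw^gamma`, so 1
#'   means no normalization and 0 full flattening. The default 0.45 yields
#'   Spearman rank correlations between normalized and non-normalized
#'   profiles of roughly 0.65-0.80 at survey-like depths.
#' @param platform `"GS20"` or `"GSFLX"`; sets read-length defaults
#'   (100 +/- 10 nt and 230 +/- 20 nt respectively) unless overridden.
#' @param read_length_mean,read_length_sd read length distribution in nt;
#'   `NULL` means use the platform default.
#' @param sub_rate per-base substitution probability.
#' @param hp_indel_rate per-homopolymer-run indel probability scale: a run
#'   of length L >= 2 gains or loses one repeat unit with probability
#'   `hp_indel_rate * (L - 1)`.
#' @param three_prime_lambda geometric decay of read start positions toward
#'   the 5' end; 0 gives uniform starts, larger values concentrate reads at
#'   the 3' end.
#' @param p_allelic probability a gene carries a second haplotype.
#' @param allelic_div per-base divergence between haplotypes.
#' @param p_paralog probability a gene has a diverged duplicate (emitted as
#'   a separate gene sharing a paralog group).
#' @param paralog_div per-base divergence of paralog copies.
#' @param primer_mask_rate fraction of reads carrying a soft-masked
#'   (lowercase) primer/adapter prefix, emulating screened contamination.
#' @param primer_length length of that masked prefix in nt.
#' @param n_reads reads per generated library.
#' @param seed master RNG seed; all stages derive deterministic substreams.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       length_range = c(500, 3000),
                       expression_model = c("zipf", "lognormal"),
                       expression_shape = 1.5,
                       gamma = 0.45,
                       platform = c("GS20", "GSFLX"),
                       read_length_mean = NULL,
                       read_length_sd = NULL,
                       sub_rate = 0.008,
                       hp_indel_rate = 0.02,
                       three_prime_lambda = 0.005,
                       p_allelic = 0.3,
                       allelic_div = 0.005,
                       p_paralog = 0.1,
                       paralog_div = 0.03,
                       primer_mask_rate = 0,
                       primer_length = 20,
                       n_reads = 20000,
                       seed = 1L) {
  expression_model <- match.arg(expression_model)
  platform <- match.arg(platform)
  defaults <- list(GS20 = c(100, 10), GSFLX = c(230, 20))[[platform]]
  if (is.null(read_length_mean)) read_length_mean <- defaults[1]
  if (is.null(read_length_sd))  read_length_sd  <- defaults[2]

  stopifnot(n_genes >= 1, length(length_range) == 2,
            length_range[1] >= 1, length_range[1] <= length_range[2],
            expression_shape > 0, n_reads >= 1,
            read_length_mean > 0, read_length_sd >= 0,
            primer_length >= 1)
  for (p in c(gamma, sub_rate, p_allelic, allelic_div, p_paralog,
              paralog_div, primer_mask_rate)) {
    if (!is.numeric(p) || p < 0 || p > 1)
      stop("probability parameters must lie in [0, 1]", call. = FALSE)
  }
  if (hp_indel_rate < 0 || three_prime_lambda < 0)
    stop("rates must be non-negative", call. = FALSE)

  structure(list(
    n_genes = as.integer(n_genes), length_range = as.integer(length_range),
    expression_model = expression_model, expression_shape = expression_shape,
    gamma = gamma, platform = platform,
    read_length_mean = read_length_mean, read_length_sd = read_length_sd,
    sub_rate = sub_rate, hp_indel_rate = hp_indel_rate,
    three_prime_lambda = three_prime_lambda,
    p_allelic = p_allelic, allelic_div = allelic_div,
    p_paralog = p_paralog, paralog_div = paralog_div,
    primer_mask_rate = primer_mask_rate,
    primer_length = as.integer(primer_length),
    n_reads = as.integer(n_reads), seed = as.integer(seed)
  ), class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Substitute each base independently with probability `div`, always to a
# different base. Returns c(sequence, n_changed).
diverge_seq <- function(seq, div) {
  if (div == 0) return(list(seq = seq, n = 0L))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < div)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  list(seq = paste(chars, collapse = ""), n = length(hit))
}

#' Build a synthetic transcriptome with allelic and paralogous variation
#'
#' Each base gene gets a random transcript; with probability `p_allelic` a
#' second haplotype diverged by `allelic_div` per base is added, and with
#' probability `p_paralog` a duplicated gene (suffix `"p"`) diverged by
#' `paralog_div` is emitted as a separate gene sharing the original's
#' paralog group. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_transcriptome` with elements `sequences`
#'   (named list, one character vector of haplotype sequences per gene) and
#'   `paralog_group` (named character vector, gene id -> group id).
#' @export
build_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ids <- sprintf("g%04d", seq_len(config$n_genes))
  len_choices <- seq(config$length_range[1], config$length_range[2])
  lens <- if (length(len_choices) == 1L) {
    rep(len_choices, config$n_genes)  # sample() would misread a scalar
  } else {
    sample(len_choices, config$n_genes, replace = TRUE)
  }
  sequences <- list()
  paralog_group <- character(0)
  for (i in seq_len(config$n_genes)) {
    base <- random_dna(lens[i])
    haps <- base
    if (stats::runif(1) < config$p_allelic)
      haps <- c(haps, diverge_seq(base, config$allelic_div)$seq)
    sequences[[ids[i]]] <- haps
    paralog_group[ids[i]] <- ids[i]
    if (stats::runif(1) < config$p_paralog) {
      pid <- paste0(ids[i], "p")
      phaps <- diverge_seq(base, config$paralog_div)$seq
      if (stats::runif(1) < config$p_allelic)
        phaps <- c(phaps, diverge_seq(phaps[1], config$allelic_div)$seq)
      sequences[[pid]] <- phaps
      paralog_group[pid] <- ids[i]
    }
  }
  structure(list(sequences = sequences, paralog_group = paralog_group),
            class = "sim_transcriptome")
}

#' Flatten a weight vector the way cDNA normalization does
#'
#' Duplex-specific-nuclease normalization depletes abundant cDNAs only
#' partially; this is modelled as exponentiation: `w^gamma`, renormalized.
#' `gamma = 1` leaves weights unchanged, `gamma = 0` flattens completely.
#'
#' @param w non-negative weight vector.
#' @param gamma flattening exponent in `[0, 1]`.
#' @return weights summing to 1.
#' @export
normalize_weights <- function(w, gamma) {
  stopifnot(all(w >= 0), gamma >= 0, gamma <= 1)
  v <- w^gamma
  v / sum(v)
}

#' Draw per-gene sampling weights (raw and normalized)
#'
#' Raw weights follow the configured expression model over a random
#' permutation of the genes (so abundance is unlinked from gene id); the
#' normalized column is [normalize_weights()] applied with `config$gamma`.
#'
#' @param transcriptome a [build_transcriptome()] result.
#' @param config a [sim_config()].
#' @return data frame with `gene_id`, `raw_weight`, `norm_weight`; both
#'   weight columns sum to 1.
#' @export
draw_weights <- function(transcriptome, config) {
  stopifnot(inherits(transcriptome, "sim_transcriptome"))
  set.seed(config$seed + 1L)
  ids <- names(transcriptome$sequences)
  g <- length(ids)
  if (config$expression_model == "zipf") {
    ranks <- sample(g)
    raw <- ranks^(-config$expression_shape)
  } else {
    raw <- exp(stats::rnorm(g, sd = config$expression_shape))
  }
  raw <- raw / sum(raw)
  data.frame(gene_id = ids, raw_weight = raw,
             norm_weight = normalize_weights(raw, config$gamma),
             stringsAsFactors = FALSE)
}

#' Generate a 454-style read library with full ground truth
#'
#' Reads are drawn i.i.d. by gene weight, a haplotype is picked uniformly,
#' read length is Gaussian around the platform mean (truncated to the
#' transcript), and start positions decay geometrically away from the 3'
#' end (`three_prime_lambda = 0` gives uniform starts). Substitutions are
#' planted per base at `sub_rate`; each homopolymer run of length L >= 2 in
#' the read gains or loses one repeat unit with probability
#' `hp_indel_rate * (L - 1)`. Optionally a lowercase primer prefix is
#' prepended to a fraction of reads to emulate masked contamination.
#'
#' @param transcriptome a [build_transcriptome()] result.
#' @param weights named numeric vector of sampling weights (one per gene,
#'   summing to 1), e.g. a column of [draw_weights()].
#' @param config a [sim_config()].
#' @param library label stored with each read.
#' @param seed RNG seed for this library; defaults to a substream derived
#'   from `config$seed`.
#' @return list with `reads` (data frame: `id`, `sequence`, `library`) and
#'   `truth` (list: `reads` data frame with source gene, haplotype, start,
#'   end, strand and planted-error counts; `genes` data frame with the
#'   weight used and the realized read count, summing to `n_reads`).
#' @export
generate_reads <- function(transcriptome, weights, config,
                           library = "lib1", seed = config$seed + 2L) {
  stopifnot(inherits(transcriptome, "sim_transcriptome"),
            !is.null(names(weights)),
            all(names(weights) %in% names(transcriptome$sequences)))
  set.seed(seed)
  n <- config$n_reads
  ids <- names(weights)
  gene <- sample(ids, n, replace = TRUE, prob = weights)
  seqs <- transcriptome$sequences

  read_id <- sprintf("%s_r%06d", library, seq_len(n))
  hap <- integer(n); start <- integer(n); end <- integer(n)
  n_sub <- integer(n); n_indel <- integer(n); truncated <- logical(n)
  out_seq <- character(n)

  raw_len <- pmax(1L, as.integer(round(
    stats::rnorm(n, config$read_length_mean, config$read_length_sd))))
  lam <- config$three_prime_lambda
  q <- exp(-lam)
  alt_base <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                   G = c("A", "C", "T"), T = c("A", "C", "G"))

  for (i in seq_len(n)) {
    haps <- seqs[[gene[i]]]
    hap[i] <- if (length(haps) == 1L) 1L else sample.int(length(haps), 1)
    tx <- haps[[hap[i]]]
    tl <- nchar(tx)
    rl <- raw_len[i]
    if (rl > tl) { rl <- tl; truncated[i] <- TRUE }
    smax <- tl - rl + 1L
    if (lam == 0 || smax == 1L) {
      s <- sample.int(smax, 1)
    } else {
      # truncated-geometric distance from the 3'-most feasible start:
      # P(d = j) proportional to exp(-lam * j), j in 0..smax-1
      u <- stats::runif(1)
      d <- min(smax - 1L, floor(log(1 - u * (1 - q^smax)) / log(q)))
      s <- smax - as.integer(d)
    }
    start[i] <- s; end[i] <- s + rl - 1L
    chars <- strsplit(substr(tx, s, end[i]), "", fixed = TRUE)[[1]]

    if (config$sub_rate > 0) {
      ns <- stats::rbinom(1, rl, config$sub_rate)
      if (ns > 0) {
        hit <- sample.int(rl, ns)
        for (j in hit)
          chars[j] <- alt_base[[chars[j]]][sample.int(3L, 1)]
        n_sub[i] <- ns
      }
    }
    if (config$hp_indel_rate > 0) {
      r <- rle(chars)
      keep <- which(r$lengths >= 2L)
      if (length(keep)) {
        run_end <- cumsum(r$lengths)
        p_ev <- pmin(1, config$hp_indel_rate * (r$lengths[keep] - 1L))
        ev <- keep[stats::runif(length(keep)) < p_ev]
        # apply right-to-left so earlier run coordinates stay valid
        for (j in rev(ev)) {
          at <- run_end[j] - r$lengths[j] + 1L
          if (stats::runif(1) < 0.5) {
            chars <- append(chars, r$values[j], after = at)
          } else {
            chars <- chars[-at]
          }
        }
        n_indel[i] <- length(ev)
      }
    }
    out_seq[i] <- paste(chars, collapse = "")
  }

  if (config$primer_mask_rate > 0) {
    masked <- which(stats::runif(n) < config$primer_mask_rate)
    for (i in masked) {
      out_seq[i] <- paste0(tolower(random_dna(config$primer_length)),
                           out_seq[i])
    }
  }

  counts <- table(factor(gene, levels = ids))
  truth_genes <- data.frame(gene_id = ids,
                            weight = as.numeric(weights),
                            count = as.integer(counts),
                            stringsAsFactors = FALSE)
  list(
    reads = data.frame(id = read_id, sequence = out_seq, library = library,
                       stringsAsFactors = FALSE),
    truth = list(
      reads = data.frame(read_id = read_id, gene_id = gene, haplotype = hap,
                         start = start, end = end, strand = "+",
                         n_sub = n_sub, n_indel = n_indel,
                         truncated = truncated, stringsAsFactors = FALSE),
      genes = truth_genes
    )
  )
}

#' Assign a random hierarchical category map to simulated genes
#'
#' Produces MapMan-bincode-like dotted codes: each gene receives one leaf
#' code drawn from a two-level hierarchy (`n_top` top-level bins, each with
#' `n_children` children). Paralog copies share their group's category, as
#' duplicated genes share function.
#'
#' @param transcriptome a [build_transcriptome()] result.
#' @param n_top number of top-level categories.
#' @param n_children children per top-level category.
#' @param seed RNG seed.
#' @return data frame with `gene_id`, `code`.
#' @export
sim_category_map <- function(transcriptome, n_top = 25, n_children = 3,
                             seed = 99L) {
  set.seed(seed)
  groups <- unique(transcriptome$paralog_group)
  codes <- sprintf("%d.%d", sample.int(n_top, length(groups), replace = TRUE),
                   sample.int(n_children, length(groups), replace = TRUE))
  names(codes) <- groups
  ids <- names(transcriptome$sequences)
  data.frame(gene_id = ids, code = codes[transcriptome$paralog_group[ids]],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Simulate unigenes from a haplotype mixture, as SAM alignments
#'
#' Emulates the redundancy situation of a conservative EST assembly: many
#' unigenes derive from one reference cDNA, some carrying shared biological
#' variants (a second haplotype), all carrying sporadic sequencing errors.
#' Unigenes are substrings of one of two haplotypes; haplotype 2 differs
#' from the reference at `variant_positions` (substitutions to a fixed
#' alternative base) and optionally carries one in-frame insertion.
#' Random per-base substitution errors are added at `error_rate`.
#' Alignments are emitted as SAM records against haplotype 1.
#'
#' @param ref_seq reference (haplotype 1) sequence.
#' @param n_unigenes number of unigenes to emit.
#' @param variant_positions 1-based reference positions carrying the
#'   haplotype-2 substitution alleles.
#' @param p_hap2 fraction of unigenes drawn from haplotype 2.
#' @param error_rate per-base random substitution error rate.
#' @param insertion optional list `list(pos =, seq =)`: an insertion
#'   carried by haplotype 2, anchored after reference position `pos`.
#' @param min_len,max_len unigene length range.
#' @param seed RNG seed.
#' @return list: `sam` (data frame of SAM fields), `truth` (planted variant
#'   positions and per-unigene error positions in reference coordinates).
#' @export
simulate_unigene_alignment <- function(ref_seq, n_unigenes = 60,
                                       variant_positions = integer(0),
                                       p_hap2 = 0.5, error_rate = 0.005,
                                       insertion = NULL,
                                       min_len = 80, max_len = 250,
                                       seed = 1L) {
  set.seed(seed)
  L <- nchar(ref_seq)
  ref_chars <- strsplit(ref_seq, "", fixed = TRUE)[[1]]
  alt <- vapply(variant_positions, function(p)
    sample(setdiff(c("A", "C", "G", "T"), ref_chars[p]), 1), character(1))

  qname <- sprintf("u%04d", seq_len(n_unigenes))
  rows <- vector("list", n_unigenes)
  err_pos <- vector("list", n_unigenes)
  for (i in seq_len(n_unigenes)) {
    len <- sample(min_len:min(max_len, L), 1)
    pos <- sample.int(L - len + 1L, 1)
    endp <- pos + len - 1L
    is2 <- stats::runif(1) < p_hap2
    chars <- ref_chars[pos:endp]
    if (is2 && length(variant_positions)) {
      inwin <- which(variant_positions >= pos & variant_positions <= endp)
      chars[variant_positions[inwin] - pos + 1L] <- alt[inwin]
    }
    ehit <- which(stats::runif(len) < error_rate)
    for (j in ehit) chars[j] <- sample(setdiff(c("A", "C", "G", "T"),
                                               chars[j]), 1)
    err_pos[[i]] <- pos + ehit - 1L
    cigar <- paste0(len, "M")
    seqstr <- paste(chars, collapse = "")
    if (is2 && !is.null(insertion) &&
        insertion$pos >= pos && insertion$pos < endp) {
      k <- insertion$pos - pos + 1L
      seqstr <- paste0(substr(seqstr, 1, k), insertion$seq,
                       substr(seqstr, k + 1, len))
      cigar <- sprintf("%dM%dI%dM", k, nchar(insertion$seq), len - k)
    }
    rows[[i]] <- data.frame(qname = qname[i], flag = 0L, rname = "ref",
                            pos = pos, mapq = 60L, cigar = cigar,
                            seq = seqstr, stringsAsFactors = FALSE)
  }
  list(sam = do.call(rbind, rows),
       truth = list(variant_positions = variant_positions,
                    variant_alleles = alt,
                    insertion = insertion,
                    error_positions = sort(unique(unlist(err_pos)))))
}

#' Write alignment records as a SAM file
#'
#' @param sam data frame with columns `qname`, `flag`, `rname`, `pos`,
#'   `mapq`, `cigar`, `seq` (one reference).
#' @param ref_lengths named integer vector of reference lengths for the
#'   `@SQ` header lines.
#' @param path output path.
#' @export
write_sam <- function(sam, ref_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (rn in names(ref_lengths))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", rn, ref_lengths[[rn]]), con)
  apply(sam, 1, function(r) {
    writeLines(paste(r[["qname"]], r[["flag"]], r[["rname"]], r[["pos"]],
                     r[["mapq"]], r[["cigar"]], "*", 0, 0, r[["seq"]], "*",
                     sep = "\t"), con)
  })
  invisible(path)
}

#' Write a simulated library to FASTA plus truth tables
#'
#' @param lib a [generate_reads()] result.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix, defaulting to the library label.
#' @return invisibly, the paths written.
#' @export
write_library <- function(lib, dir, prefix = lib$reads$library[1]) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(prefix, "_reads.fasta"))
  seqs <- lib$reads$sequence
  names(seqs) <- lib$reads$id
  write_fasta(seqs, fa)
  rt <- file.path(dir, paste0(prefix, "_truth_reads.tsv"))
  gt <- file.path(dir, paste0(prefix, "_truth_genes.tsv"))
  write_tsv(lib$truth$reads, rt)
  write_tsv(lib$truth$genes, gt)
  invisible(c(fa, rt, gt))
}
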
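#' Trimming configuration for masked-read clean-up
#'
#' Screening tools mark primer or vector contamination by X-masking
#' (crossmatch) or lowercase soft-masking (dust); clean-up keeps the longest
#' clear segment of each read and drops reads that end up shorter than
#' `min_length`.
#'
#' @param min_length minimum kept read length in nt (default 50).
#' @param mask_n treat `N`/`n` as masked (default `TRUE`).
#' @return list of class `trim_config`.
#' @export
trim_config <- function(min_length = 50, mask_n = TRUE) {
  stopifnot(min_length >= 1)
  structure(list(min_length = as.integer(min_length), mask_n = mask_n),
            class = "trim_config")
}

#' Clip masked contamination from one read
#'
#' Keeps the longest contiguous run of unmasked bases (uppercase `ACGT`,
#' plus `N` when `mask_n = FALSE`); everything lowercase or `X` counts as
#' masked. The quality vector, when present, is sliced to the same window.
#' Reads whose longest clear segment is shorter than `cfg$min_length` are
#' discarded.
#'
#' @param sequence read sequence (character scalar).
#' @param quality optional numeric per-base quality vector of the same
#'   length.
#' @param cfg a [trim_config()].
#' @return list with `kept` (logical), `sequence`, `quality`, and `range`
#'   (1-based start/end of the retained window in the input); when
#'   `kept = FALSE` the sequence is `NA`.
#' @export
clip_masked <- function(sequence, quality = NULL, cfg = trim_config()) {
  stopifnot(is.character(sequence), length(sequence) == 1, nzchar(sequence))
  if (!is.null(quality) && length(quality) != nchar(sequence))
    stop("quality length does not match sequence length", call. = FALSE)
  pat <- if (cfg$mask_n) "[ACGT]+" else "[ACGTN]+"
  m <- gregexpr(pat, sequence)[[1]]
  discard <- list(kept = FALSE, sequence = NA_character_, quality = NULL,
                  range = c(NA_integer_, NA_integer_))
  if (m[1] == -1) return(discard)
  lens <- attr(m, "match.length")
  best <- which.max(lens)  # ties: first (5'-most) segment
  if (lens[best] < cfg$min_length) return(discard)
  s <- m[best]; e <- m[best] + lens[best] - 1L
  list(kept = TRUE, sequence = substr(sequence, s, e),
       quality = if (!is.null(quality)) quality[s:e],
       range = c(s, e))
}

#' Clean a whole read library and summarize the clean-up
#'
#' Applies [clip_masked()] to every read and reports counts and mean read
#' lengths before and after, mirroring the per-library bookkeeping of a
#' survey's pre-processing table.
#'
#' @param reads data frame with columns `id` and `sequence` (and optionally
#'   `library`); or a named character vector of sequences.
#' @param cfg a [trim_config()].
#' @param quality optional named list of per-read quality vectors.
#' @return list with `kept` (data frame of surviving reads, clipped) and
#'   `summary` (one-row data frame: `n_in`, `n_kept`, `mean_len_in`,
#'   `mean_len_kept`; means are `NA` over empty sets).
#' @export
filter_library <- function(reads, cfg = trim_config(), quality = NULL) {
  if (is.character(reads)) {
    reads <- data.frame(id = names(reads), sequence = unname(reads),
                        stringsAsFactors = FALSE)
  }
  n_in <- nrow(reads)
  mean_in <- if (n_in) mean(nchar(reads$sequence)) else NA_real_
  kept <- logical(n_in)
  clipped <- character(n_in)
  qual_out <- if (!is.null(quality)) vector("list", n_in)
  for (i in seq_len(n_in)) {
    q <- if (!is.null(quality)) quality[[reads$id[i]]]
    r <- clip_masked(reads$sequence[i], q, cfg)
    kept[i] <- r$kept
    if (r$kept) {
      clipped[i] <- r$sequence
      if (!is.null(quality)) qual_out[[i]] <- r$quality
    }
  }
  out <- reads[kept, , drop = FALSE]
  out$sequence <- clipped[kept]
  rownames(out) <- NULL
  list(
    kept = out,
    quality = if (!is.null(quality))
      stats::setNames(qual_out[kept], out$id),
    summary = data.frame(
      n_in = n_in, n_kept = nrow(out),
      mean_len_in = mean_in,
      mean_len_kept = if (nrow(out)) mean(nchar(out$sequence)) else NA_real_)
  )
}
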
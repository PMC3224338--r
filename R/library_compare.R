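profile_vector <- function(p) {
  if (is.data.frame(p)) stats::setNames(as.numeric(p$count), p$gene_id)
  else p
}

#' Spearman rank correlation between two expression profiles
#'
#' Used to ask how much quantitative information a normalized cDNA library
#' retains relative to a non-normalized one: partial normalization flattens
#' counts but preserves much of their ranking. Under the default `union`
#' universe a gene detected in only one library enters with count 0 in the
#' other, so detection dropout is penalized; `intersection` restricts to
#' genes detected in both.
#'
#' @param p1,p2 profiles: data frames with `gene_id` and `count`, or named
#'   numeric vectors.
#' @param universe `"union"` (default) or `"intersection"`.
#' @return list of class `profile_comparison`: `rho`, `n_genes`,
#'   `universe`. `rho` is `NA` with a warning when either vector is
#'   constant over the universe.
#' @export
spearman_profiles <- function(p1, p2,
                              universe = c("union", "intersection")) {
  universe <- match.arg(universe)
  v1 <- profile_vector(p1); v2 <- profile_vector(p2)
  genes <- switch(universe,
                  union = union(names(v1), names(v2)),
                  intersection = intersect(names(v1), names(v2)))
  if (length(genes) < 3)
    stop("need at least 3 genes in the chosen universe", call. = FALSE)
  x <- ifelse(is.na(v1[genes]), 0, v1[genes])
  y <- ifelse(is.na(v2[genes]), 0, v2[genes])
  names(x) <- names(y) <- genes
  rho <- if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant profile over the chosen universe; rho undefined")
    NA_real_
  } else {
    stats::cor(x, y, method = "spearman")
  }
  structure(list(rho = rho, n_genes = length(genes), universe = universe),
            class = "profile_comparison")
}

#' Pairwise Spearman matrix over a set of profiles
#'
#' @param profiles named list of profiles (see [spearman_profiles()]).
#' @param universe gene-universe policy, per pair.
#' @return symmetric matrix of rank correlations with unit diagonal.
#' @export
compare_matrix <- function(profiles, universe = c("union", "intersection")) {
  universe <- match.arg(universe)
  labs <- names(profiles)
  m <- diag(1, length(labs))
  dimnames(m) <- list(labs, labs)
  if (length(labs) < 2) return(m)
  for (i in seq_len(length(labs) - 1)) {
    for (j in (i + 1):length(labs)) {
      r <- spearman_profiles(profiles[[i]], profiles[[j]], universe)$rho
      m[i, j] <- m[j, i] <- r
    }
  }
  m
}

#' Annotation retention between assembly passes (chimera proxy)
#'
#' An assembly pass that joins fragments of different transcripts into
#' chimeric contigs loses distinct reference-gene annotations. Retention is
#' the fraction of the genes tagged by the raw reads that each pass's
#' unigenes still tag; genes a pass gains that the reads never tagged do
#' not count.
#'
#' @param genes_reads character vector: genes tagged at the read level
#'   (must be non-empty).
#' @param ... one or more character vectors of genes tagged by successive
#'   assembly passes, in order.
#' @return data frame: `pass`, `n_genes`, `n_retained`, `fraction`.
#' @export
annotation_retention <- function(genes_reads, ...) {
  genes_reads <- unique(genes_reads)
  if (!length(genes_reads))
    stop("read-level gene set is empty", call. = FALSE)
  passes <- list(...)
  if (!length(passes)) stop("no assembly-pass gene sets given", call. = FALSE)
  if (is.null(names(passes)) || any(!nzchar(names(passes))))
    names(passes) <- paste0("pass", seq_along(passes))
  rows <- lapply(names(passes), function(nm) {
    g <- unique(passes[[nm]])
    ret <- length(intersect(g, genes_reads))
    data.frame(pass = nm, n_genes = length(g), n_retained = ret,
               fraction = ret / length(genes_reads),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
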
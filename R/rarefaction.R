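#' Define a read pool for rarefaction
#'
#' A pool is the multiset of reference-gene labels of all assigned reads
#' from one library (or from several libraries combined); unassigned reads
#' are excluded before pooling.
#'
#' @param x either a character vector of gene labels (one per read), a
#'   profile data frame with `gene_id` and `count` columns, or a named
#'   integer vector of per-gene counts.
#' @return list of class `read_pool`: `genes`, `counts` (per-gene read
#'   counts), `N` (total reads), `G` (distinct genes).
#' @export
read_pool <- function(x) {
  if (is.data.frame(x)) {
    counts <- stats::setNames(as.integer(x$count), x$gene_id)
  } else if (is.character(x)) {
    tab <- table(x)
    counts <- stats::setNames(as.integer(tab), names(tab))
  } else if (is.numeric(x) && !is.null(names(x))) {
    counts <- stats::setNames(as.integer(x), names(x))
  } else {
    stop("cannot interpret input as a read pool", call. = FALSE)
  }
  counts <- counts[counts > 0]
  structure(list(genes = names(counts), counts = unname(counts),
                 N = sum(counts), G = length(counts)),
            class = "read_pool")
}

#' Exact expected number of genes detected at threshold k
#'
#' When `n` reads are drawn without replacement from a pool of `N`, the
#' number of reads from a gene with `c` copies is hypergeometric, so the
#' expected count of genes seen at least `k` times is
#' `sum_g P(X_g >= k)` with `X_g ~ Hypergeometric(N, c_g, n)`. This is the
#' closed-form oracle for the Monte-Carlo rarefaction.
#'
#' @param pool a [read_pool()].
#' @param n sample size (0 <= n <= N); vectorized.
#' @param k detection threshold (>= 1).
#' @return expected detections, one value per element of `n`.
#' @export
expected_detections <- function(pool, n, k = 1) {
  stopifnot(inherits(pool, "read_pool"), k >= 1, all(n >= 0),
            all(n <= pool$N))
  vapply(n, function(ni) {
    sum(1 - stats::phyper(k - 1, pool$counts, pool$N - pool$counts, ni))
  }, numeric(1))
}

#' Monte-Carlo rarefaction at one sample size
#'
#' Each replicate draws `n` reads without replacement from the pool and
#' counts the genes drawn at least `k` times.
#'
#' @param pool a [read_pool()].
#' @param n sample size.
#' @param k detection threshold.
#' @param reps number of replicates.
#' @param seed RNG seed.
#' @return list with `mean` and `detections` (per-replicate values).
#' @export
subsample_detections <- function(pool, n, k = 1, reps = 10, seed = 1L) {
  stopifnot(inherits(pool, "read_pool"), k >= 1, reps >= 1)
  if (n > pool$N) stop("sample size exceeds pool size", call. = FALSE)
  set.seed(seed)
  gene_of_read <- rep.int(seq_len(pool$G), pool$counts)
  det <- vapply(seq_len(reps), function(r) {
    drawn <- gene_of_read[sample.int(pool$N, n)]
    sum(tabulate(drawn, nbins = pool$G) >= k)
  }, numeric(1))
  list(mean = mean(det), detections = det)
}

#' Rarefaction curves over a grid of sample sizes
#'
#' Draws replicated subsamples at each grid point for each detection
#' threshold; the default grid is 20 geometrically spaced sizes ending at
#' the full pool, so the full-pool point (where detections at k = 1 equal
#' the number of distinct genes) is always included.
#'
#' @param pool a [read_pool()].
#' @param grid sorted vector of sample sizes, max equal to `pool$N`;
#'   `NULL` for the default geometric grid.
#' @param thresholds detection thresholds (default `c(1, 5, 10, 100)`).
#' @param reps replicates per grid point.
#' @param seed RNG seed; each (threshold, grid point) uses a derived
#'   substream so curves are individually reproducible.
#' @return long-format data frame: `k`, `n`, `rep`, `detections`.
#' @export
build_curves <- function(pool, grid = NULL, thresholds = c(1, 5, 10, 100),
                         reps = 10, seed = 1L) {
  stopifnot(inherits(pool, "read_pool"))
  if (is.null(grid)) {
    grid <- unique(round(exp(seq(log(min(100, pool$N)), log(pool$N),
                                 length.out = 20))))
  }
  stopifnot(!is.unsorted(grid), max(grid) == pool$N)
  out <- vector("list", length(thresholds) * length(grid))
  idx <- 0L
  for (k in thresholds) {
    for (j in seq_along(grid)) {
      idx <- idx + 1L
      s <- subsample_detections(pool, grid[j], k, reps,
                                seed = seed + 1000L * match(k, thresholds) + j)
      out[[idx]] <- data.frame(k = k, n = grid[j],
                               rep = seq_len(reps),
                               detections = s$detections)
    }
  }
  do.call(rbind, out)
}

#' Average a rarefaction curve over replicates
#'
#' @param curves long-format data frame from [build_curves()].
#' @return data frame `k`, `n`, `detections` (replicate mean), `sd`.
#' @export
curve_means <- function(curves) {
  agg <- stats::aggregate(detections ~ k + n, data = curves,
                          FUN = function(v) c(mean(v), stats::sd(v)))
  data.frame(k = agg$k, n = agg$n,
             detections = agg$detections[, 1], sd = agg$detections[, 2])
}
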
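#' Propagate gene-category membership up a dotted hierarchy
#'
#' Category codes are hierarchical by dotted prefix (`"29.5.3"` is a child
#' of `"29.5"`, which is a child of `"29"`), as in MapMan bincodes. After
#' propagation every gene annotated to a code is also annotated to all its
#' ancestors, so enrichment can be tested at every level.
#'
#' @param map data frame with columns `gene_id` and `code`.
#' @return data frame of the same shape with ancestor rows added
#'   (deduplicated).
#' @export
propagate_hierarchy <- function(map) {
  stopifnot(all(c("gene_id", "code") %in% names(map)))
  map$code <- as.character(map$code)
  bad <- grepl("^\\.|\\.$|\\.\\.", map$code) | !nzchar(map$code)
  if (any(bad))
    stop("invalid category code: ", map$code[which(bad)[1]], call. = FALSE)
  expand <- function(code) {
    parts <- strsplit(code, ".", fixed = TRUE)[[1]]
    vapply(seq_along(parts), function(i)
      paste(parts[1:i], collapse = "."), character(1))
  }
  codes <- lapply(map$code, expand)
  out <- data.frame(gene_id = rep(map$gene_id, lengths(codes)),
                    code = unlist(codes), stringsAsFactors = FALSE)
  unique(out)
}

#' Fisher's exact enrichment test for one category
#'
#' Tests whether genes of a category are over- or under-represented in a
#' test gene set relative to a background (reference) set, on the 2x2
#' table `[[k, n-k], [K-k, (N-n)-(K-k)]]` where `k` of the `n` test genes
#' and `K` of the `N` background genes belong to the category. Two-sided
#' p-value by the point-probability rule (sum of all tables no more
#' probable than the observed one).
#'
#' @param test character vector of test-set gene ids (must be a subset of
#'   `background`).
#' @param background character vector of background gene ids.
#' @param category category code to test.
#' @param map propagated category map ([propagate_hierarchy()]).
#' @return one-row data frame: `category`, `k`, `n`, `K`, `N`, `p`,
#'   `direction` (`"over"`, `"under"` or `"neutral"`); `NULL` with a
#'   message when the category is absent from the background.
#' @export
fisher_category <- function(test, background, category, map) {
  test <- unique(test); background <- unique(background)
  if (!length(background)) stop("empty background", call. = FALSE)
  if (length(setdiff(test, background)))
    stop("test set is not a subset of the background", call. = FALSE)
  cat_genes <- unique(map$gene_id[map$code == category])
  K <- length(intersect(cat_genes, background))
  if (K == 0) {
    message("category ", category, " absent from background; skipped")
    return(NULL)
  }
  n <- length(test); N <- length(background)
  k <- length(intersect(cat_genes, test))
  tab <- matrix(c(k, n - k, K - k, (N - n) - (K - k)), nrow = 2)
  p <- stats::fisher.test(tab)$p.value
  direction <- if (k / n > K / N) "over"
  else if (k / n < K / N) "under"
  else "neutral"
  data.frame(category = category, k = k, n = n, K = K, N = N,
             p = min(p, 1), direction = direction,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return adjusted p-values (monotone, capped at 1).
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Transform a two-sided p-value into a signed z-score
#'
#' `z = sign * qnorm(1 - p/2)`, positive for over-representation, so a
#' p-value of 0.05 maps to 1.96. Used for heatmap rendering of enrichment
#' matrices, where colour encodes direction and intensity significance.
#'
#' @param p p-value(s) in `(0, 1]`; `p = 0` is capped at `z_max`.
#' @param direction `"over"`, `"under"` or `"neutral"` (recycled).
#' @param z_max cap on `|z|` (default 10).
#' @return signed z-score(s).
#' @export
signed_z <- function(p, direction = "over", z_max = 10) {
  stopifnot(all(p >= 0 & p <= 1))
  z <- ifelse(p == 0, z_max, pmin(stats::qnorm(1 - p / 2), z_max))
  sgn <- ifelse(direction == "under", -1, ifelse(direction == "over", 1, 0))
  sgn * z
}

#' Test every category of a map for enrichment in one gene set
#'
#' Runs [fisher_category()] for each category present in the background,
#' adjusts the family of p-values by Benjamini-Hochberg (unless
#' `fdr = FALSE`, the uncorrected variant used for exploratory figures),
#' and attaches signed z-scores computed from the p-value that defines
#' significance (adjusted when `fdr = TRUE`).
#'
#' @param test,background gene-id vectors, test a subset of background.
#' @param map category map; propagated with [propagate_hierarchy()] unless
#'   `propagate = FALSE`.
#' @param categories categories to test; default all codes of the
#'   propagated map.
#' @param fdr apply BH correction (default `TRUE`).
#' @param propagate propagate the hierarchy first (default `TRUE`).
#' @param z_max cap for [signed_z()].
#' @return data frame of per-category results: counts, `p`, `p_adj`
#'   (equal to `p` when `fdr = FALSE`), `direction`, `z`.
#' @export
enrich_categories <- function(test, background, map, categories = NULL,
                              fdr = TRUE, propagate = TRUE, z_max = 10) {
  if (propagate) map <- propagate_hierarchy(map)
  if (is.null(categories)) categories <- sort(unique(map$code))
  rows <- lapply(categories, function(cc)
    suppressMessages(fisher_category(test, background, cc, map)))
  res <- do.call(rbind, rows)
  if (is.null(res)) return(NULL)
  res$p_adj <- if (fdr) bh_adjust(res$p) else res$p
  res$z <- signed_z(res$p_adj, res$direction, z_max)
  res
}

#' Signed z-score matrix of category enrichment across libraries
#'
#' One column per library gene set, one row per category: the layout used
#' for enrichment heatmaps (red over-represented, blue under-represented).
#'
#' @param test_sets named list of gene-id vectors.
#' @param background background gene-id vector (typically the union of the
#'   sets relevant to the question).
#' @param map category map (unpropagated).
#' @param fdr apply BH per library column (default `TRUE`).
#' @param z_max cap for [signed_z()].
#' @return numeric matrix, categories x libraries.
#' @export
enrichment_matrix <- function(test_sets, background, map, fdr = TRUE,
                              z_max = 10) {
  pmap <- propagate_hierarchy(map)
  cats <- sort(unique(pmap$code))
  m <- matrix(NA_real_, length(cats), length(test_sets),
              dimnames = list(cats, names(test_sets)))
  for (lib in names(test_sets)) {
    res <- enrich_categories(test_sets[[lib]], background, pmap,
                             categories = cats, fdr = fdr,
                             propagate = FALSE, z_max = z_max)
    if (!is.null(res)) m[res$category, lib] <- res$z
  }
  m
}
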
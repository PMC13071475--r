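# Category enrichment for gene sets by per-category 2x2 Pearson chi-square.

#' Chi-square category enrichment test
#'
#' For every category in the annotation map, forms the 2x2 contingency table
#' (in gene set / not) x (in category / not) over the universe and applies
#' the Pearson chi-square test with df = 1. No continuity correction and no
#' multiple-testing adjustment by default, both available behind flags.
#' Categories with any expected cell below 5 are flagged
#' (\code{low_expected}); a degenerate table (no contrast, e.g. the gene set
#' equals the universe) yields chi2 = 0, p = 1.
#'
#' @param gene_set Character vector of genes of interest (subset of the
#'   universe).
#' @param annotation_map Data frame with columns \code{gene_id},
#'   \code{category_id}.
#' @param universe Character vector of background genes; default all
#'   annotated genes.
#' @param correct Apply Yates continuity correction (default FALSE).
#' @param adjust Multiple-testing adjustment method for an extra
#'   \code{p_adj} column (\code{"none"} default; any
#'   \code{\link[stats]{p.adjust}} method).
#' @return Data frame sorted by p: \code{category_id}, \code{k} (set genes in
#'   category), \code{n} (set size), \code{K} (universe genes in category),
#'   \code{N} (universe size), \code{chi2}, \code{p}, \code{direction}
#'   (\code{"over"}/\code{"under"}), \code{low_expected}, and \code{p_adj}
#'   when \code{adjust != "none"}.
#' @export
enrichment_test <- function(gene_set, annotation_map, universe = NULL,
                            correct = FALSE, adjust = "none") {
  stopifnot(all(c("gene_id", "category_id") %in% names(annotation_map)))
  if (is.null(universe)) universe <- unique(annotation_map$gene_id)
  if (length(universe) == 0L) stop("empty universe")
  gene_set <- unique(gene_set)
  out_set <- setdiff(gene_set, universe)
  if (length(out_set)) {
    stop("gene set not contained in universe: ",
         paste(out_set, collapse = ", "))
  }
  ann <- annotation_map[annotation_map$gene_id %in% universe, , drop = FALSE]
  n <- length(gene_set)
  N <- length(universe)
  rows <- lapply(unique(ann$category_id), function(cat) {
    in_cat <- unique(ann$gene_id[ann$category_id == cat])
    k <- length(intersect(gene_set, in_cat))
    K <- length(in_cat)
    tab <- matrix(c(k, n - k, K - k, N - n - (K - k)), 2L, 2L)
    exp_min <- min(outer(rowSums(tab), colSums(tab)) / sum(tab))
    degenerate <- any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)
    if (degenerate) {
      chi2 <- 0; p <- 1
    } else {
      ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
      chi2 <- unname(ht$statistic); p <- unname(ht$p.value)
    }
    data.frame(category_id = cat, k = k, n = n, K = K, N = N,
               chi2 = chi2, p = p,
               direction = if (k / max(n, 1L) >= K / N) "over" else "under",
               low_expected = exp_min < 5,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (!identical(adjust, "none")) {
    res$p_adj <- stats::p.adjust(res$p, method = adjust)
  }
  res <- res[order(res$p, res$category_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
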
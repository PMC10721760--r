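#' Profile correlation against an anchor gene
#'
#' Pearson correlation between the anchor gene's NPP row and every other
#' gene's row, ranking genes by r and returning the top fraction as the
#' anchor's co-evolved set. Pearson is appropriate here: profiles are
#' column-standardized and their correlation coefficients are approximately
#' normally distributed.
#'
#' @param npp An [npp_matrix()] with at least 3 species columns.
#' @param anchor Gene id present in the matrix.
#' @param fraction Fraction of non-anchor genes to flag as the top set
#'   (default 0.01); the set size is `floor(fraction * (n_genes - 1))`, at
#'   least 1, ties broken by gene id.
#' @return `pp_correlation` object: data.frame `table` with `gene`, `r`,
#'   `rank`, `in_top_set` (anchor excluded), plus `anchor`.
#' @export
profile_correlation <- function(npp, anchor, fraction = 0.01) {
  stopifnot(inherits(npp, "pp_npp"))
  vals <- npp$values
  if (ncol(vals) < 3) stop("need at least 3 species columns", call. = FALSE)
  if (!anchor %in% rownames(vals))
    stop(sprintf("anchor gene '%s' not in the matrix", anchor), call. = FALSE)
  av <- vals[anchor, ]
  if (stats::sd(av) == 0)
    stop(sprintf("anchor '%s' has a constant profile; correlation undefined",
                 anchor), call. = FALSE)
  others <- setdiff(rownames(vals), anchor)
  r <- as.vector(stats::cor(av, t(vals[others, , drop = FALSE])))
  ok <- !is.na(r)   # constant non-anchor rows get NA; rank them last
  r[!ok] <- -Inf
  ord <- lex_order(-r, others)
  tab <- data.frame(gene = others[ord],
                    r = ifelse(is.finite(r[ord]), r[ord], NA_real_),
                    rank = seq_along(others),
                    row.names = NULL, stringsAsFactors = FALSE)
  n_top <- max(1L, floor(fraction * length(others)))
  tab$in_top_set <- tab$rank <= n_top
  structure(list(table = tab, anchor = anchor), class = "pp_correlation")
}

#' @export
print.pp_correlation <- function(x, ...) {
  cat(sprintf("<pp_correlation> anchor %s, %d genes, top set of %d\n",
              x$anchor, nrow(x$table), sum(x$table$in_top_set)))
  invisible(x)
}

#' Hypergeometric term enrichment with BH correction
#'
#' For every annotation term, tests over-representation in the query set by
#' the hypergeometric upper tail: with universe size N, term size K, query
#' size n and overlap k, `p = P(X >= k)` for `X ~ Hypergeom(N, K, n)`.
#' P-values are adjusted across all tested terms by Benjamini-Hochberg
#' step-up.
#'
#' @param query Character vector of gene ids (must lie within the
#'   universe; ids outside it raise an error).
#' @param annotations data.frame with columns `gene` and `term` (flat
#'   annotations, multiple rows per gene), as from [read_annotations()].
#' @param universe Character vector of background gene ids. Defaults to all
#'   annotated genes.
#' @return data.frame sorted by p-value: `term`, `k`, `K`, `n`, `N`,
#'   `pvalue`, `p_adj`.
#' @export
hypergeom_enrich <- function(query, annotations, universe = NULL) {
  stopifnot(is.data.frame(annotations),
            all(c("gene", "term") %in% names(annotations)))
  if (is.null(universe)) universe <- unique(annotations$gene)
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  if (length(query) == 0) stop("empty query set", call. = FALSE)
  outside <- setdiff(query, universe)
  if (length(outside))
    stop(sprintf("query gene(s) outside the universe: %s",
                 paste(utils::head(outside, 5), collapse = ", ")),
         call. = FALSE)
  ann <- annotations[annotations$gene %in% universe, , drop = FALSE]
  ann <- unique(ann[, c("gene", "term")])

  N <- length(universe)
  n <- length(query)
  terms <- lex_sort(unique(ann$term))
  rows <- lapply(terms, function(tm) {
    members <- ann$gene[ann$term == tm]
    K <- length(members)
    k <- length(intersect(members, query))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, K = K, n = n, N = N, pvalue = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$pvalue, method = "BH")
  out <- out[lex_order(out$pvalue, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
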
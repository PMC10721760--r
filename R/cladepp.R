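#' Ward hierarchical clustering of profile rows within a clade
#'
#' Clusters gene rows of an NPP matrix restricted to a subset of species
#' columns, using Euclidean distance and Ward's minimum-variance linkage
#' (`hclust` method `"ward.D2"`). Clade-wise clustering exposes local
#' co-evolution signal that is washed out at the global level.
#'
#' @param npp An [npp_matrix()].
#' @param species_subset Character vector of species ids (columns) to use,
#'   or `"ALL"` for every species.
#' @return An [stats::hclust] dendrogram over genes.
#' @export
cluster_clade <- function(npp, species_subset = "ALL") {
  stopifnot(inherits(npp, "pp_npp"))
  if (nrow(npp$values) < 2) stop("need at least 2 genes to cluster")
  if (identical(species_subset, "ALL"))
    species_subset <- colnames(npp$values)
  if (length(species_subset) < 1) stop("species subset is empty")
  missing <- setdiff(species_subset, colnames(npp$values))
  if (length(missing))
    stop(sprintf("species not in matrix: %s",
                 paste(utils::head(missing, 5), collapse = ", ")))
  sub <- npp$values[, species_subset, drop = FALSE]
  stats::hclust(stats::dist(sub), method = "ward.D2")
}

#' Cut a dendrogram at a grid of resolutions
#'
#' Produces flat partitions at every cluster count in the grid that is
#' feasible for the gene count (k restricted to `[2, n_genes - 1]`). A
#' multi-resolution grid lets the ratio score pick up query enrichment in
#' both small tight clusters and larger loose ones.
#'
#' @param dendrogram An [stats::hclust] object over genes.
#' @param grid Integer vector of cluster counts (default
#'   `c(10, 20, 50, 100, 200, 500)`).
#' @return Named list (names = k) of integer cluster assignments, each a
#'   partition of the genes into exactly k clusters.
#' @export
cut_grid <- function(dendrogram, grid = c(10, 20, 50, 100, 200, 500)) {
  stopifnot(inherits(dendrogram, "hclust"))
  n <- length(dendrogram$order)
  ks <- sort(unique(as.integer(grid)))
  ks <- ks[ks >= 2 & ks <= n - 1]
  if (length(ks) == 0)
    stop(sprintf("no feasible cut level in the grid for %d genes", n))
  stats::setNames(lapply(ks, function(k) stats::cutree(dendrogram, k = k)),
                  as.character(ks))
}

#' Maximal ratio score (MRS) across clades and cut levels
#'
#' For gene g in cluster C at clade c and cut level k the ratio score is the
#' query purity of its cluster, excluding the gene itself:
#' `ratio(g, c, k) = |C inter Q \ {g}| / |C \ {g}|` when `|C| >=
#' min_cluster_size`, else 0. The MRS is the maximum ratio over every clade
#' and cut level; values near 1 mean the gene consistently co-clusters with
#' the query set. Note the paper-level definition fixes only the `[0, 1]`
#' range and the similarity semantics; this purity formula is this package's
#' reconstruction of the score.
#'
#' @param assignments Nested list: `assignments[[clade]][[k]]` is an integer
#'   cluster-assignment vector named by gene (as from [cut_grid()]).
#' @param query Character vector of query (gold standard) gene ids.
#' @param min_cluster_size Clusters smaller than this score 0 (default 3;
#'   prevents trivial purity-1 pairs).
#' @return `pp_mrs` object: a data.frame `table` with columns `gene`, `mrs`,
#'   `best_clade`, `best_cut`, plus a genes x clades matrix `per_clade` of
#'   per-clade best ratios.
#' @export
mrs_scores <- function(assignments, query, min_cluster_size = 3) {
  stopifnot(is.list(assignments), length(assignments) >= 1)
  genes <- names(assignments[[1]][[1]])
  if (is.null(genes)) stop("cluster assignments must be named by gene")
  query <- intersect(query, genes)
  if (length(query) == 0)
    stop("query set does not intersect the gene set", call. = FALSE)
  is_q <- genes %in% query

  per_clade <- matrix(0, length(genes), length(assignments),
                      dimnames = list(genes, names(assignments)))
  best_cut <- matrix(NA_integer_, length(genes), length(assignments),
                     dimnames = list(genes, names(assignments)))
  for (cl in names(assignments)) {
    for (k in names(assignments[[cl]])) {
      asg <- assignments[[cl]][[k]]
      stopifnot(identical(names(asg), genes))
      size <- tabulate(asg)
      qcnt <- tabulate(asg[is_q], nbins = length(size))
      num <- qcnt[asg] - as.integer(is_q)
      den <- size[asg] - 1L
      ratio <- ifelse(size[asg] >= min_cluster_size & den > 0L, num / den, 0)
      upd <- ratio > per_clade[, cl]
      per_clade[upd, cl] <- ratio[upd]
      best_cut[upd, cl] <- as.integer(k)
    }
  }
  mrs <- apply(per_clade, 1, max)
  arg <- apply(per_clade, 1, which.max)
  tab <- data.frame(gene = genes, mrs = mrs,
                    best_clade = colnames(per_clade)[arg],
                    best_cut = best_cut[cbind(seq_along(genes), arg)],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, per_clade = per_clade), class = "pp_mrs")
}

#' @export
print.pp_mrs <- function(x, ...) {
  cat(sprintf("<pp_mrs> %d genes, %d clade(s); MRS range [%.3f, %.3f]\n",
              nrow(x$table), ncol(x$per_clade),
              min(x$table$mrs), max(x$table$mrs)))
  invisible(x)
}

#' Select top-fraction candidate genes by MRS
#'
#' Genes are ranked by MRS (descending, ties broken by gene id). Query genes
#' keep their rank but are excluded from the returned candidate list, so the
#' list contains the top `floor(fraction * n_genes)` (at least 1) non-query
#' genes.
#'
#' @param mrs A `pp_mrs` from [mrs_scores()] (or its `$table` data.frame).
#' @param fraction Fraction of genes to call as candidates (default 0.01,
#'   i.e. the top 1 percent).
#' @param query Character vector of query gene ids to exclude from the list.
#' @return data.frame `gene`, `mrs`, `best_clade`, `best_cut`, `rank`
#'   (overall rank including query genes), ordered by rank.
#' @export
select_candidates <- function(mrs, fraction = 0.01, query = character(0)) {
  check_scalar_num(fraction, "fraction", lower = 0, upper = 1,
                   strict_lower = TRUE)
  tab <- if (inherits(mrs, "pp_mrs")) mrs$table else mrs
  stopifnot(is.data.frame(tab), all(c("gene", "mrs") %in% names(tab)))
  ord <- lex_order(-tab$mrs, tab$gene)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  n_cand <- max(1L, floor(fraction * nrow(tab)))
  cand <- tab[!(tab$gene %in% query), , drop = FALSE]
  cand <- utils::head(cand, n_cand)
  rownames(cand) <- NULL
  cand
}

#' Run the clade-wise co-evolution scan end-to-end
#'
#' Clusters the NPP rows on the full species set (pseudo-clade `"ALL"`) and
#' on every clade with at least `clade_min_species` species, cuts each
#' dendrogram at the resolution grid, scores every gene with the maximal
#' ratio score against the query set, and calls the top-fraction candidates.
#'
#' @param npp An [npp_matrix()].
#' @param clades A [clade_map()] covering the matrix's species.
#' @param query Character vector of query gene ids; ids absent from the
#'   matrix are dropped with a warning.
#' @param clade_min_species Minimum species count for a clade to be scored
#'   on its own (default 10).
#' @param grid Cut-level grid, see [cut_grid()].
#' @param min_cluster_size See [mrs_scores()].
#' @param fraction See [select_candidates()].
#' @return List with `mrs` (a `pp_mrs`), `candidates` (data.frame), `clades`
#'   (clade labels scored, including `"ALL"`), and `query` (ids actually
#'   used).
#' @export
cladepp_scan <- function(npp, clades, query, clade_min_species = 10,
                         grid = c(10, 20, 50, 100, 200, 500),
                         min_cluster_size = 3, fraction = 0.01) {
  stopifnot(inherits(npp, "pp_npp"), inherits(clades, "pp_clade_map"))
  genes <- rownames(npp$values)
  dropped <- setdiff(query, genes)
  if (length(dropped))
    warning(sprintf("%d query gene(s) not in the matrix were dropped: %s",
                    length(dropped),
                    paste(utils::head(dropped, 5), collapse = ", ")),
            call. = FALSE)
  query <- intersect(query, genes)
  if (length(query) == 0) stop("no query gene is present in the matrix")

  elig <- eligible_clades(clades, clade_min_species)
  subsets <- c(list(ALL = colnames(npp$values)),
               stats::setNames(lapply(elig, function(cl)
                 intersect(clades$species[clades$clade == cl],
                           colnames(npp$values))), elig))
  subsets <- subsets[vapply(subsets, length, 0L) >= 1]
  assignments <- lapply(subsets, function(sp)
    cut_grid(cluster_clade(npp, sp), grid = grid))
  mrs <- mrs_scores(assignments, query, min_cluster_size = min_cluster_size)
  list(mrs = mrs,
       candidates = select_candidates(mrs, fraction = fraction, query = query),
       clades = names(subsets), query = query)
}
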
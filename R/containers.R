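#' Best-hit bit-score matrix
#'
#' Container for a genes x species matrix of best-hit bit-scores together with
#' each gene's self-alignment score and protein length. Absent hits (no match
#' in a proteome) are stored as `NA` until [filter_and_floor()] replaces them
#' with the noise floor.
#'
#' @param scores Numeric matrix, genes in rows (rownames = gene ids), species
#'   in columns (colnames = species ids). `NA` marks an absent hit.
#' @param self_scores Named numeric vector of self-alignment bit-scores, one
#'   per gene.
#' @param lengths Named integer vector of protein lengths (residues), one per
#'   gene.
#' @param reference Optional species id naming the reference proteome among
#'   the columns; excluded when counting "other proteome" support in
#'   [filter_and_floor()].
#' @return An object of class `pp_bitscore`.
#' @export
bitscore_matrix <- function(scores, self_scores, lengths, reference = NULL) {
  if (!is.matrix(scores) || !is.numeric(scores))
    stop_field("scores", "must be a numeric matrix")
  if (is.null(rownames(scores)) || is.null(colnames(scores)))
    stop_field("scores", "must have gene rownames and species colnames")
  genes <- rownames(scores)
  if (anyDuplicated(genes)) stop_field("scores", "duplicated gene ids")
  miss <- setdiff(genes, names(self_scores))
  if (length(miss))
    stop_field("self_scores", paste("missing for gene(s):",
                                    paste(utils::head(miss, 5), collapse = ", ")))
  miss <- setdiff(genes, names(lengths))
  if (length(miss))
    stop_field("lengths", paste("missing for gene(s):",
                                paste(utils::head(miss, 5), collapse = ", ")))
  structure(
    list(scores = scores,
         self_scores = self_scores[genes],
         lengths = as.integer(lengths[genes]) |> stats::setNames(genes),
         reference = reference),
    class = "pp_bitscore")
}

#' @export
print.pp_bitscore <- function(x, ...) {
  cat(sprintf("<pp_bitscore> %d genes x %d species (%.1f%% absent)\n",
              nrow(x$scores), ncol(x$scores),
              100 * mean(is.na(x$scores))))
  invisible(x)
}

#' @export
dim.pp_bitscore <- function(x) dim(x$scores)

#' Normalized phylogenetic profile (NPP) matrix
#'
#' Column-standardized profile matrix: each entry is the Z-score, within a
#' species, of the length-normalized profile value LPP = BS / self-score.
#' Produced by [zscore_columns()].
#'
#' @param values Numeric matrix of Z-scores (genes x species).
#' @param column_stats Data frame with one row per species: `species`, `mu`,
#'   `sigma` (statistics used for the transform) and `degenerate` (constant
#'   column, set to zeros).
#' @return An object of class `pp_npp`.
#' @export
npp_matrix <- function(values, column_stats) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_field("values", "must have gene rownames and species colnames")
  stopifnot(identical(column_stats$species, colnames(values)))
  structure(list(values = values, column_stats = column_stats),
            class = "pp_npp")
}

#' @export
print.pp_npp <- function(x, ...) {
  cat(sprintf("<pp_npp> %d genes x %d species (%d degenerate column%s)\n",
              nrow(x$values), ncol(x$values),
              sum(x$column_stats$degenerate),
              if (sum(x$column_stats$degenerate) == 1) "" else "s"))
  invisible(x)
}

#' @export
dim.pp_npp <- function(x) dim(x$values)

#' Species-to-clade map
#'
#' @param species Character vector of species ids.
#' @param clade Character vector of clade labels, same length.
#' @return An object of class `pp_clade_map`: a data frame with columns
#'   `species` and `clade`.
#' @export
clade_map <- function(species, clade) {
  if (length(species) != length(clade))
    stop_field("clade", "must have one clade per species")
  if (anyDuplicated(species))
    stop_field("species", "duplicated species id (each species has exactly one clade)")
  structure(data.frame(species = as.character(species),
                       clade = as.character(clade),
                       stringsAsFactors = FALSE),
            class = c("pp_clade_map", "data.frame"))
}

#' Clades eligible for clade-wise clustering
#'
#' Returns the clade labels whose species count is at least `min_species`
#' (default 10, the eligibility rule used for clade-wise co-evolution
#' scoring), in lexicographic order. The pseudo-clade `"ALL"` (every species)
#' is always prepended by the clustering driver, not here.
#'
#' @param map A [clade_map()].
#' @param min_species Minimum number of species for a clade to be scored.
#' @return Character vector of clade labels.
#' @export
eligible_clades <- function(map, min_species = 10) {
  tab <- table(map$clade)
  lex_sort(names(tab)[tab >= min_species])
}
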
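#' Read protein lengths from a FASTA file
#'
#' Supports the minimum-length filter of the profile pipeline: only record
#' ids and residue counts are used, never sequence content.
#'
#' @param fasta Path to a FASTA file of protein sequences.
#' @return Named integer vector: gene id (first word of the header) to
#'   residue count. Empty file gives an empty vector.
#' @export
read_proteome_lengths <- function(fasta) {
  seqs <- Biostrings::readAAStringSet(fasta)
  if (length(seqs) == 0) return(stats::setNames(integer(0), character(0)))
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(sprintf("duplicate FASTA id(s): %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  stats::setNames(Biostrings::width(seqs), ids)
}

# Parse one BLAST/DIAMOND tabular (outfmt 6) file. The 12-column dialect has
# qseqid, sseqid, ..., bitscore; a 13-column dialect carries a leading
# species column. Returns a data.table with species (NA for 12-col), qseqid,
# sseqid, bitscore.
read_hits_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("hit file not found: %s", path))
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1:2))
  if (nrow(dt) == 0)
    return(data.table::data.table(species = character(0), qseqid = character(0),
                                  sseqid = character(0), bitscore = numeric(0)))
  nc <- ncol(dt)
  if (nc == 12) {
    out <- data.table::data.table(species = NA_character_,
                                  qseqid = as.character(dt[[1]]),
                                  sseqid = as.character(dt[[2]]),
                                  bitscore = suppressWarnings(as.numeric(dt[[12]])))
  } else if (nc == 13) {
    out <- data.table::data.table(species = as.character(dt[[1]]),
                                  qseqid = as.character(dt[[2]]),
                                  sseqid = as.character(dt[[3]]),
                                  bitscore = suppressWarnings(as.numeric(dt[[13]])))
  } else {
    stop(sprintf("%s: expected 12 or 13 tab-separated columns, found %d",
                 path, nc))
  }
  bad <- which(is.na(out$bitscore))
  if (length(bad))
    stop(sprintf("%s: non-numeric bit-score at line %d", path, bad[1]))
  out
}

#' Build the best-hit bit-score matrix from search output
#'
#' Entry (i, j) is the maximum bit-score of gene i over all its hits in
#' proteome j; genes with no hit in a proteome stay absent (`NA`).
#' Self-alignment scores are taken from the reference-vs-reference hit file,
#' using rows with `qseqid == sseqid`.
#'
#' @param hit_files Named character vector of per-species hit files (names
#'   are species ids), or a single unnamed path to a combined 13-column file
#'   whose first column is the species id.
#' @param self_hits Path to the reference-vs-reference hit file.
#' @param gene_ids Genes to keep as rows (order preserved). Defaults to the
#'   genes seen in `self_hits`.
#' @param species_ids Species to keep as columns. Defaults to the names of
#'   `hit_files` (or the species seen in a combined file), sorted.
#' @param lengths Optional named integer vector of protein lengths (from
#'   [read_proteome_lengths()]); genes without an entry get `NA` length.
#' @return A [bitscore_matrix()] (pre-filter; may contain absent entries).
#' @export
best_hit_matrix <- function(hit_files, self_hits, gene_ids = NULL,
                            species_ids = NULL, lengths = NULL) {
  selfdt <- read_hits_table(self_hits)
  selfdt <- selfdt[selfdt$qseqid == selfdt$sseqid, ]
  self_scores <- tapply(selfdt$bitscore, selfdt$qseqid, max)
  self_scores <- stats::setNames(as.numeric(self_scores), names(self_scores))

  combined <- length(hit_files) == 1L && is.null(names(hit_files))
  if (combined) {
    hits <- read_hits_table(hit_files)
    if (all(is.na(hits$species)))
      stop("combined hit file must use the 13-column dialect with a species column")
  } else {
    if (is.null(names(hit_files)) || any(!nzchar(names(hit_files))))
      stop("hit_files must be named by species id")
    hits <- data.table::rbindlist(lapply(names(hit_files), function(sp) {
      h <- read_hits_table(hit_files[[sp]])
      h$species <- sp
      h
    }))
  }

  if (is.null(gene_ids)) gene_ids <- lex_sort(names(self_scores))
  if (is.null(species_ids))
    species_ids <- lex_sort(unique(hits$species))

  hits <- hits[hits$qseqid %in% gene_ids & hits$species %in% species_ids, ]
  scores <- matrix(NA_real_, length(gene_ids), length(species_ids),
                   dimnames = list(gene_ids, species_ids))
  if (nrow(hits)) {
    best <- hits[, list(bitscore = max(bitscore)), by = c("qseqid", "species")]
    scores[cbind(match(best$qseqid, gene_ids),
                 match(best$species, species_ids))] <- best$bitscore
  }

  len <- stats::setNames(rep(NA_integer_, length(gene_ids)), gene_ids)
  if (!is.null(lengths)) {
    common <- intersect(gene_ids, names(lengths))
    len[common] <- as.integer(lengths[common])
  }
  ss <- stats::setNames(rep(NA_real_, length(gene_ids)), gene_ids)
  common <- intersect(gene_ids, names(self_scores))
  ss[common] <- self_scores[common]
  bitscore_matrix(scores, ss, len)
}

#' Filter genes and floor bit-scores
#'
#' Applies the profile-matrix cleaning rules in a fixed order:
#' 1. drop genes shorter than `min_length` residues;
#' 2. drop genes whose self-alignment score is `<= max(min_self_score)`;
#' 3. floor: every present score below `floor` and every absent entry is set
#'    to `floor` (an absent hit is below any reporting threshold);
#' 4. drop genes without a score strictly above `floor` in at least
#'    `min_other_species` non-reference proteomes.
#'
#' The operation is idempotent. A per-gene report of the first rule that
#' removed each dropped gene is attached as attribute `"filter_report"`.
#'
#' @param bm A [bitscore_matrix()].
#' @param min_length Minimum protein length in residues (default 40).
#' @param min_self_score Self-score threshold; genes with self-score at or
#'   below it are dropped (default 80).
#' @param floor Noise-floor bit-score (default 24.6, the score equivalent to
#'   an E-value of 0.05).
#' @param min_other_species Minimum number of non-reference proteomes with a
#'   score above the floor (default 5).
#' @return A filtered [bitscore_matrix()] with no absent entries and all
#'   scores `>= floor`.
#' @export
filter_and_floor <- function(bm, min_length = 40, min_self_score = 80,
                             floor = 24.6, min_other_species = 5) {
  stopifnot(inherits(bm, "pp_bitscore"))
  genes <- rownames(bm$scores)
  removed <- character(0); rule <- character(0)

  keep <- is.na(bm$lengths) | bm$lengths >= min_length
  # genes with unknown length are kept: the rule needs evidence to drop
  drop1 <- genes[!keep]
  scores <- bm$scores[keep, , drop = FALSE]
  self <- bm$self_scores[keep]; lens <- bm$lengths[keep]

  keep2 <- !is.na(self) & self > min_self_score
  drop2 <- rownames(scores)[!keep2]
  scores <- scores[keep2, , drop = FALSE]
  self <- self[keep2]; lens <- lens[keep2]

  scores[is.na(scores) | scores < floor] <- floor

  other <- colnames(scores)
  if (!is.null(bm$reference)) other <- setdiff(other, bm$reference)
  support <- rowSums(scores[, other, drop = FALSE] > floor)
  keep4 <- support >= min_other_species
  drop4 <- rownames(scores)[!keep4]
  scores <- scores[keep4, , drop = FALSE]
  self <- self[keep4]; lens <- lens[keep4]

  report <- data.frame(
    gene = c(drop1, drop2, drop4),
    rule = rep(c("min_length", "self_score", "min_other_species"),
               c(length(drop1), length(drop2), length(drop4))),
    stringsAsFactors = FALSE)
  out <- bitscore_matrix(scores, self, lens, reference = bm$reference)
  attr(out, "filter_report") <- report
  out
}

#' Length-normalize bit-scores (LPP)
#'
#' Divides every bit-score by the gene's self-alignment score, removing the
#' dependence of raw bit-scores on protein length:
#' `LPP[i, j] = BS[i, j] / BS[i, self]`.
#'
#' @param bm A filtered [bitscore_matrix()] (no absent entries, positive
#'   self-scores).
#' @return Numeric matrix of LPP values (genes x species), strictly positive.
#' @export
normalize_lpp <- function(bm) {
  stopifnot(inherits(bm, "pp_bitscore"))
  bad <- names(bm$self_scores)[is.na(bm$self_scores) | bm$self_scores <= 0]
  if (length(bad))
    stop(sprintf("non-positive or missing self-score for gene(s): %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  if (anyNA(bm$scores))
    stop("absent entries present; run filter_and_floor() first", call. = FALSE)
  bm$scores / bm$self_scores
}

#' Standardize LPP columns into Z-scores (NPP)
#'
#' Transforms each species column to zero mean and unit standard deviation
#' over the retained genes, controlling for phylogenetic distance between
#' each proteome and the reference: `NPP[i, j] = (LPP[i, j] - mu_j) / sigma_j`
#' with the sample standard deviation (n - 1 denominator). Constant columns
#' (`sigma_j == 0`) are set to zeros, flagged in `column_stats$degenerate`,
#' and reported with a warning so column indices stay aligned with the clade
#' map.
#'
#' @param lpp Numeric matrix of LPP values (genes x species), at least two
#'   rows.
#' @return An [npp_matrix()].
#' @export
zscore_columns <- function(lpp) {
  stopifnot(is.matrix(lpp), is.numeric(lpp))
  if (nrow(lpp) < 2)
    stop("at least two genes are required to standardize columns", call. = FALSE)
  mu <- colMeans(lpp)
  sigma <- apply(lpp, 2, stats::sd)
  degenerate <- sigma == 0
  vals <- sweep(lpp, 2, mu, "-")
  vals <- sweep(vals, 2, ifelse(degenerate, 1, sigma), "/")
  vals[, degenerate] <- 0
  if (any(degenerate))
    warning(sprintf("%d constant column(s) set to zeros: %s",
                    sum(degenerate),
                    paste(utils::head(colnames(lpp)[degenerate], 5),
                          collapse = ", ")), call. = FALSE)
  npp_matrix(vals, data.frame(species = colnames(lpp), mu = mu,
                              sigma = sigma, degenerate = degenerate,
                              row.names = NULL, stringsAsFactors = FALSE))
}

#' Build an NPP matrix from raw inputs in one call
#'
#' Convenience wrapper chaining [read_proteome_lengths()],
#' [best_hit_matrix()], [filter_and_floor()], [normalize_lpp()] and
#' [zscore_columns()].
#'
#' @param fasta Reference proteome FASTA (ids and lengths only).
#' @param hit_files Named per-species hit files or one combined file (see
#'   [best_hit_matrix()]).
#' @param self_hits Reference-vs-reference hit file.
#' @param ... Thresholds passed to [filter_and_floor()].
#' @return An [npp_matrix()]; the filter report is attached as attribute
#'   `"filter_report"`.
#' @export
build_npp <- function(fasta, hit_files, self_hits, ...) {
  lens <- read_proteome_lengths(fasta)
  bm <- best_hit_matrix(hit_files, self_hits, gene_ids = lex_sort(names(lens)),
                        lengths = lens)
  bm <- filter_and_floor(bm, ...)
  npp <- zscore_columns(normalize_lpp(bm))
  attr(npp, "filter_report") <- attr(bm, "filter_report")
  npp
}

#' Write / read an NPP matrix as TSV
#'
#' Genes in rows (first column `gene`), species ids in the header. A `.gz`
#' path triggers transparent compression. Values survive the round trip to
#' within 1e-12.
#'
#' @param npp An [npp_matrix()] (or a plain numeric matrix with dimnames).
#' @param path Output (input) TSV path.
#' @return `write_npp()`: the path, invisibly. `read_npp()`: an
#'   [npp_matrix()]; column statistics are recomputed flags only (mu/sigma of
#'   the stored values are not persisted, degenerate columns are detected as
#'   all-zero columns).
#' @export
write_npp <- function(npp, path) {
  vals <- if (inherits(npp, "pp_npp")) npp$values else npp
  dt <- data.table::data.table(gene = rownames(vals))
  for (j in colnames(vals)) dt[[j]] <- vals[, j]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_npp
#' @export
read_npp <- function(path) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "r")
    on.exit(close(con))
    dt <- data.table::fread(text = readLines(con), header = TRUE, sep = "\t")
  } else {
    dt <- data.table::fread(path, header = TRUE, sep = "\t")
  }
  genes <- as.character(dt[[1]])
  vals <- as.matrix(dt[, -1, with = FALSE])
  rownames(vals) <- genes
  sigma <- apply(vals, 2, stats::sd)
  npp_matrix(vals, data.frame(species = colnames(vals),
                              mu = colMeans(vals), sigma = sigma,
                              degenerate = apply(vals == 0, 2, all),
                              row.names = NULL, stringsAsFactors = FALSE))
}

#' Read a species-to-clade TSV
#'
#' Two tab-separated columns (`species`, `clade`), no header (a header line
#' `species<TAB>clade` is tolerated and skipped).
#'
#' @param path TSV path.
#' @return A [clade_map()].
#' @export
read_clade_map <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = "character")
  if (ncol(dt) < 2) stop(sprintf("%s: expected 2 columns", path))
  if (nrow(dt) && identical(unname(tolower(unlist(dt[1, 1:2]))),
                            c("species", "clade")))
    dt <- dt[-1, ]
  clade_map(dt[[1]], dt[[2]])
}

#' Read a gene list (one id per line)
#' @param path File path.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x)]
}

#' Read a flat gene-to-term annotation TSV
#'
#' Two tab-separated columns `gene_id`, `term_id`, multiple rows per gene,
#' no header.
#'
#' @param path TSV path.
#' @return data.frame with columns `gene` and `term`.
#' @export
read_annotations <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = "character")
  if (ncol(dt) < 2) stop(sprintf("%s: expected 2 columns", path))
  data.frame(gene = dt[[1]], term = dt[[2]], stringsAsFactors = FALSE)
}
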
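#' Specification for a synthetic clade-structured dataset
#'
#' Defines the generative model used by [simulate_dataset()]: a genes x
#' species bit-score matrix with clade-block structure, planted modules of
#' co-evolving genes (shared latent conservation profiles), independent
#' background genes, per-gene self-alignment scores, and injected
#' missingness. The seed fully determines the output.
#'
#' @param n_genes Total number of genes (module + background).
#' @param clade_sizes Integer vector: number of species in each clade.
#' @param modules List of planted modules; each element is a list with
#'   `size` (genes in the module) and `signal` (co-evolution signal strength
#'   in `[0, 1]`; 1 means noise-free shared profiles).
#' @param background_noise_sd Standard deviation, on the latent `[0, 1]`
#'   conservation scale, of per-species noise for background genes. Module
#'   genes receive the same noise scaled by `1 - signal`.
#' @param missing_rate Fraction of matrix entries set to absent (no hit).
#' @param self_score_range Length-2 numeric: self-alignment bit-scores are
#'   drawn uniformly from this interval; both ends must exceed 80 so the
#'   self-score filter is exercised only when configured explicitly.
#' @param length_range Length-2 integer: protein lengths are drawn uniformly
#'   from this interval (residues).
#' @param seed Integer seed; identical specs produce bit-identical datasets.
#' @return An object of class `pp_sim_spec`.
#' @export
simulation_spec <- function(n_genes = 2000,
                            clade_sizes = rep(12L, 5),
                            modules = list(list(size = 20, signal = 0.9)),
                            background_noise_sd = 0.5,
                            missing_rate = 0.1,
                            self_score_range = c(200, 1000),
                            length_range = c(100L, 800L),
                            seed = 1L) {
  check_scalar_num(n_genes, "n_genes", lower = 2)
  if (!is.numeric(clade_sizes) || length(clade_sizes) < 1 || any(clade_sizes < 1))
    stop_field("clade_sizes", "must be a vector of counts, all >= 1")
  if (!is.list(modules))
    stop_field("modules", "must be a list of list(size=, signal=)")
  for (m in modules) {
    if (is.null(m$size) || is.null(m$signal))
      stop_field("modules", "each module needs 'size' and 'signal'")
    check_scalar_num(m$size, "modules$size", lower = 2)
    check_scalar_num(m$signal, "modules$signal", lower = 0, upper = 1)
  }
  if (sum(vapply(modules, function(m) m$size, 0)) > n_genes)
    stop_field("modules", "sum of module sizes exceeds n_genes")
  check_scalar_num(background_noise_sd, "background_noise_sd",
                   lower = 0, strict_lower = TRUE)
  check_scalar_num(missing_rate, "missing_rate", lower = 0, upper = 1,
                   strict_upper = TRUE)
  if (!is.numeric(self_score_range) || length(self_score_range) != 2 ||
      any(self_score_range <= 80) || diff(self_score_range) < 0)
    stop_field("self_score_range", "must be (lo, hi) with both > 80 and lo <= hi")
  check_scalar_num(seed, "seed")
  structure(list(n_genes = as.integer(n_genes),
                 clade_sizes = as.integer(clade_sizes),
                 modules = modules,
                 background_noise_sd = background_noise_sd,
                 missing_rate = missing_rate,
                 self_score_range = as.numeric(self_score_range),
                 length_range = as.integer(length_range),
                 seed = as.integer(seed)),
            class = "pp_sim_spec")
}

# Bit-score noise floor used when mapping latent conservation onto scores;
# identical to the floor applied by filter_and_floor() so that absent /
# fully-diverged entries normalize like real floored hits.
PP_SCORE_FLOOR <- 24.6

#' Simulate a clade-structured phylogenetic-profiling dataset
#'
#' Genes in the same planted module share a latent per-species conservation
#' profile built from per-clade means (clade-block structure); each module
#' gene perturbs it with independent Gaussian noise scaled by
#' `1 - signal`. Background genes draw their own independent clade means and
#' full-strength noise. Latent profiles in `[0, 1]` are mapped affinely onto
#' `[24.6, self_score]` per gene, and a `missing_rate` fraction of entries is
#' set to absent (`NA`, i.e. omitted from hit tables).
#'
#' @param spec A [simulation_spec()].
#' @return An object of class `pp_sim_dataset` with elements
#'   `bitscore_matrix` (a [bitscore_matrix()]), `clade_map` (a
#'   [clade_map()]), `module_labels` (named character, `"background"` or the
#'   module id), `ml_labels` (named 0/1 integer, 1 for planted-module genes)
#'   and `spec`.
#' @export
simulate_dataset <- function(spec) {
  if (!inherits(spec, "pp_sim_spec"))
    stop("spec must be created with simulation_spec()")
  set.seed(spec$seed)

  n_clades <- length(spec$clade_sizes)
  clades <- sprintf("clade%02d", seq_len(n_clades))
  species <- unlist(lapply(seq_len(n_clades), function(c)
    sprintf("sp_%02d_%02d", c, seq_len(spec$clade_sizes[c]))))
  clade_of <- rep(clades, spec$clade_sizes)
  n_sp <- length(species)

  genes <- sprintf("g%05d", seq_len(spec$n_genes))
  module_labels <- stats::setNames(rep("background", spec$n_genes), genes)
  idx <- 1L
  for (m in seq_along(spec$modules)) {
    sz <- spec$modules[[m]]$size
    module_labels[idx:(idx + sz - 1L)] <- sprintf("module%02d", m)
    idx <- idx + sz
  }

  latent <- matrix(0, spec$n_genes, n_sp, dimnames = list(genes, species))
  for (m in seq_along(spec$modules)) {
    mod <- spec$modules[[m]]
    rows <- which(module_labels == sprintf("module%02d", m))
    clade_mean <- stats::runif(n_clades)           # drawn once per module
    shared <- clade_mean[match(clade_of, clades)]  # clade-block profile
    noise_sd <- (1 - mod$signal) * spec$background_noise_sd
    for (g in rows)
      latent[g, ] <- shared + stats::rnorm(n_sp, sd = noise_sd)
  }
  bg <- which(module_labels == "background")
  for (g in bg) {
    own_mean <- stats::runif(n_clades)
    latent[g, ] <- own_mean[match(clade_of, clades)] +
      stats::rnorm(n_sp, sd = spec$background_noise_sd)
  }
  latent <- pmin(pmax(latent, 0), 1)

  self_scores <- stats::setNames(
    stats::runif(spec$n_genes, spec$self_score_range[1], spec$self_score_range[2]),
    genes)
  lengths <- stats::setNames(
    as.integer(round(stats::runif(spec$n_genes,
                                  spec$length_range[1], spec$length_range[2]))),
    genes)

  scores <- PP_SCORE_FLOOR + latent * (self_scores - PP_SCORE_FLOOR)
  if (spec$missing_rate > 0) {
    absent <- which(stats::runif(length(scores)) < spec$missing_rate)
    scores[absent] <- NA_real_
  }

  structure(
    list(bitscore_matrix = bitscore_matrix(scores, self_scores, lengths),
         clade_map = clade_map(species, clade_of),
         module_labels = module_labels,
         ml_labels = stats::setNames(
           as.integer(module_labels != "background"), genes),
         spec = spec),
    class = "pp_sim_dataset")
}

#' @export
print.pp_sim_dataset <- function(x, ...) {
  cat(sprintf(
    "<pp_sim_dataset> %d genes x %d species, %d module gene(s), seed %d\n",
    length(x$module_labels), nrow(x$clade_map),
    sum(x$ml_labels), x$spec$seed))
  invisible(x)
}

#' Write file fixtures for a simulated dataset
#'
#' Serializes a [simulate_dataset()] result into the on-disk formats the
#' readers consume: a FASTA of dummy sequences with the simulated lengths,
#' one BLAST tabular (outfmt 6) hit file per species, a self-hits file
#' (reference vs reference), a species-to-clade TSV, a query gene list (the
#' first half of each planted module) and a flat gene-to-term annotation TSV
#' (each module is one term; background genes get a shared background term).
#' Bit-scores are written with 17 significant digits so the round trip
#' through [best_hit_matrix()] is lossless to floating-point precision.
#'
#' @param dataset A `pp_sim_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a manifest list of file paths: `fasta`, `hit_files`
#'   (named by species), `self_hits`, `clade_map`, `query`, `annotations`.
#' @export
write_fixtures <- function(dataset, dir) {
  if (!inherits(dataset, "pp_sim_dataset"))
    stop("dataset must come from simulate_dataset()")
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, 2) != 0)
    stop(sprintf("cannot write to directory '%s'", dir))
  hitdir <- file.path(dir, "hits")
  dir.create(hitdir, showWarnings = FALSE)

  bm <- dataset$bitscore_matrix
  genes <- rownames(bm$scores)
  species <- colnames(bm$scores)

  # FASTA: placeholder sequences, only id + length are meaningful
  fasta <- file.path(dir, "proteome.fasta")
  seqs <- Biostrings::AAStringSet(vapply(bm$lengths, function(n)
    paste0("M", strrep("A", n - 1L)), ""))
  names(seqs) <- genes
  Biostrings::writeXStringSet(seqs, fasta)

  fmt <- function(x) formatC(x, digits = 17, format = "g")
  hit_row <- function(q, s, bits) {
    data.table::data.table(
      qseqid = q, sseqid = s, pident = "50.0", length = "100",
      mismatch = "50", gapopen = "0", qstart = "1", qend = "100",
      sstart = "1", send = "100", evalue = "1e-10", bitscore = fmt(bits))
  }
  hit_files <- stats::setNames(file.path(hitdir, paste0(species, ".tsv")), species)
  for (sp in species) {
    present <- which(!is.na(bm$scores[, sp]))
    tab <- hit_row(genes[present], paste0(sp, "|", genes[present]),
                   bm$scores[present, sp])
    data.table::fwrite(tab, hit_files[[sp]], sep = "\t", col.names = FALSE)
  }
  self_hits <- file.path(hitdir, "self_hits.tsv")
  data.table::fwrite(hit_row(genes, genes, bm$self_scores),
                     self_hits, sep = "\t", col.names = FALSE)

  clade_path <- file.path(dir, "clades.tsv")
  data.table::fwrite(dataset$clade_map, clade_path, sep = "\t",
                     col.names = FALSE)

  # query = first half of each planted module (gold standard); the second
  # half is held out for recovery checks
  labs <- dataset$module_labels
  query <- as.character(unlist(
    lapply(lex_sort(setdiff(unique(labs), "background")), function(m) {
      g <- names(labs)[labs == m]
      g[seq_len(floor(length(g) / 2))]
    }), use.names = FALSE))
  query_path <- file.path(dir, "query.txt")
  writeLines(query, query_path)

  annot_path <- file.path(dir, "annotations.tsv")
  annot <- data.table::data.table(
    gene_id = names(labs),
    term_id = ifelse(labs == "background", "TERM:background",
                     paste0("TERM:", labs)))
  data.table::fwrite(annot, annot_path, sep = "\t", col.names = FALSE)

  invisible(list(fasta = fasta, hit_files = hit_files, self_hits = self_hits,
                 clade_map = clade_path, query = query_path,
                 annotations = annot_path))
}
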
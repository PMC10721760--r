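#' Pipeline configuration
#'
#' Collects every threshold and path the pipeline needs. Defaults are the
#' analysis constants of the method: 40-residue minimum protein length,
#' self-score filter at 80 bits, 24.6-bit noise floor, support in at least 5
#' other proteomes, 10-species clade eligibility, top 1 percent candidate
#' fraction, 20 percent missingness cutoff and the 3-sigma outlier rule.
#'
#' @param fasta,hit_files,self_hits,clade_file,query_file,annotation_file
#'   Input paths (see [build_npp()], [read_clade_map()]); `hit_files` is a
#'   named vector or a directory containing `<species>.tsv` files.
#' @param out_dir Output directory for stage TSVs and the run manifest.
#' @param min_length,min_self_score,score_floor,min_other_species Filter
#'   thresholds, see [filter_and_floor()].
#' @param clade_min_species Clade eligibility threshold, see
#'   [cladepp_scan()].
#' @param top_fraction Candidate fraction, see [select_candidates()].
#' @param max_missing_fraction,sigma_mult Cleaning thresholds, see
#'   [ml_clean()].
#' @param cut_grid Dendrogram cut levels, see [cut_grid()].
#' @param run_ml Fit and evaluate the classifiers (default `FALSE`).
#' @param anchors Gene ids for per-anchor profile-correlation analyses
#'   (default: none).
#' @param seed Integer master seed.
#' @return Validated `pp_config` list.
#' @export
pp_config <- function(fasta = NULL, hit_files = NULL, self_hits = NULL,
                      clade_file = NULL, query_file = NULL,
                      annotation_file = NULL, out_dir = "plantpp_out",
                      min_length = 40, min_self_score = 80,
                      score_floor = 24.6, min_other_species = 5,
                      clade_min_species = 10, top_fraction = 0.01,
                      max_missing_fraction = 0.2, sigma_mult = 3,
                      cut_grid = c(10, 20, 50, 100, 200, 500),
                      run_ml = FALSE, anchors = character(0), seed = 1L) {
  check_scalar_num(min_length, "min_length", lower = 0, strict_lower = TRUE)
  check_scalar_num(min_self_score, "min_self_score", lower = 0)
  check_scalar_num(score_floor, "score_floor", lower = 0, strict_lower = TRUE)
  check_scalar_num(min_other_species, "min_other_species", lower = 0)
  check_scalar_num(clade_min_species, "clade_min_species", lower = 1)
  check_scalar_num(top_fraction, "top_fraction", lower = 0, upper = 1,
                   strict_lower = TRUE)
  check_scalar_num(max_missing_fraction, "max_missing_fraction",
                   lower = 0, upper = 1, strict_upper = TRUE)
  check_scalar_num(sigma_mult, "sigma_mult", lower = 0, strict_lower = TRUE)
  if (!is.numeric(cut_grid) || !length(cut_grid) || any(cut_grid < 2))
    stop_field("cut_grid", "must be cluster counts >= 2")
  structure(list(fasta = fasta, hit_files = hit_files, self_hits = self_hits,
                 clade_file = clade_file, query_file = query_file,
                 annotation_file = annotation_file, out_dir = out_dir,
                 min_length = min_length, min_self_score = min_self_score,
                 score_floor = score_floor,
                 min_other_species = min_other_species,
                 clade_min_species = clade_min_species,
                 top_fraction = top_fraction,
                 max_missing_fraction = max_missing_fraction,
                 sigma_mult = sigma_mult, cut_grid = as.integer(cut_grid),
                 run_ml = isTRUE(run_ml), anchors = anchors,
                 seed = as.integer(seed)),
            class = "pp_config")
}

resolve_hit_files <- function(hit_files) {
  if (length(hit_files) == 1L && is.null(names(hit_files)) &&
      dir.exists(hit_files)) {
    paths <- list.files(hit_files, pattern = "\\.tsv$", full.names = TRUE)
    paths <- paths[basename(paths) != "self_hits.tsv"]
    return(stats::setNames(paths, sub("\\.tsv$", "", basename(paths))))
  }
  hit_files
}

#' Run the full phylogenetic-profiling pipeline
#'
#' Chains the stages: NPP construction ([build_npp()]), clade-wise
#' co-evolution scan ([cladepp_scan()]), optional classifier validation
#' (clean, undersample, train and evaluate MLP and RF), and per-anchor
#' profile correlation plus hypergeometric enrichment of the candidate set.
#' Stage outputs are written as TSV under `config$out_dir` together with a
#' JSON manifest recording the configuration, input digests and per-stage
#' row counts; a rerun with the same config reproduces identical outputs.
#'
#' @param config A [pp_config()] with input paths set.
#' @return Invisibly, the manifest list (also written to
#'   `<out_dir>/manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pp_config"))
  for (f in c("fasta", "self_hits", "clade_file", "query_file")) {
    if (is.null(config[[f]]))
      stop(sprintf("config field '%s' is required", f), call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  hit_files <- resolve_hit_files(config$hit_files)
  manifest <- list(
    package_version = as.character(utils::packageVersion("plantpp")),
    seed = config$seed,
    config = config[setdiff(names(config), "hit_files")],
    input_md5 = as.list(tools::md5sum(c(config$fasta, config$self_hits,
                                        config$clade_file,
                                        config$query_file))),
    stages = list())

  npp <- stage("build-npp", build_npp(
    config$fasta, hit_files, config$self_hits,
    min_length = config$min_length, min_self_score = config$min_self_score,
    floor = config$score_floor,
    min_other_species = config$min_other_species))
  write_npp(npp, file.path(config$out_dir, "npp.tsv"))
  rep <- attr(npp, "filter_report")
  data.table::fwrite(rep, file.path(config$out_dir, "filter_report.tsv"),
                     sep = "\t")
  manifest$stages$build_npp <- list(genes = nrow(npp$values),
                                    species = ncol(npp$values),
                                    genes_filtered = nrow(rep))
  message(sprintf("[build-npp] %d genes x %d species retained (%d filtered)",
                  nrow(npp$values), ncol(npp$values), nrow(rep)))

  clades <- stage("cladepp", read_clade_map(config$clade_file))
  query <- stage("cladepp", read_gene_list(config$query_file))
  scan <- stage("cladepp", cladepp_scan(
    npp, clades, query, clade_min_species = config$clade_min_species,
    grid = config$cut_grid, fraction = config$top_fraction))
  data.table::fwrite(scan$mrs$table, file.path(config$out_dir, "mrs.tsv"),
                     sep = "\t")
  data.table::fwrite(scan$candidates,
                     file.path(config$out_dir, "candidates.tsv"), sep = "\t")
  manifest$stages$cladepp <- list(clades = scan$clades,
                                  query_used = length(scan$query),
                                  candidates = nrow(scan$candidates))
  message(sprintf("[cladepp] %d clade(s), %d candidate(s)",
                  length(scan$clades), nrow(scan$candidates)))

  if (config$run_ml) {
    ml <- stage("ml-validate", {
      cleaned <- ml_clean(npp$values,
                          max_missing_fraction = config$max_missing_fraction,
                          sigma_mult = config$sigma_mult)
      labels <- as.integer(rownames(cleaned) %in% scan$query)
      ds <- ml_dataset(cleaned, labels)
      split <- train_test_split(ds, seed = config$seed)
      bal <- cluster_centroids_undersample(split$train, seed = config$seed)
      res <- lapply(c(mlp = "mlp", rf = "rf"), function(kind)
        train_and_eval(bal, split$test,
                       classifier_spec(kind, seed = config$seed)))
      imp <- clade_feature_importance(res$rf$model, clades,
                                      min_species = config$clade_min_species)
      list(res = res, imp = imp)
    })
    metrics <- lapply(ml$res, function(r) unclass(r$metrics))
    jsonlite::write_json(metrics,
                         file.path(config$out_dir, "ml_metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    data.table::fwrite(ml$imp,
                       file.path(config$out_dir, "clade_importance.tsv"),
                       sep = "\t")
    manifest$stages$ml_validate <- metrics
    message(sprintf("[ml-validate] rf accuracy %.3f, mlp accuracy %.3f",
                    metrics$rf$accuracy, metrics$mlp$accuracy))
  }

  if (!is.null(config$annotation_file)) {
    enr <- stage("enrich", {
      ann <- read_annotations(config$annotation_file)
      universe <- intersect(rownames(npp$values), unique(ann$gene))
      hypergeom_enrich(intersect(scan$candidates$gene, universe), ann,
                       universe)
    })
    data.table::fwrite(enr, file.path(config$out_dir, "enrichment.tsv"),
                       sep = "\t")
    manifest$stages$enrich <- list(terms_tested = nrow(enr),
                                   significant = sum(enr$p_adj < 0.05))
    message(sprintf("[enrich] %d term(s) tested, %d at BH p < 0.05",
                    nrow(enr), sum(enr$p_adj < 0.05)))
  }

  for (anchor in config$anchors) {
    cres <- stage("coevolve", profile_correlation(npp, anchor,
                                                  config$top_fraction))
    data.table::fwrite(cres$table,
                       file.path(config$out_dir,
                                 sprintf("correlation_%s.tsv", anchor)),
                       sep = "\t")
    manifest$stages$coevolve[[anchor]] <-
      list(top_set = sum(cres$table$in_top_set))
  }

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(manifest)
}

#' One-command synthetic demo
#'
#' Simulates a clade-structured dataset, writes its file fixtures, and runs
#' the full pipeline on them (including classifier validation and candidate
#' enrichment).
#'
#' @param seed Integer seed (drives the simulation and every stochastic
#'   stage).
#' @param out_dir Output directory.
#' @param spec Optional [simulation_spec()]; default is the package's
#'   standard synthetic scenario with the given seed.
#' @param run_ml Run the classifier-validation stage (default `TRUE`).
#' @return Invisibly, the pipeline manifest.
#' @export
demo_pipeline <- function(seed = 1L, out_dir = tempfile("plantpp_demo"),
                          spec = NULL, run_ml = TRUE) {
  if (is.null(spec)) spec <- simulation_spec(seed = seed)
  ds <- simulate_dataset(spec)
  fixdir <- file.path(out_dir, "fixtures")
  manifest <- write_fixtures(ds, fixdir)
  cfg <- pp_config(fasta = manifest$fasta,
                   hit_files = manifest$hit_files,
                   self_hits = manifest$self_hits,
                   clade_file = manifest$clade_map,
                   query_file = manifest$query,
                   annotation_file = manifest$annotations,
                   out_dir = file.path(out_dir, "results"),
                   run_ml = run_ml, seed = seed)
  run_pipeline(cfg)
}
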
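write_fasta <- function(records) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(unlist(lapply(names(records), function(id)
    c(paste0(">", id), records[[id]]))), path)
  path
}

write_hits <- function(rows) {
  # rows: list of c(qseqid, sseqid, bitscore)
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  lines <- vapply(rows, function(r)
    paste(c(r[1], r[2], "50.0", "100", "50", "0", "1", "100", "1", "100",
            "1e-10", r[3]), collapse = "\t"), "")
  writeLines(lines, path)
  path
}

test_that("proteome lengths come from residue counts, duplicates are fatal", {
  fa <- write_fasta(list(g1 = strrep("A", 100)))
  expect_identical(read_proteome_lengths(fa), c(g1 = 100L))

  fa2 <- write_fasta(list(g1 = strrep("M", 39), g2 = strrep("M", 40)))
  expect_identical(read_proteome_lengths(fa2), c(g1 = 39L, g2 = 40L))

  fa3 <- write_fasta(list(g1 = "AAAA", g1 = "MMMM"))
  expect_error(read_proteome_lengths(fa3), "duplicate.*g1")
})

test_that("best-hit matrix keeps the maximum bit-score per gene and species", {
  sp1 <- write_hits(list(c("g1", "h1", "50.1"), c("g1", "h2", "75.3"),
                         c("g2", "h3", "30")))
  sp2 <- write_hits(list(c("g1", "h4", "99")))
  selfh <- write_hits(list(c("g1", "g1", "500"), c("g2", "g2", "400"),
                           c("g1", "g9", "120")))
  bm <- best_hit_matrix(c(spA = sp1, spB = sp2), selfh)
  expect_equal(bm$scores["g1", "spA"], 75.3)
  expect_equal(bm$scores["g2", "spA"], 30)
  expect_true(is.na(bm$scores["g2", "spB"]))          # no hit -> absent
  expect_equal(unname(bm$self_scores), c(500, 400))   # qseqid == sseqid only
})

test_that("combined 13-column hit files and malformed input are handled", {
  comb <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(c("spA", "g1", "h1", rep("0", 9), "42.5"),
                     collapse = "\t"),
               paste(c("spB", "g1", "h2", rep("0", 9), "17.2"),
                     collapse = "\t")), comb)
  selfh <- write_hits(list(c("g1", "g1", "300")))
  bm <- best_hit_matrix(comb, selfh)
  expect_equal(unname(bm$scores["g1", c("spA", "spB")]), c(42.5, 17.2))

  expect_error(best_hit_matrix(c(spA = "no/such/file.tsv"), selfh),
               "not found")
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(c("g1", "h1", rep("0", 9), "42.5"), collapse = "\t"),
               paste(c("g1", "h2", rep("0", 9), "oops"), collapse = "\t")),
             bad)
  expect_error(best_hit_matrix(c(spA = bad), selfh), "line 2")
})

make_bm <- function(scores, self = NULL, lengths = NULL) {
  genes <- rownames(scores)
  if (is.null(self)) self <- stats::setNames(rep(500, length(genes)), genes)
  if (is.null(lengths))
    lengths <- stats::setNames(rep(100L, length(genes)), genes)
  bitscore_matrix(scores, self, lengths)
}

test_that("filtering applies length, self-score, floor and support rules in order", {
  scores <- rbind(
    g1 = c(10, 100, 100, 100, 100, 100),   # 10 must be floored
    g2 = c(100, 100, 100, 100, NA, NA),    # support 4 -> dropped
    g3 = c(100, 100, 100, 100, 100, NA),   # support 5 -> kept
    g4 = c(24.6, 24.6, 24.6, 24.6, 24.6, 24.6),  # support 0 -> dropped
    g5 = c(100, 100, 100, 100, 100, 100),  # short protein -> dropped
    g6 = c(100, 100, 100, 100, 100, 100))  # weak self-score -> dropped
  colnames(scores) <- paste0("s", 1:6)
  bm <- make_bm(scores,
                self = c(g1 = 500, g2 = 500, g3 = 500, g4 = 500, g5 = 500,
                         g6 = 80),
                lengths = c(g1 = 100L, g2 = 100L, g3 = 100L, g4 = 100L,
                            g5 = 39L, g6 = 100L))
  out <- filter_and_floor(bm)
  expect_identical(rownames(out$scores), c("g1", "g3"))
  expect_equal(out$scores["g1", "s1"], 24.6)       # floored
  expect_equal(out$scores["g3", "s6"], 24.6)       # absent -> floor
  expect_true(all(out$scores >= 24.6))
  rep <- attr(out, "filter_report")
  expect_identical(rep$rule[rep$gene == "g5"], "min_length")
  expect_identical(rep$rule[rep$gene == "g6"], "self_score")
  expect_identical(rep$rule[rep$gene == "g2"], "min_other_species")
  expect_identical(rep$rule[rep$gene == "g4"], "min_other_species")

  # boundary: score exactly at the floor is a fixed point, self-score just
  # above 80 survives
  bm2 <- make_bm(rbind(g1 = c(24.6, 90, 90, 90, 90, 90),
                       g2 = c(90, 90, 90, 90, 90, 90)) |>
                   (\(m) { colnames(m) <- paste0("s", 1:6); m })(),
                 self = c(g1 = 80.1, g2 = 500))
  out2 <- filter_and_floor(bm2)
  expect_equal(out2$scores["g1", "s1"], 24.6)
  expect_identical(rownames(out2$scores), c("g1", "g2"))
})

test_that("filter_and_floor is idempotent", {
  ds <- simulate_dataset(simulation_spec(n_genes = 120, clade_sizes = c(6, 6),
                                         seed = 9))
  once <- filter_and_floor(ds$bitscore_matrix)
  twice <- filter_and_floor(once)
  expect_equal(once$scores, twice$scores)
  expect_identical(rownames(once$scores), rownames(twice$scores))
  expect_identical(nrow(attr(twice, "filter_report")), 0L)
})

test_that("LPP normalization divides by the self-score", {
  bm <- make_bm(rbind(g1 = c(50, 200), g2 = c(24.6, 24.6)) |>
                  (\(m) { colnames(m) <- c("s1", "s2"); m })(),
                self = c(g1 = 200, g2 = 246))
  lpp <- normalize_lpp(bm)
  expect_equal(lpp["g1", "s1"], 0.25)
  expect_equal(lpp["g1", "s2"], 1.0)           # BS == self
  expect_equal(unname(lpp["g2", ]), c(0.1, 0.1))  # floored row is constant
  expect_true(all(lpp > 0))

  bm$self_scores["g1"] <- 0
  expect_error(normalize_lpp(bm), "g1")
})

test_that("column Z-scoring matches the sample-sd definition", {
  lpp <- cbind(s1 = c(1, 3), s2 = c(2, 2))
  rownames(lpp) <- c("g1", "g2")
  expect_warning(npp <- zscore_columns(lpp), "constant")
  expect_equal(unname(npp$values[, "s1"]),
               c(-1 / sqrt(2), 1 / sqrt(2)), tolerance = 1e-12)
  expect_equal(unname(npp$values[, "s2"]), c(0, 0))
  expect_true(npp$column_stats$degenerate[2])
  expect_equal(npp$column_stats$mu, c(2, 2))

  expect_error(zscore_columns(lpp[1, , drop = FALSE]), "two genes")
})

test_that("every non-degenerate NPP column is standardized to 1e-9", {
  ds <- simulate_dataset(simulation_spec(n_genes = 300, clade_sizes = rep(8, 3),
                                         seed = 21))
  npp <- sim_npp(ds)
  ok <- !npp$column_stats$degenerate
  expect_true(any(ok))
  expect_true(all(abs(colMeans(npp$values[, ok])) < 1e-9))
  expect_true(all(abs(apply(npp$values[, ok], 2, stats::sd) - 1) < 1e-9))
})

test_that("permuting gene order permutes all outputs identically", {
  ds <- simulate_dataset(simulation_spec(n_genes = 80, clade_sizes = c(5, 5),
                                         seed = 13))
  bm <- ds$bitscore_matrix
  set.seed(1)
  perm <- sample(nrow(bm$scores))
  bm_p <- bitscore_matrix(bm$scores[perm, ], bm$self_scores, bm$lengths)
  npp <- sim_npp(ds)
  npp_p <- zscore_columns(normalize_lpp(filter_and_floor(bm_p)))
  common <- rownames(npp$values)
  expect_setequal(common, rownames(npp_p$values))
  expect_equal(npp_p$values[common, ], npp$values[common, ], tolerance = 1e-12)
})

test_that("NPP matrices survive the TSV round trip, plain and gzipped", {
  ds <- simulate_dataset(simulation_spec(n_genes = 60, clade_sizes = c(4, 4),
                                         seed = 17))
  npp <- sim_npp(ds)
  for (ext in c(".tsv", ".tsv.gz")) {
    path <- withr::local_tempfile(fileext = ext)
    write_npp(npp, path)
    back <- read_npp(path)
    expect_identical(rownames(back$values), rownames(npp$values))
    expect_equal(back$values, npp$values, tolerance = 1e-12)
  }
})
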
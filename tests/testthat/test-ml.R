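two_gaussians <- function(n = 200, d = 10, sep = 5, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  x <- matrix(stats::rnorm(n * d), n) + outer(y, rep(sep / sqrt(d), d))
  colnames(x) <- paste0("f", seq_len(d))
  ml_dataset(x, y)
}

test_that("3-sigma outliers are nulled and the missingness rules use strict boundaries", {
  set.seed(2)
  x <- matrix(stats::rnorm(100 * 5), 100, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  spike <- 50
  x[7, 2] <- spike
  mu <- mean(x[, 2]); sg <- stats::sd(x[, 2])
  expect_gt(spike, mu + 3 * sg)       # planted point is a 3-sigma outlier
  out <- ml_clean(x)
  expect_false(anyNA(out))
  expect_lt(out[7, 2], spike)         # replaced by interpolation, not kept

  # feature with exactly 20% missing is kept, above 20% is dropped
  x2 <- matrix(stats::rnorm(20 * 5), 20, 5,
               dimnames = list(NULL, paste0("f", 1:5)))
  x2[1:4, 1] <- NA    # 20% exactly
  x2[1:5, 2] <- NA    # 25%
  out2 <- ml_clean(x2)
  expect_true("f1" %in% colnames(out2))
  expect_false("f2" %in% colnames(out2))
})

test_that("row gaps are filled by linear interpolation with nearest-value edges", {
  x <- rbind(c(1, NA, 3, 4, 5),
             c(NA, 2, 4, 6, 8),
             c(1, 2, 3, 4, NA),
             matrix(1:35 / 7, 7, 5, byrow = TRUE))
  colnames(x) <- paste0("f", 1:5)
  out <- ml_clean(x, sigma_mult = 100)   # isolate the interpolation rule
  expect_equal(unname(out[1, ]), c(1, 2, 3, 4, 5))
  expect_equal(unname(out[2, 1]), 2)     # leading gap -> nearest value
  expect_equal(unname(out[3, 5]), 4)     # trailing gap -> nearest value
})

test_that("cleaning is idempotent on its own output", {
  set.seed(5)
  x <- matrix(stats::runif(200 * 8), 200, 8,
              dimnames = list(NULL, paste0("f", 1:8)))
  x[cbind(sample(200, 6), sample(8, 6, replace = TRUE))] <-
    c(90, -80, 120, -95, 70, 85)       # gross spikes
  once <- ml_clean(x)
  twice <- ml_clean(once)
  a <- once; attributes(a)[c("feature_stats")] <- NULL
  b <- twice; attributes(b)[c("feature_stats")] <- NULL
  expect_equal(a, b)
})

test_that("cluster-centroids undersampling balances classes and preserves minority rows", {
  set.seed(3)
  x <- matrix(stats::rnorm(13 * 4), 13, 4,
              dimnames = list(paste0("r", 1:13), paste0("f", 1:4)))
  ds <- ml_dataset(x, c(rep(0L, 10), rep(1L, 3)))
  bal <- cluster_centroids_undersample(ds, seed = 9)
  expect_equal(nrow(bal$features), 6)
  expect_equal(as.integer(table(bal$labels)), c(3L, 3L))
  expect_identical(bal$features[1:3, ], x[11:13, ])   # minority untouched

  balanced <- ml_dataset(x[1:6, ], rep(c(0L, 1L), 3))
  expect_message(same <- cluster_centroids_undersample(balanced), "balanced")
  expect_identical(same, balanced)

  expect_error(cluster_centroids_undersample(
    ml_dataset(x, rep(0L, 13))), "both classes")
})

test_that("centroids of duplicated majority rows equal the row itself", {
  row <- c(1.5, -2, 0.25)
  x <- rbind(matrix(rep(row, 4), 4, byrow = TRUE),
             matrix(stats::rnorm(6), 2, 3))
  colnames(x) <- paste0("f", 1:3)
  ds <- ml_dataset(x, c(rep(0L, 4), 1L, 1L))
  bal <- cluster_centroids_undersample(ds, seed = 1)
  centroids <- bal$features[bal$labels == 0L, ]
  expect_equal(unname(centroids), rbind(row, row), ignore_attr = TRUE)
})

test_that("undersampling contract holds over random imbalanced datasets", {
  for (s in 1:10) {
    set.seed(s)
    n_maj <- sample(20:60, 1); n_min <- sample(2:10, 1)
    x <- matrix(stats::rnorm((n_maj + n_min) * 6), ncol = 6,
                dimnames = list(NULL, paste0("f", 1:6)))
    ds <- ml_dataset(x, c(rep(0L, n_maj), rep(1L, n_min)))
    bal <- cluster_centroids_undersample(ds, seed = s)
    expect_equal(sum(bal$labels == 0L), sum(bal$labels == 1L))
    expect_identical(bal$features[bal$labels == 1L, , drop = FALSE],
                     x[ds$labels == 1L, , drop = FALSE])
  }
})

test_that("metrics satisfy their confusion-count identities", {
  m <- eval_metrics(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
                    c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0))
  expect_equal(m$tp, 3); expect_equal(m$fp, 1)
  expect_equal(m$fn, 1); expect_equal(m$tn, 5)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 0.75)
  expect_equal(m$accuracy, 0.8)

  perfect <- eval_metrics(c(0, 1, 0, 1), c(0, 1, 0, 1))
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))

  all_neg <- eval_metrics(c(0, 0), c(1, 0))
  expect_equal(all_neg$f1, 0)   # P + R degenerate -> defined as 0
})

test_that("classifiers are reproducible and reject single-class training labels", {
  ds <- two_gaussians(n = 120, d = 6, sep = 4, seed = 11)
  sp <- train_test_split(ds, seed = 2)
  expect_equal(nrow(sp$test$features), 24)
  for (kind in c("mlp", "rf")) {
    spec <- classifier_spec(kind, hidden = c(16, 8), max_iter = 150, seed = 5)
    r1 <- train_and_eval(sp$train, sp$test, spec)
    r2 <- train_and_eval(sp$train, sp$test, spec)
    expect_identical(unclass(r1$metrics), unclass(r2$metrics), label = kind)
  }
  bad <- ml_dataset(sp$train$features, rep(0L, nrow(sp$train$features)))
  expect_error(train_and_eval(bad, sp$test, classifier_spec("rf")),
               "single class")
})

test_that("grid search picks the better hyperparameter by CV accuracy", {
  ds <- two_gaussians(n = 120, d = 6, sep = 4, seed = 13)
  gs <- grid_search(ds, classifier_spec("rf", seed = 3),
                    grid = list(num_trees = c(5, 55)), folds = 3, seed = 3)
  expect_true(gs$best_spec$num_trees %in% c(5, 55))
  expect_equal(nrow(gs$cv), 2)
  expect_true(all(gs$cv$cv_accuracy >= 0 & gs$cv$cv_accuracy <= 1))
})

test_that("clade importance averages per-species importances with SE = sd/sqrt(n)", {
  sp_a <- paste0("a", 1:10); sp_b <- paste0("b", 1:12); sp_c <- "c1"
  cm <- clade_map(c(sp_a, sp_b, sp_c),
                  c(rep("A", 10), rep("B", 12), "C"))
  imp <- c(stats::setNames(seq(1, 2, length.out = 10), sp_a),
           stats::setNames(rep(5, 12), sp_b),
           stats::setNames(9, sp_c))
  fake_rf <- structure(list(variable.importance = imp), class = "ranger")

  out <- clade_feature_importance(fake_rf, cm, min_species = 10)
  expect_setequal(out$clade, c("A", "B"))   # 1-species clade omitted
  expect_equal(out$mean_importance[out$clade == "B"], 5)
  expect_equal(out$se[out$clade == "B"], 0)
  expect_equal(out$se[out$clade == "A"],
               stats::sd(imp[sp_a]) / sqrt(10))

  out1 <- clade_feature_importance(fake_rf, cm, min_species = 1)
  expect_equal(out1$se[out1$clade == "C"], 0)   # single species -> SE 0

  # uniform importances -> all clade means equal
  fake_u <- structure(list(variable.importance =
                             stats::setNames(rep(2, 23), names(imp))),
                      class = "ranger")
  outu <- clade_feature_importance(fake_u, cm, min_species = 1)
  expect_true(all(outu$mean_importance == 2))
})

test_that("importance concentrates in the clade carrying the planted signal", {
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    n <- 200
    sp_names <- c(paste0("A", 1:10), paste0("B", 1:10))
    cm <- clade_map(sp_names, rep(c("A", "B"), each = 10))
    y <- rep(c(0L, 1L), each = n / 2)
    x <- matrix(stats::rnorm(n * 20), n)
    x[, 1:10] <- x[, 1:10] + outer(y, rep(1.5, 10))  # signal only in clade A
    colnames(x) <- sp_names
    fit <- train_and_eval(ml_dataset(x, y), ml_dataset(x, y),
                          classifier_spec("rf", seed = s))
    imp <- clade_feature_importance(fit$model, cm, min_species = 10)
    hits <- hits + (imp$clade[1] == "A")
  }
  expect_gte(hits, 9)
})
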
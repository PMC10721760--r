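#' Clean a feature matrix for classification
#'
#' Applies, in order: (1) per-feature 3-sigma outlier nulling — values
#' strictly outside `mu +/- sigma_mult * sigma` (sample statistics over
#' non-missing entries) become missing; (2) features with more than
#' `max_missing_fraction` missing are dropped; (3) then samples with more
#' than `max_missing_fraction` missing are dropped; (4) remaining gaps are
#' filled by linear interpolation along each gene row over the fixed feature
#' (species) order, with leading/trailing gaps taking the nearest observed
#' value.
#'
#' @param x Numeric matrix, genes (samples) x species (features); `NA`
#'   allowed.
#' @param max_missing_fraction Strict threshold for dropping features, then
#'   samples (default 0.2: "more than 20 percent missing").
#' @param sigma_mult Outlier cutoff in standard deviations (default 3).
#' @return Numeric matrix with no missing values; per-feature `mu` and
#'   `sigma` used by the outlier rule are attached as attribute
#'   `"feature_stats"`.
#' @export
ml_clean <- function(x, max_missing_fraction = 0.2, sigma_mult = 3) {
  stopifnot(is.matrix(x), is.numeric(x))
  mu <- colMeans(x, na.rm = TRUE)
  sigma <- apply(x, 2, stats::sd, na.rm = TRUE)
  lo <- mu - sigma_mult * sigma
  hi <- mu + sigma_mult * sigma
  out <- x
  out[sweep(x, 2, lo, "<") | sweep(x, 2, hi, ">")] <- NA

  keep_f <- colMeans(is.na(out)) <= max_missing_fraction
  if (!any(keep_f)) stop("all features dropped by the missingness rule",
                         call. = FALSE)
  out <- out[, keep_f, drop = FALSE]
  keep_s <- rowMeans(is.na(out)) <= max_missing_fraction
  out <- out[keep_s, , drop = FALSE]

  if (anyNA(out))
    out <- t(apply(out, 1, function(r) zoo::na.approx(r, na.rm = FALSE,
                                                      rule = 2)))
  colnames(out) <- colnames(x)[keep_f]
  attr(out, "feature_stats") <- data.frame(
    feature = colnames(x), mu = mu, sigma = sigma, kept = keep_f,
    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Bundle features and binary labels into an ML dataset
#'
#' @param features Numeric matrix, samples x features, no missing values.
#' @param labels 0/1 vector (or anything coercible), one per sample.
#' @return `pp_ml_dataset` list with `features` and integer `labels`.
#' @export
ml_dataset <- function(features, labels) {
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  if (anyNA(features)) stop("features contain missing values; run ml_clean()")
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop_field("labels", "must be 0/1")
  structure(list(features = features, labels = labels),
            class = "pp_ml_dataset")
}

# k-means++ seeding (Arthur & Vassilvitskii): spread initial centers by
# sampling points with probability proportional to squared distance from the
# nearest center chosen so far.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  if (k > 1) {
    d2 <- rowSums(sweep(x, 2, centers[1, ], "-")^2)
    for (j in 2:k) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j, ] <- x[sample.int(n, 1, prob = prob), ]
      d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ], "-")^2))
    }
  }
  centers
}

#' Balance classes with Cluster-Centroids undersampling
#'
#' Runs K-means (k = minority-class count, k-means++ seeding, Lloyd
#' iterations) on the majority-class rows and replaces the majority class
#' with the k cluster centroids; minority rows pass through unchanged, so
#' the output has equal class counts. If the classes are already balanced
#' (or the minority is not smaller), the dataset is returned unchanged with
#' a message.
#'
#' @param dataset A [ml_dataset()] containing both classes.
#' @param seed Integer seed controlling the K-means initialization.
#' @return A balanced `pp_ml_dataset` (centroid rows are named
#'   `centroid_1 ...`).
#' @export
cluster_centroids_undersample <- function(dataset, seed = 1L) {
  stopifnot(inherits(dataset, "pp_ml_dataset"))
  y <- dataset$labels
  counts <- table(factor(y, levels = c(0L, 1L)))
  if (any(counts == 0)) stop("both classes must be present", call. = FALSE)
  minority <- if (counts[["1"]] <= counts[["0"]]) 1L else 0L
  k <- min(counts)
  if (counts[["0"]] == counts[["1"]]) {
    message("classes already balanced; returning dataset unchanged")
    return(dataset)
  }
  maj <- dataset$features[y != minority, , drop = FALSE]
  minr <- dataset$features[y == minority, , drop = FALSE]

  set.seed(as.integer(seed))
  uniq <- unique(maj)
  if (nrow(uniq) <= k) {
    # fewer distinct points than clusters: each cluster collapses onto one
    # of the duplicated rows, so the centroids are the rows themselves
    centers <- uniq[rep(seq_len(nrow(uniq)), length.out = k), , drop = FALSE]
  } else {
    km <- stats::kmeans(maj, centers = kmeanspp_init(maj, k),
                        iter.max = 300, algorithm = "Lloyd")
    centers <- km$centers
  }
  rownames(centers) <- if (is.null(rownames(dataset$features))) NULL else
    paste0("centroid_", seq_len(k))
  feats <- rbind(minr, centers)
  ml_dataset(feats, c(rep(minority, nrow(minr)),
                      rep(1L - minority, k)))
}

#' Classifier specification
#'
#' @param kind `"mlp"` (feed-forward network) or `"rf"` (random forest).
#' @param hidden MLP hidden-layer sizes (default `c(180, 90, 40)`, ReLU
#'   activations, Adam updates).
#' @param learning_rate MLP initial Adam learning rate (default 1e-4).
#' @param alpha MLP L2 regularization coefficient (default 0.1).
#' @param max_iter MLP training epochs (default 1000).
#' @param batch_size MLP minibatch size (default 200, capped at n).
#' @param num_trees RF ensemble size (default 55).
#' @param max_depth RF maximum tree depth (default 15).
#' @param seed Integer seed for weight init / bootstrap.
#' @return `pp_classifier_spec` list.
#' @export
classifier_spec <- function(kind = c("mlp", "rf"), hidden = c(180, 90, 40),
                            learning_rate = 1e-4, alpha = 0.1,
                            max_iter = 1000, batch_size = 200,
                            num_trees = 55, max_depth = 15, seed = 1L) {
  kind <- match.arg(kind)
  check_scalar_num(learning_rate, "learning_rate", lower = 0, strict_lower = TRUE)
  check_scalar_num(alpha, "alpha", lower = 0)
  check_scalar_num(num_trees, "num_trees", lower = 1)
  check_scalar_num(max_depth, "max_depth", lower = 1)
  if (any(hidden < 1)) stop_field("hidden", "layer sizes must be positive")
  structure(list(kind = kind, hidden = as.integer(hidden),
                 learning_rate = learning_rate, alpha = alpha,
                 max_iter = as.integer(max_iter),
                 batch_size = as.integer(batch_size),
                 num_trees = as.integer(num_trees),
                 max_depth = as.integer(max_depth),
                 seed = as.integer(seed)),
            class = "pp_classifier_spec")
}

#' Classification metrics from predictions
#'
#' @param predicted 0/1 predicted labels.
#' @param truth 0/1 true labels.
#' @return `pp_metrics` list: `accuracy`, `precision`, `recall`, `f1` (for
#'   the positive class; 0 when precision + recall is 0) and confusion
#'   counts `tp`, `fp`, `fn`, `tn`.
#' @export
eval_metrics <- function(predicted, truth) {
  predicted <- as.integer(predicted); truth <- as.integer(truth)
  stopifnot(length(predicted) == length(truth))
  tp <- sum(predicted == 1 & truth == 1)
  fp <- sum(predicted == 1 & truth == 0)
  fn <- sum(predicted == 0 & truth == 1)
  tn <- sum(predicted == 0 & truth == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(list(accuracy = (tp + tn) / length(truth),
                 precision = precision, recall = recall, f1 = f1,
                 tp = tp, fp = fp, fn = fn, tn = tn),
            class = "pp_metrics")
}

#' @export
print.pp_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.4f  precision %.4f  recall %.4f  f1 %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  cat(sprintf("confusion: TP %d  FP %d  FN %d  TN %d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Train a classifier and evaluate it on a test set
#'
#' Fits the classifier described by `spec` on the training set and reports
#' test-set metrics. Random forests use `ranger` (impurity importance is
#' retained for [clade_feature_importance()]); the MLP is the package's
#' feed-forward network (see [mlp_fit()]).
#'
#' @param train,test [ml_dataset()]s with identical feature columns.
#' @param spec A [classifier_spec()].
#' @return List: `metrics` (a `pp_metrics`), `model` (fitted handle),
#'   `spec`.
#' @export
train_and_eval <- function(train, test, spec = classifier_spec("rf")) {
  stopifnot(inherits(train, "pp_ml_dataset"), inherits(test, "pp_ml_dataset"),
            inherits(spec, "pp_classifier_spec"))
  if (!identical(colnames(train$features), colnames(test$features)))
    stop("train and test feature columns differ", call. = FALSE)
  if (length(unique(train$labels)) < 2)
    stop("training labels contain a single class", call. = FALSE)

  if (spec$kind == "rf") {
    df <- data.frame(.y = factor(train$labels, levels = c(0, 1)),
                     train$features, check.names = FALSE)
    model <- ranger::ranger(
      dependent.variable.name = ".y", data = df,
      num.trees = spec$num_trees, max.depth = spec$max_depth,
      importance = "impurity", seed = spec$seed, num.threads = 1)
    pred <- stats::predict(model, data.frame(test$features,
                                             check.names = FALSE),
                           num.threads = 1)
    predicted <- as.integer(as.character(pred$predictions))
  } else {
    model <- mlp_fit(train$features, train$labels, hidden = spec$hidden,
                     learning_rate = spec$learning_rate, alpha = spec$alpha,
                     max_iter = spec$max_iter, batch_size = spec$batch_size,
                     seed = spec$seed)
    predicted <- as.integer(mlp_predict(model, test$features) >= 0.5)
  }
  list(metrics = eval_metrics(predicted, test$labels), model = model,
       spec = spec)
}

#' Stratified train/test split
#'
#' @param dataset A [ml_dataset()].
#' @param test_fraction Fraction of each class assigned to the test set
#'   (default 0.2).
#' @param seed Integer seed.
#' @return List of `pp_ml_dataset`s: `train`, `test`.
#' @export
train_test_split <- function(dataset, test_fraction = 0.2, seed = 1L) {
  stopifnot(inherits(dataset, "pp_ml_dataset"))
  check_scalar_num(test_fraction, "test_fraction", lower = 0, upper = 1,
                   strict_lower = TRUE, strict_upper = TRUE)
  set.seed(as.integer(seed))
  test_idx <- unlist(lapply(c(0L, 1L), function(cl) {
    idx <- which(dataset$labels == cl)
    sample(idx, max(1L, round(test_fraction * length(idx))))
  }))
  list(train = ml_dataset(dataset$features[-test_idx, , drop = FALSE],
                          dataset$labels[-test_idx]),
       test = ml_dataset(dataset$features[test_idx, , drop = FALSE],
                         dataset$labels[test_idx]))
}

#' Grid-search hyperparameters by cross-validated accuracy
#'
#' Simple k-fold cross-validation over a declared grid of
#' [classifier_spec()] modifications; the best setting (highest mean CV
#' accuracy, first on ties) is refit on the full training set.
#'
#' @param train A [ml_dataset()].
#' @param base A [classifier_spec()] providing fixed settings.
#' @param grid Named list of parameter vectors to cross (e.g.
#'   `list(num_trees = c(25, 55), max_depth = c(5, 15))`).
#' @param folds Number of CV folds (default 3).
#' @param seed Integer seed for fold assignment.
#' @return List: `best_spec`, `cv` (data.frame of settings and mean CV
#'   accuracy).
#' @export
grid_search <- function(train, base, grid, folds = 3, seed = 1L) {
  stopifnot(inherits(train, "pp_ml_dataset"), length(grid) >= 1)
  combos <- expand.grid(grid, stringsAsFactors = FALSE)
  set.seed(as.integer(seed))
  fold <- sample(rep_len(seq_len(folds), nrow(train$features)))
  acc <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    spec_i <- base
    for (p in names(combos)) spec_i[[p]] <- combos[[p]][i]
    fold_acc <- vapply(seq_len(folds), function(f) {
      tr <- ml_dataset(train$features[fold != f, , drop = FALSE],
                       train$labels[fold != f])
      te <- ml_dataset(train$features[fold == f, , drop = FALSE],
                       train$labels[fold == f])
      train_and_eval(tr, te, spec_i)$metrics$accuracy
    }, 0)
    acc[i] <- mean(fold_acc)
  }
  best <- base
  for (p in names(combos)) best[[p]] <- combos[[p]][which.max(acc)]
  list(best_spec = best, cv = cbind(combos, cv_accuracy = acc))
}

#' Clade-level feature importance of a fitted random forest
#'
#' Averages impurity-based per-species importances within clades; the
#' standard error is `sd / sqrt(clade size)` (0 for single-species clades).
#' Clades with fewer than `min_species` species in the map are omitted, as
#' are clades none of whose species survived as features (with a warning).
#'
#' @param model A fitted `ranger` object with impurity importance.
#' @param clades A [clade_map()].
#' @param min_species Minimum clade size to report (default 10).
#' @return data.frame `clade`, `n_species` (features contributing),
#'   `mean_importance`, `se`, sorted by mean importance descending.
#' @export
clade_feature_importance <- function(model, clades, min_species = 10) {
  imp <- ranger::importance(model)
  if (is.null(imp) || !length(imp))
    stop("model has no feature importances; fit with importance = 'impurity'")
  keep <- eligible_clades(clades, min_species)
  rows <- lapply(keep, function(cl) {
    sp <- intersect(clades$species[clades$clade == cl], names(imp))
    if (length(sp) == 0) {
      warning(sprintf("clade '%s' has no surviving features; omitted", cl),
              call. = FALSE)
      return(NULL)
    }
    v <- imp[sp]
    data.frame(clade = cl, n_species = length(sp),
               mean_importance = mean(v),
               se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no clade has surviving features")
  out[order(-out$mean_importance), , drop = FALSE]
}
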
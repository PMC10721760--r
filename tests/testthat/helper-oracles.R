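# Independent oracles used to cross-check the implementation.

# Canonical form of a partition (list of index sets) so two partitions can be
# compared independently of cluster labels or ordering.
canonical_partition <- function(clusters) {
  sets <- unname(lapply(clusters, sort))
  sets[order(vapply(sets, min, 0L))]
}

# Brute-force Ward agglomeration: at every step merge the pair of clusters
# whose fusion minimizes the increase in total within-cluster sum of squares,
# Delta = |A||B|/(|A|+|B|) * ||mean(A) - mean(B)||^2. Returns the partition
# after each merge.
ward_oracle_partitions <- function(x) {
  clusters <- as.list(seq_len(nrow(x)))
  out <- list()
  while (length(clusters) > 1) {
    best <- NULL; best_d <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        A <- clusters[[i]]; B <- clusters[[j]]
        mA <- colMeans(x[A, , drop = FALSE])
        mB <- colMeans(x[B, , drop = FALSE])
        d <- (length(A) * length(B)) / (length(A) + length(B)) *
          sum((mA - mB)^2)
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    out[[length(out) + 1]] <- canonical_partition(clusters)
  }
  out
}

# Partition after each merge step of an hclust tree, in canonical form.
hclust_partitions <- function(hc) {
  n <- length(hc$order)
  merged_sets <- vector("list", nrow(hc$merge))
  active <- stats::setNames(lapply(seq_len(n), identity),
                            as.character(-seq_len(n)))
  out <- vector("list", nrow(hc$merge))
  for (s in seq_len(nrow(hc$merge))) {
    get_set <- function(v) if (v < 0) -v else merged_sets[[v]]
    newset <- c(get_set(hc$merge[s, 1]), get_set(hc$merge[s, 2]))
    merged_sets[[s]] <- newset
    active[[as.character(hc$merge[s, 1])]] <- NULL
    active[[as.character(hc$merge[s, 2])]] <- NULL
    active[[as.character(s)]] <- newset
    out[[s]] <- canonical_partition(active)
  }
  out
}

# Exhaustive hypergeometric upper tail: fraction of all n-subsets of a size-N
# universe that contain at least k of the K term members.
hyper_enum_p <- function(k, K, N, n) {
  draws <- utils::combn(N, n)
  mean(apply(draws, 2, function(d) sum(d <= K) >= k))
}

# Small helper: simulated dataset -> NPP matrix via the package pipeline.
sim_npp <- function(ds, ...) {
  zscore_columns(normalize_lpp(filter_and_floor(ds$bitscore_matrix, ...)))
}

# Named module/query/held-out gene sets of a simulated dataset.
sim_gene_sets <- function(ds) {
  labs <- ds$module_labels
  mod <- names(labs)[labs != "background"]
  list(module = mod,
       query = mod[seq_len(floor(length(mod) / 2))],
       held = mod[(floor(length(mod) / 2) + 1):length(mod)],
       background = names(labs)[labs == "background"])
}
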
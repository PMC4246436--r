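# Independent oracles and small utilities shared across the test files.
# Each oracle is a deliberately naive re-derivation (loops, enumeration,
# exhaustive recomputation) kept free of the code paths it checks.

# strip corr_matrix attributes down to the bare numeric matrix
bare <- function(x) {
  attributes(x) <- attributes(x)[c("dim", "dimnames")]
  x
}

# element-by-element Euclidean distance
euclidean_loop_oracle <- function(x, y) {
  acc <- 0
  for (t in seq_along(x)) acc <- acc + (x[t] - y[t])^2
  sqrt(acc)
}

# definitional two-pass Pearson correlation
pearson_loop_oracle <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  num <- 0; sx <- 0; sy <- 0
  for (t in seq_along(x)) {
    num <- num + (x[t] - mx) * (y[t] - my)
    sx <- sx + (x[t] - mx)^2
    sy <- sy + (y[t] - my)^2
  }
  num / sqrt(sx * sy)
}

# midranks via explicit sorting: positions of each value's tie group
midrank_sort_oracle <- function(x) {
  ord <- order(x)
  r <- numeric(length(x))
  pos <- 1L
  while (pos <= length(x)) {
    grp <- pos
    while (grp < length(x) && x[ord[grp + 1L]] == x[ord[pos]]) grp <- grp + 1L
    r[ord[pos:grp]] <- mean(pos:grp)
    pos <- grp + 1L
  }
  r
}

# exhaustive-recomputation agglomerative clustering: at every step scan all
# cluster pairs and recompute the linkage distance from the original matrix
naive_hclust_oracle <- function(d, linkage) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1L) {
    best <- Inf; ba <- NA; bb <- NA
    for (a in seq_len(length(clusters) - 1L)) {
      for (b in (a + 1L):length(clusters)) {
        vals <- d[clusters[[a]], clusters[[b]]]
        dd <- switch(linkage, complete = max(vals), single = min(vals),
                     average = mean(vals))
        if (dd < best) { best <- dd; ba <- a; bb <- b }
      }
    }
    heights <- c(heights, best)
    clusters <- c(clusters[-c(ba, bb)], list(c(clusters[[ba]], clusters[[bb]])))
    partitions[[length(partitions) + 1L]] <- clusters
  }
  list(heights = heights, partitions = partitions)
}

# label-invariant canonical form of a partition (list of sorted index sets,
# ordered by smallest member)
canonical_partition <- function(groups) {
  sets <- lapply(unname(groups), sort)
  sets[order(vapply(sets, min, numeric(1L)))]
}

partition_from_labels <- function(labels) {
  canonical_partition(split(seq_along(labels), labels))
}

# two labelings describe the same partition up to relabeling
same_partition <- function(a, b) {
  identical(partition_from_labels(a), partition_from_labels(b))
}

# expression matrix + populated block store in one call
make_store <- function(n, p, k, g = 3, seed = 1, ...) {
  sim <- simulate_expression(n = n, p = p, g = g, seed = seed, ...)
  store <- withr::local_tempdir(.local_envir = parent.frame())
  part <- split_blocks(sim$matrix, k, store)
  list(sim = sim, store = store, partition = part)
}
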
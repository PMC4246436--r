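# Block-pair scheduling: enumeration of unordered block pairs and the four
# distribution strategies (full, skip, balanced, combiner-rebalanced).
# Block ids and worker ids are 0-based throughout.

#' Enumerate unordered block pairs
#'
#' Lists every unordered pair of block ids `(i, j)` with `0 <= i <= j <= k-1`
#' in lexicographic order.  These pairs are the units of work when computing a
#' symmetric coefficient matrix block-by-block: the tile for pair `(i, j)`
#' also yields the mirrored tile `(j, i)`, so only `k(k+1)/2` of the `k^2`
#' ordered pairs ever need computing.
#'
#' @param k number of blocks (positive integer).
#' @return Integer matrix with `k(k+1)/2` rows and columns `i`, `j`.
#' @examples
#' enumerate_pairs(3)  # 6 pairs
#' @export
enumerate_pairs <- function(k) {
  k <- check_count(k, "k")
  i <- rep.int(0:(k - 1L), times = k:1L)
  j <- unlist(lapply(0:(k - 1L), function(a) a:(k - 1L)), use.names = FALSE)
  cbind(i = i, j = as.integer(j))
}

new_assignment <- function(k, w, tasks, strategy) {
  a <- (k + 1) / 2
  structure(
    list(k = as.integer(k), w = as.integer(w),
         tasks = tasks,
         a = a, c = as.integer(ceiling(a)), f = as.integer(floor(a)),
         strategy = strategy),
    class = "pair_assignment"
  )
}

#' @export
print.pair_assignment <- function(x, ...) {
  cat(sprintf("<pair_assignment> strategy=%s k=%d workers=%d tasks=%d\n",
              x$strategy, x$k, x$w, nrow(x$tasks)))
  cat(sprintf("  average load a=%.3g  ceiling c=%d  floor f=%d\n", x$a, x$c, x$f))
  loads <- assignment_loads(x)
  cat("  load histogram:", paste(loads, collapse = " "), "\n")
  invisible(x)
}

#' Per-worker task counts of an assignment
#'
#' @param assignment a `pair_assignment`.
#' @return Integer vector of length `w`: task count of workers `0..w-1`.
#' @export
assignment_loads <- function(assignment) {
  stopifnot(inherits(assignment, "pair_assignment"))
  tabulate(assignment$tasks[, "worker"] + 1L, nbins = assignment$w)
}

#' Full (redundant) assignment
#'
#' The naive distribution: every block is shipped to every worker, so worker
#' `r` computes the `k` ordered tiles `(i, r)` for all blocks `i`.  Every
#' off-diagonal coefficient is computed twice (`d_ij` and `d_ji`); total work
#' is `k^2` tiles.  Kept as the baseline the optimised strategies are
#' measured against.
#'
#' @param k number of blocks.
#' @return A `pair_assignment` with ordered tasks (column `i` may exceed `j`).
#' @export
full_assignment <- function(k) {
  k <- check_count(k, "k")
  tasks <- cbind(i = rep.int(0:(k - 1L), times = k),
                 j = rep(0:(k - 1L), each = k),
                 worker = rep(0:(k - 1L), each = k))
  new_assignment(k, k, tasks, "full")
}

#' Triangular skip assignment
#'
#' Redundancy-free but imbalanced: a block is never shipped to a worker with
#' a smaller id, so worker `j` computes exactly the pairs `(i, j)` with
#' `i <= j`.  Each coefficient is computed once, but worker loads grow as
#' `1, 2, ..., k` and the largest worker dominates the wall time.
#'
#' @param k number of blocks.
#' @return A `pair_assignment` covering each unordered pair exactly once.
#' @export
skip_assignment <- function(k) {
  k <- check_count(k, "k")
  pairs <- enumerate_pairs(k)
  tasks <- cbind(pairs, worker = pairs[, "j"])
  new_assignment(k, k, tasks, "skip")
}

#' Balanced circular assignment
#'
#' The load-balancing schedule at the core of the package.  The triangular
#' workload of [skip_assignment()] (loads `1..k`) is redistributed so that
#' every one of the `k` workers carries either `c = ceiling((k+1)/2)` or
#' `f = floor((k+1)/2)` pair tasks, while still covering each unordered pair
#' exactly once.  Geometrically this folds the lower triangle of the pair
#' matrix onto the upper triangle so every row holds `c` or `f` entries.
#'
#' The realisation is circular: worker `r` takes the pairs
#' `{r, (r + d) mod k}` for offsets `d = 0 .. f-1`.  For odd `k` this already
#' covers every circular distance once and all loads equal `(k+1)/2`.  For
#' even `k` the wrap offset `d = k/2` would generate each of its `k/2` pairs
#' twice, so only workers `r < k/2` take it; they carry `c` tasks and the
#' rest carry `f`.
#'
#' @param k number of blocks.
#' @return A `pair_assignment` with strategy `"balanced"`.
#' @examples
#' assignment_loads(balanced_assignment(3))  # 2 2 2
#' assignment_loads(balanced_assignment(4))  # 3 3 2 2
#' @export
balanced_assignment <- function(k) {
  k <- check_count(k, "k")
  f <- (k + 1L) %/% 2L
  rows <- lapply(0:(k - 1L), function(r) {
    d <- 0:(f - 1L)
    if (k %% 2L == 0L && r < k %/% 2L) d <- c(d, k %/% 2L)
    other <- (r + d) %% k
    cbind(i = pmin(r, other), j = pmax(r, other), worker = r)
  })
  tasks <- do.call(rbind, rows)
  new_assignment(k, k, tasks, "balanced")
}

#' Rebalance a pair list onto an arbitrary worker count
#'
#' Combiner-mode scheduling: when the number of available workers `w` differs
#' from the number of blocks `k`, the deterministic pair order is chunked
#' contiguously into `w` near-equal slices (the first `m mod w` workers take
#' `ceiling(m/w)` pairs, the rest `floor(m/w)`), so the load spread is at
#' most 1.  Contiguous chunking is used instead of hashing: hash partitioning
#' cannot guarantee an even mapping onto the available workers, which is the
#' skew this mode exists to avoid.
#'
#' @param pairs integer matrix with columns `i`, `j` (e.g. from
#'   [enumerate_pairs()]); must be duplicate-free.
#' @param w number of workers (positive integer).
#' @return A `pair_assignment` with strategy `"combiner"`.
#' @export
rebalance_to_workers <- function(pairs, w) {
  w <- check_count(w, "w")
  if (!is.matrix(pairs) || nrow(pairs) < 1L ||
      !all(c("i", "j") %in% colnames(pairs)))
    stop("`pairs` must be a nonempty matrix with columns i and j", call. = FALSE)
  if (anyDuplicated(pairs[, c("i", "j"), drop = FALSE]))
    stop("duplicate pair in `pairs`", call. = FALSE)
  m <- nrow(pairs)
  base <- m %/% w
  sizes <- rep.int(base, w)
  extra <- m %% w
  if (extra > 0L) sizes[seq_len(extra)] <- base + 1L
  worker <- rep.int(0:(w - 1L), times = sizes)
  k <- max(pairs[, c("i", "j")]) + 1L
  tasks <- cbind(i = as.integer(pairs[, "i"]), j = as.integer(pairs[, "j"]),
                 worker = worker)
  new_assignment(k, w, tasks, "combiner")
}

#' Validate an assignment against its strategy's guarantees
#'
#' Checks pair coverage (each unordered pair exactly once for the unordered
#' strategies; all `k^2` ordered pairs for the full strategy) and the
#' strategy's load guarantee: loads in `{f, c}` for balanced, spread at most
#' 1 for combiner, the triangular profile `1..k` for skip, uniform `k` for
#' full.
#'
#' @param assignment a `pair_assignment`.
#' @return A list with elements `pass` (logical), `loads` (integer vector),
#'   `missing` and `duplicated` (matrices of offending pairs), `messages`
#'   (character).
#' @export
validate_assignment <- function(assignment) {
  stopifnot(inherits(assignment, "pair_assignment"))
  k <- assignment$k
  tasks <- assignment$tasks
  loads <- assignment_loads(assignment)
  msgs <- character()
  if (assignment$strategy == "full") {
    key <- paste(tasks[, "i"], tasks[, "j"])
    want <- paste(rep.int(0:(k - 1L), k), rep(0:(k - 1L), each = k))
    miss <- setdiff(want, key)
    dup <- unique(key[duplicated(key)])
    ok_load <- all(loads == k)
    if (!ok_load) msgs <- c(msgs, "full strategy loads must all equal k")
  } else {
    key <- paste(pmin(tasks[, "i"], tasks[, "j"]),
                 pmax(tasks[, "i"], tasks[, "j"]))
    pairs <- enumerate_pairs(k)
    want <- paste(pairs[, "i"], pairs[, "j"])
    miss <- setdiff(want, key)
    dup <- unique(key[duplicated(key)])
    ok_load <- switch(assignment$strategy,
      balanced = all(loads %in% c(assignment$f, assignment$c)),
      skip     = identical(loads, 1:k),
      combiner = (max(loads) - min(loads)) <= 1L,
      serial   = TRUE,
      TRUE)
    if (!ok_load)
      msgs <- c(msgs, sprintf("load spread violates the %s guarantee",
                              assignment$strategy))
  }
  if (length(miss)) msgs <- c(msgs, paste("missing pair(s):", paste(miss, collapse = "; ")))
  if (length(dup)) msgs <- c(msgs, paste("duplicated pair(s):", paste(dup, collapse = "; ")))
  to_mat <- function(keys) {
    if (!length(keys)) return(matrix(integer(), 0L, 2L, dimnames = list(NULL, c("i", "j"))))
    parts <- do.call(rbind, strsplit(keys, " ", fixed = TRUE))
    matrix(as.integer(parts), ncol = 2L, dimnames = list(NULL, c("i", "j")))
  }
  list(pass = length(miss) == 0L && length(dup) == 0L && ok_load,
       loads = loads, missing = to_mat(miss), duplicated = to_mat(dup),
       messages = msgs)
}

check_count <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 1 || x != floor(x))
    stop(sprintf("`%s` must be a single integer >= 1", name), call. = FALSE)
  as.integer(x)
}
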
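# Job execution: run an assignment over a block store with a worker pool
# and assemble the tiles into the full symmetric coefficient matrix.
#
# The parallelism contract is share-nothing: each worker is an isolated
# executor that reads its blocks from the store and returns finished tiles.
# A forked process pool satisfies it; so does fully serial execution, and
# both produce bitwise-identical matrices because every tile is computed by
# the same kernel with a fixed internal summation order.

new_corr_matrix <- function(values, metric) {
  structure(values, metric = metric, class = c("corr_matrix", class(values)))
}

unclass_corr <- function(cm) {
  attr(cm, "metric") <- NULL
  unclass(cm)
}

#' @export
print.corr_matrix <- function(x, ...) {
  cat(sprintf("<corr_matrix> metric=%s, %d x %d subjects\n",
              attr(x, "metric"), nrow(x), ncol(x)))
  st <- attr(x, "stats")
  if (!is.null(st))
    cat(sprintf("  strategy=%s workers=%d tiles_computed=%d elapsed=%.2fs\n",
                st$strategy, st$workers, st$tiles_computed, st$elapsed))
  print(utils::head(unclass_corr(x)[, seq_len(min(6L, ncol(x))), drop = FALSE],
                    6L), ...)
  invisible(x)
}

#' Metric of a coefficient matrix
#' @param cm a `corr_matrix`.
#' @return The metric name the matrix was computed with.
#' @export
corr_metric <- function(cm) attr(cm, "metric")

strategy_names <- c("serial", "full", "skip", "balanced", "combiner")

build_assignment <- function(strategy, k, workers) {
  switch(strategy,
    serial   = {
      pairs <- enumerate_pairs(k)
      asg <- new_assignment(k, 1L, cbind(pairs, worker = 0L), "serial")
      asg
    },
    full     = full_assignment(k),
    skip     = skip_assignment(k),
    balanced = balanced_assignment(k),
    combiner = rebalance_to_workers(enumerate_pairs(k), workers))
}

#' Compute the full coefficient matrix from a block store
#'
#' Executes one of the five execution strategies over the block store and
#' returns the assembled `n x n` symmetric matrix.  All strategies produce
#' identical matrices; they differ in how the pair tasks are distributed:
#'
#' * `serial` — all pairs on one worker (the reference).
#' * `full` — the redundant baseline; `k^2` ordered tiles across `k`
#'   workers, duplicates reconciled before assembly.
#' * `skip` — redundancy-free triangular distribution, loads `1..k`.
#' * `balanced` — the balanced circular schedule, every worker carries
#'   `ceiling((k+1)/2)` or `floor((k+1)/2)` tasks.
#' * `combiner` — map-side computation: the pair list is rebalanced onto an
#'   arbitrary `workers` count and each worker reads both blocks of its
#'   pairs directly from the store.
#'
#' @param store block store directory from [split_blocks()].
#' @param metric `"euclidean"`, `"pearson"`, `"spearman"` or `"kendall"`.
#' @param strategy execution strategy (see above).
#' @param workers worker count; defaults to 1 for `serial`, `k` otherwise.
#'   Only `combiner` may use `workers != k`.
#' @param parallel run workers as forked processes (unix); `FALSE` executes
#'   the same per-worker task lists sequentially.
#' @param log_file optional path for a tab-separated task log.
#' @return A `corr_matrix` with attributes `stats` (strategy, workers,
#'   tiles_computed, elapsed seconds) and `task_log` (one row per tile:
#'   worker, i, j, tile dimensions, seconds).
#' @export
run_job <- function(store, metric = c("euclidean", "pearson", "spearman", "kendall"),
                    strategy = c("balanced", "serial", "full", "skip", "combiner"),
                    workers = NULL, parallel = FALSE, log_file = NULL) {
  metric <- match.arg(metric)
  strategy <- match.arg(strategy)
  part <- read_partition(store)
  k <- part$k
  if (is.null(workers)) workers <- if (strategy == "serial") 1L else k
  workers <- check_count(workers, "workers")
  if (strategy %in% c("full", "skip", "balanced") && workers != k)
    stop(sprintf("strategy '%s' binds workers to blocks (workers = k = %d); use strategy 'combiner' for workers != k",
                 strategy, k), call. = FALSE)
  if (strategy == "serial" && workers != 1L)
    stop("strategy 'serial' uses a single worker", call. = FALSE)
  asg <- build_assignment(strategy, k, workers)

  t0 <- proc.time()[["elapsed"]]
  groups <- split(seq_len(nrow(asg$tasks)), asg$tasks[, "worker"])
  run_group <- function(rows) {
    cache <- new.env(parent = emptyenv())
    get_block <- function(id) {
      key <- as.character(id)
      if (is.null(cache[[key]])) cache[[key]] <- read_block(store, id)
      cache[[key]]
    }
    lapply(rows, function(r) {
      task <- asg$tasks[r, ]
      tt0 <- proc.time()[["elapsed"]]
      res <- tryCatch(
        block_correlate(get_block(task[["i"]]), get_block(task[["j"]]), metric),
        error = function(e) e)
      if (inherits(res, "error"))
        stop(sprintf("worker %d failed on pair task (%d, %d): %s",
                     task[["worker"]], task[["i"]], task[["j"]],
                     conditionMessage(res)), call. = FALSE)
      res$i <- as.integer(task[["i"]])  # keep the ordered task ids (full strategy)
      res$j <- as.integer(task[["j"]])
      res$worker <- as.integer(task[["worker"]])
      res$seconds <- proc.time()[["elapsed"]] - tt0
      res
    })
  }
  use_fork <- isTRUE(parallel) && length(groups) > 1L &&
    .Platform$OS.type == "unix"
  results <- if (use_fork) {
    out <- parallel::mclapply(groups, run_group, mc.cores = length(groups),
                              mc.preschedule = FALSE)
    err <- vapply(out, inherits, logical(1L), what = "try-error")
    if (any(err)) stop(attr(out[[which(err)[1L]]], "condition"))
    out
  } else {
    lapply(groups, run_group)
  }
  results <- unlist(results, recursive = FALSE, use.names = FALSE)
  tiles_computed <- length(results)

  task_log <- data.frame(
    worker = vapply(results, `[[`, integer(1L), "worker"),
    i = vapply(results, `[[`, integer(1L), "i"),
    j = vapply(results, `[[`, integer(1L), "j"),
    rows = vapply(results, function(r) nrow(r$tile), integer(1L)),
    cols = vapply(results, function(r) ncol(r$tile), integer(1L)),
    seconds = vapply(results, `[[`, numeric(1L), "seconds"))

  if (strategy == "full") {
    # each off-diagonal pair was computed twice (ordered (i, j) and (j, i));
    # keep the i <= j copy so assembly sees each unordered pair once
    results <- results[vapply(results, function(r) r$i <= r$j, logical(1L))]
  }

  cm <- assemble(results, part, metric = metric)
  elapsed <- proc.time()[["elapsed"]] - t0
  attr(cm, "stats") <- list(strategy = strategy, workers = workers,
                            tiles_computed = tiles_computed, elapsed = elapsed)
  attr(cm, "task_log") <- task_log
  if (!is.null(log_file)) write_task_log(task_log, log_file)
  cm
}

write_task_log <- function(task_log, path) {
  totals <- data.frame(worker = NA_integer_, i = NA_integer_, j = NA_integer_,
                       rows = sum(task_log$rows), cols = sum(task_log$cols),
                       seconds = sum(task_log$seconds))
  out <- rbind(task_log, totals)
  out$record <- c(rep.int("task", nrow(task_log)), "totals")
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Assemble block tiles into the full symmetric matrix
#'
#' Places tile `(i, j)` at the rows of block `i` by the columns of block `j`
#' and mirrors it to `(j, i)`; no cell is written twice except by mirroring,
#' so the result is symmetric to the last bit.  The tile set must cover
#' every unordered block pair exactly once.
#'
#' @param results list of `block_result` tiles (one per unordered pair).
#' @param partition the `block_partition` of the source matrix.
#' @param subject_ids optional subject ids; defaults to the ids carried on
#'   the tiles.
#' @param metric metric name recorded on the output.
#' @return A `corr_matrix` (`n x n`, symmetric).
#' @export
assemble <- function(results, partition, subject_ids = NULL, metric = NULL) {
  stopifnot(inherits(partition, "block_partition"))
  k <- partition$k
  n <- partition$n
  got <- vapply(results, function(r) paste(min(r$i, r$j), max(r$i, r$j)),
                character(1L))
  pairs <- enumerate_pairs(k)
  want <- paste(pairs[, "i"], pairs[, "j"])
  missing <- setdiff(want, got)
  if (length(missing))
    stop(sprintf("assembly incomplete, missing pair tile(s): %s",
                 paste(sub(" ", ",", sprintf("(%s)", missing)), collapse = " ")),
         call. = FALSE)
  if (anyDuplicated(got))
    stop(sprintf("duplicate pair tile(s): %s",
                 paste(sub(" ", ",", sprintf("(%s)", unique(got[duplicated(got)]))),
                       collapse = " ")), call. = FALSE)
  if (is.null(metric)) metric <- results[[1L]]$metric
  values <- matrix(NA_real_, n, n)
  ids <- character(n)
  for (r in results) {
    ri <- block_rows(partition, min(r$i, r$j))
    rj <- block_rows(partition, max(r$i, r$j))
    tile <- if (r$i <= r$j) r$tile else t(r$tile)
    values[ri, rj] <- tile
    values[rj, ri] <- t(tile)
    ids[ri] <- rownames(tile)
    ids[rj] <- colnames(tile)
  }
  dimnames(values) <- list(ids, ids)
  new_corr_matrix(values, metric)
}
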
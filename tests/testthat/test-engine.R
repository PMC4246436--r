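# Job execution, assembly and work accounting.

test_that("every strategy reproduces the serial reference bitwise", {
  ctx <- make_store(n = 21, p = 60, k = 5, seed = 21)
  for (metric in c("euclidean", "pearson", "spearman", "kendall")) {
    ref <- run_job(ctx$store, metric, "serial")
    for (strategy in c("skip", "balanced", "full")) {
      cm <- run_job(ctx$store, metric, strategy)
      expect_identical(bare(cm), bare(ref),
                       info = paste(metric, strategy))
    }
    for (w in c(1, 3, 5, 8)) {
      cm <- run_job(ctx$store, metric, "combiner", workers = w)
      expect_identical(bare(cm), bare(ref), info = paste(metric, "combiner", w))
    }
  }
})

test_that("forked execution matches in-process execution bitwise", {
  ctx <- make_store(n = 12, p = 40, k = 4, seed = 22)
  a <- run_job(ctx$store, "pearson", "balanced", parallel = FALSE)
  b <- run_job(ctx$store, "pearson", "balanced", parallel = TRUE)
  expect_identical(bare(a), bare(b))
})

test_that("serial run on a single block is the all-pairs reference itself", {
  sim <- simulate_expression(n = 8, p = 30, g = 2, seed = 23)
  store <- withr::local_tempdir()
  split_blocks(sim$matrix, 1, store)
  cm <- run_job(store, "euclidean", "serial")
  expect_equal(bare(cm), as.matrix(dist(sim$matrix)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("assembled matrices agree with closed-form recomputation", {
  ctx <- make_store(n = 15, p = 50, k = 4, seed = 24)
  m <- ctx$sim$matrix
  expect_equal(bare(run_job(ctx$store, "euclidean", "balanced")),
               unname(as.matrix(dist(m))), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(bare(run_job(ctx$store, "pearson", "balanced")),
               unname(cor(t(m))), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(bare(run_job(ctx$store, "spearman", "balanced")),
               unname(cor(t(m), method = "spearman")), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(bare(run_job(ctx$store, "kendall", "balanced")),
               unname(cor(t(m), method = "kendall")), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("work accounting shows the redundancy halving", {
  ctx <- make_store(n = 18, p = 20, k = 6, seed = 25)
  full <- attr(run_job(ctx$store, "euclidean", "full"), "stats")$tiles_computed
  bal <- attr(run_job(ctx$store, "euclidean", "balanced"), "stats")$tiles_computed
  skip <- attr(run_job(ctx$store, "euclidean", "skip"), "stats")$tiles_computed
  expect_identical(full, 36L)
  expect_identical(bal, 21L)
  expect_identical(skip, 21L)
})

test_that("assembly errors name missing and duplicated tiles", {
  ctx <- make_store(n = 9, p = 25, k = 3, seed = 26)
  blocks <- lapply(0:2, read_block, store = ctx$store)
  pairs <- enumerate_pairs(3)
  tiles <- lapply(seq_len(nrow(pairs)), function(r)
    block_correlate(blocks[[pairs[r, "i"] + 1]], blocks[[pairs[r, "j"] + 1]],
                    "pearson"))
  full <- assemble(tiles, ctx$partition)
  expect_identical(bare(full), bare(run_job(ctx$store, "pearson", "serial")))
  expect_identical(t(bare(full)), bare(full))

  withheld <- tiles[-4L]  # drop pair (1, 1)... position 4 is (1,1)
  expect_error(assemble(withheld, ctx$partition), "missing.*1,1")
  expect_error(assemble(c(tiles, tiles[2L]), ctx$partition), "duplicate")
})

test_that("worker failure is reported with the offending pair task", {
  ctx <- make_store(n = 8, p = 20, k = 2, seed = 27)
  # corrupt one block after the manifest is written
  m <- ctx$sim$matrix
  write_expression(m[5:8, , drop = FALSE] * 2, file.path(ctx$store, "block_1.csv"))
  expect_error(run_job(ctx$store, "euclidean", "serial"), "pair task \\(0, 1\\)|pair task \\(1, 1\\)")
})

test_that("task logs carry one record per tile plus totals", {
  ctx <- make_store(n = 12, p = 30, k = 3, seed = 28)
  log_file <- withr::local_tempfile(fileext = ".tsv")
  cm <- run_job(ctx$store, "euclidean", "balanced", log_file = log_file)
  log <- attr(cm, "task_log")
  expect_identical(nrow(log), 6L)   # k(k+1)/2 tasks for k = 3
  expect_setequal(paste(log$i, log$j),
                  paste(enumerate_pairs(3)[, "i"], enumerate_pairs(3)[, "j"]))
  loads <- assignment_loads(balanced_assignment(3))
  expect_identical(nrow(log), sum(loads))
  on_disk <- data.table::fread(log_file)
  expect_identical(nrow(on_disk), 7L)
  expect_identical(on_disk$record[7], "totals")

  # deterministic order for a serial run
  s1 <- attr(run_job(ctx$store, "euclidean", "serial"), "task_log")
  s2 <- attr(run_job(ctx$store, "euclidean", "serial"), "task_log")
  expect_identical(s1[, c("worker", "i", "j")], s2[, c("worker", "i", "j")])
})

test_that("repeated runs write byte-identical output files", {
  ctx <- make_store(n = 10, p = 30, k = 3, seed = 29)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_matrix(run_job(ctx$store, "spearman", "balanced"), f1)
  write_matrix(run_job(ctx$store, "spearman", "balanced"), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("worker counts are bound to the strategy contract", {
  ctx <- make_store(n = 6, p = 20, k = 3, seed = 30)
  expect_error(run_job(ctx$store, "euclidean", "balanced", workers = 2),
               "workers = k")
  expect_error(run_job(ctx$store, "euclidean", "serial", workers = 2), "single")
})
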
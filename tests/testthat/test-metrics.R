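# Coefficient kernels: scalar pairs, midranks, Kendall merge-sort counting,
# and whole-tile computation.

test_that("Euclidean distance matches the element-by-element oracle", {
  expect_identical(euclidean_pair(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(euclidean_pair(c(0, 0), c(3, 4)), 5)
  set.seed(31)
  for (r in 1:20) {
    x <- rnorm(97); y <- rnorm(97)
    expect_equal(euclidean_pair(x, y), euclidean_loop_oracle(x, y),
                 tolerance = 1e-12)
  }
  expect_error(euclidean_pair(1:3, 1:4), "mismatch")
})

test_that("Euclidean distance satisfies the triangle inequality", {
  set.seed(32)
  for (r in 1:50) {
    x <- rnorm(40); y <- rnorm(40); z <- rnorm(40)
    expect_lte(euclidean_pair(x, z),
               euclidean_pair(x, y) + euclidean_pair(y, z) + 1e-12)
  }
})

test_that("Pearson correlation matches its definitional formula", {
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)
  expect_equal(pearson_pair(x, y), pearson_loop_oracle(x, y), tolerance = 1e-15)
  expect_equal(pearson_pair(x, x), 1)
  expect_equal(pearson_pair(x, -x), -1)
  set.seed(33)
  for (r in 1:30) {
    a <- rnorm(61); b <- rnorm(61)
    expect_equal(pearson_pair(a, b), pearson_loop_oracle(a, b), tolerance = 1e-13)
    expect_true(abs(pearson_pair(a, b)) <= 1 + 1e-15)
  }
  expect_warning(res <- pearson_pair(rep(2, 5), 1:5), "zero-variance")
  expect_true(is.nan(res))
})

test_that("Pearson is invariant to positive affine rescaling", {
  set.seed(34)
  for (r in 1:25) {
    x <- rnorm(50); y <- rnorm(50)
    a <- runif(1, 0.1, 10); b <- rnorm(1)
    expect_equal(pearson_pair(a * x + b, y), pearson_pair(x, y), tolerance = 1e-10)
    expect_equal(pearson_pair(x, a * y + b), pearson_pair(x, y), tolerance = 1e-10)
  }
})

test_that("midranks average tied positions and sum to p(p+1)/2", {
  expect_identical(midrank(c(10, 20, 30)), c(1, 2, 3))
  expect_identical(midrank(c(1, 2, 2, 4)), c(1, 2.5, 2.5, 4))
  expect_identical(midrank(rep(7, 4)), rep(2.5, 4))
  set.seed(35)
  for (r in 1:30) {
    x <- sample(1:6, 40, replace = TRUE)
    expect_identical(midrank(x), midrank_sort_oracle(x))
    expect_equal(sum(midrank(x)), 40 * 41 / 2)
  }
})

test_that("Spearman is Pearson on midranks and honours monotone transforms", {
  x <- sort(rnorm(20))
  expect_equal(spearman_pair(x, exp(x)), 1)
  expect_equal(spearman_pair(x, rev(seq_along(x))), -1)
  set.seed(36)
  for (r in 1:30) {
    a <- sample(1:8, 35, replace = TRUE); b <- sample(1:8, 35, replace = TRUE)
    expect_equal(spearman_pair(a, b),
                 pearson_loop_oracle(midrank_sort_oracle(a), midrank_sort_oracle(b)),
                 tolerance = 1e-13)
    # invariance under a strictly increasing nonlinear transform
    expect_equal(spearman_pair(exp(a / 2), b), spearman_pair(a, b), tolerance = 1e-13)
  }
})

test_that("merge-sort Kendall tau-b equals brute-force enumeration", {
  expect_equal(kendall_pair(c(1, 2, 3, 4), c(2, 1, 4, 3)), 1 / 3, tolerance = 1e-15)
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(kendall_pair(x, x), 1)
  expect_equal(kendall_bruteforce(c(1, 2), c(2, 1)), -1)
  expect_warning(nan <- kendall_bruteforce(c(1, 1), c(1, 2)), "all-tied")
  expect_true(is.nan(nan))
  expect_warning(nan2 <- kendall_pair(c(1, 1), c(1, 2)), "all-tied")
  expect_true(is.nan(nan2))

  set.seed(37)
  for (r in 1:120) {
    p <- sample(5:60, 1)
    x <- rnorm(p); y <- rnorm(p)
    expect_equal(kendall_pair(x, y), kendall_bruteforce(x, y), tolerance = 1e-12)
  }
  # heavy ties through the fixture generator
  for (s in 1:100) {
    fx <- tie_fixture(p = sample(5:40, 1), levels = sample(2:5, 1), seed = s)
    expect_equal(kendall_pair(fx$x, fx$y), kendall_bruteforce(fx$x, fx$y),
                 tolerance = 1e-12)
  }
})

test_that("rank correlations are invariant under monotone transforms", {
  set.seed(38)
  for (r in 1:20) {
    x <- rnorm(30); y <- rnorm(30)
    mono <- function(v) v^3 + 2 * v   # strictly increasing
    expect_equal(kendall_pair(mono(x), y), kendall_pair(x, y), tolerance = 1e-12)
    expect_equal(spearman_pair(mono(x), y), spearman_pair(x, y), tolerance = 1e-12)
  }
})

test_that("block tiles equal per-pair kernel calls", {
  set.seed(39)
  A <- matrix(rnorm(2 * 30), 2, dimnames = list(c("a1", "a2"), NULL))
  B <- matrix(rnorm(2 * 30), 2, dimnames = list(c("b1", "b2"), NULL))
  tile <- block_correlate(A, B, "euclidean")$tile
  for (r in 1:2) for (s in 1:2)
    expect_equal(tile[r, s], euclidean_pair(A[r, ], B[s, ]), tolerance = 1e-12)

  for (metric in c("euclidean", "pearson", "spearman", "kendall")) {
    A <- matrix(rnorm(4 * 25), 4)
    B <- matrix(rnorm(3 * 25), 3)
    t_ab <- block_correlate(A, B, metric)$tile
    t_ba <- block_correlate(B, A, metric)$tile
    expect_equal(t_ab, t(t_ba), tolerance = 1e-12)
    pairfun <- switch(metric, euclidean = euclidean_pair, pearson = pearson_pair,
                      spearman = spearman_pair, kendall = kendall_pair)
    for (r in 1:4) for (s in 1:3)
      expect_equal(t_ab[r, s], pairfun(A[r, ], B[s, ]), tolerance = 1e-10)
  }
  expect_error(block_correlate(matrix(1, 2, 3), matrix(1, 2, 4), "euclidean"),
               "mismatch")
})

test_that("diagonal tiles are symmetric with an analytic self-diagonal", {
  sim <- simulate_expression(n = 3, p = 40, g = 1, seed = 40)
  store <- withr::local_tempdir()
  split_blocks(sim$matrix, 1, store)
  blk <- read_block(store, 0)
  for (metric in c("pearson", "spearman", "kendall")) {
    tile <- block_correlate(blk, blk, metric)$tile
    expect_identical(tile, t(tile))   # mirrored, not recomputed
    expect_identical(unname(diag(tile)), rep(1, 3))
  }
  te <- block_correlate(blk, blk, "euclidean")$tile
  expect_identical(te, t(te))
  expect_identical(unname(diag(te)), rep(0, 3))
})
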
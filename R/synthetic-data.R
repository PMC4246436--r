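# Seeded synthetic expression matrices with planted cluster structure.
#
# Subjects fall round-robin into g clusters; each cluster has a mean vector
# whose entries are drawn independently per probeset (centred normal scaled
# by `separation`), so no single probeset dominates any metric and the rank
# metrics are exercised as much as Euclidean distance.  Independent
# Gaussian noise is added per cell, and an optional fraction of cells is
# rounded to the unit grid to induce the tied values Kendall's tau-b tie
# terms need.

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

#' Simulate an expression matrix with planted clusters
#'
#' Deterministic per seed: the generator state is Mersenne-Twister with
#' inversion normals, seeded from `seed` and restored afterwards, so the
#' same spec always yields the same matrix on any platform.
#'
#' Defaults give the desk-scale study condition used throughout the test
#' suite: 60 subjects, 500 probesets, 3 well-separated clusters.
#'
#' @param n subjects (`n >= g`).
#' @param p probesets (`p >= 2`).
#' @param g planted clusters.
#' @param separation between-cluster spread: cluster-mean entries are drawn
#'   from `N(0, separation^2)` per probeset (intensity units).
#' @param noise_sd within-cluster noise standard deviation (> 0).
#' @param tie_fraction fraction of cells rounded to the unit grid to induce
#'   ties, in `[0, 1]`.
#' @param seed integer seed.
#' @return List with `matrix` (an expression matrix, subjects as rows) and
#'   `labels` (named integer vector of planted cluster labels `1..g`,
#'   assigned round-robin).
#' @examples
#' sim <- simulate_expression(n = 12, p = 20, g = 3, seed = 1)
#' table(sim$labels)
#' @export
simulate_expression <- function(n = 60, p = 500, g = 3, separation = 3,
                                noise_sd = 1, tie_fraction = 0, seed = 1) {
  n <- check_count(n, "n")
  p <- check_count(p, "p")
  g <- check_count(g, "g")
  if (p < 2L) stop("`p` must be >= 2", call. = FALSE)
  if (n < g) stop("`n` must be >= `g`", call. = FALSE)
  if (!is.numeric(separation) || length(separation) != 1L || separation < 0)
    stop("`separation` must be a nonnegative number", call. = FALSE)
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd <= 0)
    stop("`noise_sd` must be a positive number", call. = FALSE)
  if (!is.numeric(tie_fraction) || length(tie_fraction) != 1L ||
      tie_fraction < 0 || tie_fraction > 1)
    stop("`tie_fraction` must be in [0, 1]", call. = FALSE)

  labels <- rep_len(seq_len(g), n)
  subject_ids <- sprintf("S%04d", seq_len(n))
  names(labels) <- subject_ids
  values <- with_local_seed(seed, {
    centers <- matrix(stats::rnorm(g * p, mean = 0, sd = separation), g, p)
    v <- centers[labels, , drop = FALSE] +
      matrix(stats::rnorm(n * p, mean = 0, sd = noise_sd), n, p)
    if (tie_fraction > 0) {
      n_tie <- floor(tie_fraction * length(v))
      if (n_tie > 0) {
        idx <- sample.int(length(v), n_tie)
        v[idx] <- round(v[idx])
      }
    }
    v
  })
  dimnames(values) <- list(subject_ids, sprintf("PS%06d", seq_len(p)))
  list(matrix = values, labels = labels)
}

#' Heavy-tie fixture pair for rank metrics
#'
#' Draws two independent vectors whose values are sampled with replacement
#' from `levels` distinct values, so tie groups are guaranteed whenever
#' `levels < p` (and everything is tied when `levels = 1`, the undefined
#' tau-b path).
#'
#' @param p vector length (`p >= 2`).
#' @param levels number of distinct values (`>= 1`).
#' @param seed integer seed.
#' @return List with numeric vectors `x` and `y`.
#' @export
tie_fixture <- function(p, levels, seed = 1) {
  p <- check_count(p, "p")
  levels <- check_count(levels, "levels")
  if (p < 2L) stop("`p` must be >= 2", call. = FALSE)
  with_local_seed(seed, {
    list(x = as.numeric(sample.int(levels, p, replace = TRUE)),
         y = as.numeric(sample.int(levels, p, replace = TRUE)))
  })
}
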
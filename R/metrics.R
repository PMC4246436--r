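# Correlation/distance kernels.  Scalar pair kernels define the semantics;
# block_correlate() computes whole coefficient tiles with per-block
# precomputation (one pass for means/norms, not one per pair).

#' Euclidean distance between two subject vectors
#'
#' @param x,y numeric vectors of equal length (probeset intensities).
#' @return `sqrt(sum((x - y)^2))`, a nonnegative scalar.
#' @export
euclidean_pair <- function(x, y) {
  check_same_length(x, y)
  sqrt(sum((x - y)^2))
}

#' Pearson product-moment correlation between two subject vectors
#'
#' Two-pass definitional formula: centred cross-product over the product of
#' centred norms.  A zero-variance (constant) vector yields `NaN` with a
#' warning rather than an error, so batch jobs over many subjects survive
#' degenerate rows.
#'
#' @param x,y numeric vectors of equal length (at least 2).
#' @return Correlation in `[-1, 1]`, or `NaN` for constant input.
#' @export
pearson_pair <- function(x, y) {
  check_same_length(x, y)
  if (length(x) < 2L) stop("correlation needs vectors of length >= 2", call. = FALSE)
  xc <- x - mean(x)
  yc <- y - mean(y)
  den <- sqrt(sum(xc^2)) * sqrt(sum(yc^2))
  if (is.na(den)) return(NA_real_)
  if (den == 0) {
    warning("zero-variance vector: correlation undefined, returning NaN", call. = FALSE)
    return(NaN)
  }
  sum(xc * yc) / den
}

#' Midranks of a vector
#'
#' Ranks `1..p` with every group of tied values receiving the mean of the
#' rank positions it spans, so the ranks always sum to `p(p+1)/2`.
#'
#' @param x numeric vector.
#' @return Numeric vector of midranks.
#' @examples
#' midrank(c(1, 2, 2, 4))  # 1 2.5 2.5 4
#' @export
midrank <- function(x) {
  if (length(x) < 1L) stop("`x` must be nonempty", call. = FALSE)
  rank(x, ties.method = "average", na.last = "keep")
}

#' Spearman rank correlation between two subject vectors
#'
#' Pearson correlation of the midranks, the tie convention under which a
#' perfect monotone relationship gives exactly +1 or -1.
#'
#' @inheritParams pearson_pair
#' @return Correlation in `[-1, 1]`, or `NaN` for constant input.
#' @export
spearman_pair <- function(x, y) {
  check_same_length(x, y)
  pearson_pair(midrank(x), midrank(y))
}

#' Kendall rank correlation (tau-b) by merge-sort counting
#'
#' Computes tau-b in `O(p log p)`: after sorting by `(x, y)`, the number of
#' discordant pairs equals the number of inversions removed when
#' merge-sorting `y`, counted with a divide-and-conquer pass.  Tie
#' corrections enter through
#' `tau_b = (C - D) / sqrt((n0 - n1)(n0 - n2))` with `n0 = p(p-1)/2` and
#' `n1`, `n2` the within-tie-group pair counts of `x` and `y`;
#' `C - D = n0 - n1 - n2 + n3 - 2 D` where `n3` counts pairs tied in both.
#'
#' @inheritParams pearson_pair
#' @return tau-b in `[-1, 1]`, or `NaN` when either vector is entirely tied.
#' @examples
#' kendall_pair(c(1, 2, 3, 4), c(2, 1, 4, 3))  # 1/3
#' @export
kendall_pair <- function(x, y) {
  check_same_length(x, y)
  p <- length(x)
  if (p < 2L) stop("correlation needs vectors of length >= 2", call. = FALSE)
  if (anyNA(x) || anyNA(y)) return(NA_real_)
  ord <- order(x, y)
  xs <- x[ord]
  ys <- y[ord]
  n0 <- p * (p - 1) / 2
  tie_pairs <- function(lengths) sum(lengths * (lengths - 1) / 2)
  n1 <- tie_pairs(rle(xs)$lengths)
  n2 <- tie_pairs(rle(sort(ys))$lengths)
  joint <- c(TRUE, diff(xs) != 0 | diff(ys) != 0)  # run starts of (x, y) ties
  n3 <- tie_pairs(diff(c(which(joint), p + 1L)))
  den <- sqrt((n0 - n1) * (n0 - n2))
  if (den == 0) {
    warning("all-tied vector: Kendall tau undefined, returning NaN", call. = FALSE)
    return(NaN)
  }
  disc <- count_inversions(ys)$inversions
  (n0 - n1 - n2 + n3 - 2 * disc) / den
}

# Divide-and-conquer inversion count (pairs v[a] > v[b] with a < b).
# The cross-count per merge is vectorised with findInterval on the sorted
# left half, so the recursion does O(log p) vectorised passes.
count_inversions <- function(v) {
  n <- length(v)
  if (n < 2L) return(list(inversions = 0, sorted = v))
  mid <- n %/% 2L
  left <- count_inversions(v[seq_len(mid)])
  right <- count_inversions(v[(mid + 1L):n])
  # left elements strictly greater than each right element
  cross <- sum(mid - findInterval(right$sorted, left$sorted))
  list(inversions = left$inversions + right$inversions + cross,
       sorted = sort(c(left$sorted, right$sorted), method = "radix"))
}

#' Kendall tau-b by explicit pair enumeration
#'
#' `O(p^2)` reference implementation that scores every one of the
#' `p(p-1)/2` index pairs directly.  It exists as an independent oracle for
#' [kendall_pair()]; the two must agree to machine precision on any input.
#'
#' @inheritParams pearson_pair
#' @return tau-b in `[-1, 1]`, or `NaN` when either vector is entirely tied.
#' @export
kendall_bruteforce <- function(x, y) {
  check_same_length(x, y)
  p <- length(x)
  if (p < 2L) stop("correlation needs vectors of length >= 2", call. = FALSE)
  if (anyNA(x) || anyNA(y)) return(NA_real_)
  idx <- which(upper.tri(diag(p)), arr.ind = TRUE)
  dx <- sign(x[idx[, 2L]] - x[idx[, 1L]])
  dy <- sign(y[idx[, 2L]] - y[idx[, 1L]])
  n0 <- p * (p - 1) / 2
  n1 <- sum(dx == 0)
  n2 <- sum(dy == 0)
  den <- sqrt((n0 - n1) * (n0 - n2))
  if (den == 0) {
    warning("all-tied vector: Kendall tau undefined, returning NaN", call. = FALSE)
    return(NaN)
  }
  sum(dx * dy) / den
}

metric_names <- c("euclidean", "pearson", "spearman", "kendall")

# -- tile kernels -----------------------------------------------------------
# A, B: m_a x p and m_b x p matrices of subject rows.

tile_euclidean <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

tile_pearson <- function(A, B) {
  Ac <- A - rowMeans(A)
  Bc <- B - rowMeans(B)
  const_a <- apply(A, 1L, function(r) !anyNA(r) && max(r) == min(r))
  const_b <- apply(B, 1L, function(r) !anyNA(r) && max(r) == min(r))
  if (any(const_a) || any(const_b))
    warning("zero-variance subject vector(s): correlations set to NaN", call. = FALSE)
  Ac[const_a, ] <- 0
  Bc[const_b, ] <- 0
  na <- sqrt(rowSums(Ac^2))
  nb <- sqrt(rowSums(Bc^2))
  na[const_a] <- 0
  nb[const_b] <- 0
  tcrossprod(Ac, Bc) / outer(na, nb)  # 0/0 -> NaN for constant rows
}

rank_rows <- function(A) {
  ranked <- t(apply(A, 1L, rank, ties.method = "average", na.last = "keep"))
  dimnames(ranked) <- dimnames(A)
  ranked
}

tile_spearman <- function(A, B) {
  tile_pearson(rank_rows(A), rank_rows(B))
}

tile_kendall <- function(A, B, symmetric = FALSE) {
  ma <- nrow(A)
  mb <- nrow(B)
  tile <- matrix(NA_real_, ma, mb)
  for (r in seq_len(ma)) {
    s0 <- if (symmetric) r else 1L
    for (s in seq(from = s0, length.out = mb - s0 + 1L)) {
      tile[r, s] <- kendall_pair(A[r, ], B[s, ])
    }
  }
  tile
}

#' Coefficient tile between two blocks
#'
#' Computes the `m_a x m_b` matrix of pairwise coefficients between the
#' subjects of two blocks.  For a diagonal task (both arguments are the same
#' block, i.e. equal `block_id`) only the upper triangle is computed; it is
#' mirrored to the lower triangle and the self-diagonal is filled
#' analytically (0 for Euclidean, 1 for the correlation metrics on
#' non-constant subjects, `NaN` on constant ones).
#'
#' Pearson and Spearman tiles use one pass of per-subject means/norms per
#' block rather than per pair, so large tiles reduce to a dense
#' cross-product.
#'
#' @param a,b blocks from [read_block()] / [split_blocks()], or plain numeric
#'   matrices with subjects as rows.
#' @param metric one of `"euclidean"`, `"pearson"`, `"spearman"`,
#'   `"kendall"`.
#' @return A `block_result`: list with `i`, `j` (block ids, `NA` for plain
#'   matrices), `metric` and the numeric `tile`.
#' @export
block_correlate <- function(a, b, metric = c("euclidean", "pearson", "spearman", "kendall")) {
  metric <- match.arg(metric)
  A <- block_values(a)
  B <- block_values(b)
  if (ncol(A) != ncol(B))
    stop(sprintf("probeset dimension mismatch: %d vs %d", ncol(A), ncol(B)),
         call. = FALSE)
  ia <- block_id_of(a)
  ib <- block_id_of(b)
  diagonal <- !is.na(ia) && !is.na(ib) && ia == ib
  tile <- switch(metric,
    euclidean = tile_euclidean(A, B),
    pearson   = tile_pearson(A, B),
    spearman  = tile_spearman(A, B),
    kendall   = tile_kendall(A, B, symmetric = diagonal))
  if (diagonal) {
    tile[lower.tri(tile)] <- t(tile)[lower.tri(tile)]
    diag(tile) <- self_coefficient(A, metric)
  }
  rownames(tile) <- block_subjects(a)
  colnames(tile) <- block_subjects(b)
  structure(list(i = ia, j = ib, metric = metric, tile = tile),
            class = "block_result")
}

self_coefficient <- function(A, metric) {
  if (metric == "euclidean") return(rep.int(0, nrow(A)))
  vapply(seq_len(nrow(A)), function(r) {
    row <- A[r, ]
    if (anyNA(row)) NA_real_ else if (max(row) == min(row)) NaN else 1
  }, numeric(1L))
}

block_values <- function(b) {
  if (inherits(b, "expr_block")) b$values
  else if (is.matrix(b) && is.numeric(b)) b
  else stop("expected an expr_block or a numeric matrix", call. = FALSE)
}

block_id_of <- function(b) if (inherits(b, "expr_block")) b$block_id else NA_integer_

block_subjects <- function(b) {
  if (inherits(b, "expr_block")) b$subject_ids else rownames(block_values(b))
}

check_same_length <- function(x, y) {
  if (length(x) != length(y))
    stop(sprintf("vector length mismatch: %d vs %d", length(x), length(y)),
         call. = FALSE)
  invisible(TRUE)
}
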
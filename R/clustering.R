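# Downstream stratification: hierarchical clustering of subjects from the
# assembled coefficient matrix.  The agglomeration itself is delegated to
# stats::hclust(); this module owns the correlation-to-distance transform,
# input validation, tree cutting and Newick export.

#' Convert a coefficient matrix to a distance matrix
#'
#' Euclidean matrices pass through unchanged; correlation matrices map
#' through `d = 1 - r`, the simplest monotone-decreasing transform, giving
#' distances in `[0, 2]` (identical profiles at 0, perfectly anticorrelated
#' at 2).  Matrices containing `NaN` (e.g. from zero-variance subjects) are
#' rejected: reload in strict mode or drop the offending subjects first.
#'
#' @param cm a `corr_matrix`, or a plain symmetric matrix with `metric`.
#' @param metric metric override for plain matrices.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
to_distance <- function(cm, metric = corr_metric(cm)) {
  values <- if (inherits(cm, "corr_matrix")) unclass_corr(cm) else cm
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (is.null(metric) || !metric %in% metric_names)
    stop("`metric` must name the metric the matrix was computed with", call. = FALSE)
  if (anyNA(values))
    stop(paste("coefficient matrix contains NaN/NA (zero-variance or missing data);",
               "reload with strict = TRUE or remove the affected subjects"),
         call. = FALSE)
  if (!isSymmetric(values, check.attributes = FALSE))
    stop("coefficient matrix is not symmetric", call. = FALSE)
  d <- if (metric == "euclidean") values else 1 - values
  diag(d) <- 0
  d
}

#' Agglomerative hierarchical clustering of subjects
#'
#' Standard agglomerative clustering of a distance matrix.  Complete linkage
#' is the default (matching `hclust()`'s own default); average and single
#' linkage are available since the appropriate linkage is study-dependent.
#'
#' @param d symmetric distance matrix (zero diagonal, finite) or a
#'   [stats::dist] object.
#' @param linkage `"complete"`, `"average"` or `"single"`.
#' @return An [stats::hclust] tree over the subjects.
#' @export
hier_cluster <- function(d, linkage = c("complete", "average", "single")) {
  linkage <- match.arg(linkage)
  if (is.matrix(d)) {
    if (anyNA(d) || any(!is.finite(d)))
      stop("distance matrix must be finite with no NA", call. = FALSE)
    if (!isSymmetric(d, check.attributes = FALSE))
      stop("distance matrix must be symmetric", call. = FALSE)
    d <- stats::as.dist(d)
  } else if (!inherits(d, "dist")) {
    stop("`d` must be a symmetric matrix or a dist object", call. = FALSE)
  }
  if (anyNA(d)) stop("distance matrix must be finite with no NA", call. = FALSE)
  stats::hclust(d, method = linkage)
}

#' Cut a dendrogram into g groups
#'
#' @param tree an [stats::hclust] tree.
#' @param g number of groups, `1 <= g <= n`.
#' @return Named integer vector of cluster labels `1..g`.
#' @export
cut_tree <- function(tree, g) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$order)
  if (length(g) != 1L || is.na(g) || g < 1L || g > n || g != floor(g))
    stop(sprintf("`g` must be an integer in 1..%d", n), call. = FALSE)
  stats::cutree(tree, k = g)
}

#' Export a dendrogram in Newick format
#'
#' @param tree an [stats::hclust] tree.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "hclust"))
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
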
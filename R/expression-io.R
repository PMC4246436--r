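# Expression-matrix I/O and the on-disk block store.
#
# Canonical internal orientation is subjects-as-rows (the pipeline
# correlates subjects); the common series-matrix layout with subjects as
# columns is handled by the `orientation` flag at read time.  The block
# store is a plain directory holding one delimited file per block plus a
# JSON manifest (k, n, boundaries, per-block row counts and value checksums)
# and stands in for a distributed file system.

#' Read a delimited expression matrix
#'
#' Expects a header row and an identifier first column.  With
#' `orientation = "subjects-rows"` (the canonical layout) row identifiers
#' are subjects and column names are probesets; `"subjects-cols"` reads the
#' transposed layout and returns the same subjects-as-rows matrix.
#'
#' Cells equal to `NA`, `NaN` or empty parse as `NaN` and propagate into any
#' coefficient that touches them; `strict = TRUE` rejects such cells at load
#' time instead.
#'
#' @param path CSV/TSV file.
#' @param orientation `"subjects-rows"` or `"subjects-cols"`.
#' @param delimiter field separator; default `"auto"` lets the reader sniff
#'   comma versus tab.
#' @param strict reject missing values at load time.
#' @return Numeric matrix, subjects as rows, with subject/probeset ids as
#'   dimnames.
#' @export
read_expression <- function(path, orientation = c("subjects-rows", "subjects-cols"),
                            delimiter = "auto", strict = FALSE) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  dt <- withCallingHandlers(
    data.table::fread(path, sep = delimiter, header = TRUE,
                      na.strings = c("NA", "NaN", ""), fill = FALSE,
                      colClasses = list(character = 1L), data.table = TRUE),
    warning = function(w) {
      msg <- conditionMessage(w)
      # fread tolerates some ragged shapes with a warning; treat them as
      # structure errors
      if (grepl("Discarded|Stopped early|fewer fields|more fields", msg))
        stop("malformed table structure (ragged rows?): ", msg, call. = FALSE)
      invokeRestart("muffleWarning")
    })
  if (ncol(dt) < 2L) stop("expected an identifier column plus at least one value column",
                          call. = FALSE)
  ids <- dt[[1L]]
  if (anyDuplicated(ids))
    stop(sprintf("duplicate identifier(s) in first column: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")), call. = FALSE)
  value_cols <- names(dt)[-1L]
  if (anyDuplicated(value_cols))
    stop(sprintf("duplicate identifier(s) in header: %s",
                 paste(unique(value_cols[duplicated(value_cols)]), collapse = ", ")),
         call. = FALSE)
  for (col in value_cols) {
    v <- dt[[col]]
    if (is.logical(v) && all(is.na(v))) {
      data.table::set(dt, j = col, value = as.numeric(v))
    } else if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))[1L]
      stop(sprintf("non-numeric cell at row '%s', column '%s': \"%s\"",
                   ids[bad], col, v[bad]), call. = FALSE)
    }
  }
  m <- as.matrix(dt[, -1L, with = FALSE])
  rownames(m) <- ids
  storage.mode(m) <- "double"
  if (orientation == "subjects-cols") m <- t(m)
  if (strict && anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at subject '%s', probeset '%s' (strict mode)",
                 rownames(m)[bad[1L]], colnames(m)[bad[2L]]), call. = FALSE)
  }
  m[is.na(m)] <- NaN
  validate_expression(m)
  m
}

#' Write an expression matrix
#'
#' Full-precision delimited text (values round-trip bitwise through
#' [read_expression()]).
#'
#' @param m numeric matrix, subjects as rows, dimnames set.
#' @param path output file; `.tsv` extension selects tab separation.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  validate_expression(m)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- data.frame(subject_id = rownames(m), m, check.names = FALSE)
  # readr writes shortest round-trippable doubles, so values survive the
  # text round trip bitwise
  readr::write_delim(df, path, delim = sep, na = "NA", quote = "none",
                     progress = FALSE)
  invisible(path)
}

validate_expression <- function(m) {
  if (!is.matrix(m) || !is.numeric(m) || nrow(m) < 1L || ncol(m) < 1L)
    stop("expression matrix must be a numeric matrix with n >= 1, p >= 1", call. = FALSE)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix needs subject (row) and probeset (column) identifiers",
         call. = FALSE)
  if (anyDuplicated(rownames(m))) stop("duplicate subject identifiers", call. = FALSE)
  if (anyDuplicated(colnames(m))) stop("duplicate probeset identifiers", call. = FALSE)
  invisible(m)
}

#' Equal-size contiguous block partition
#'
#' Boundaries are 0-based half-open row ranges: block `b` holds rows
#' `boundaries[b+1] .. boundaries[b+2] - 1` (1-based R rows
#' `boundaries[b+1]+1 .. boundaries[b+2]`).  The first `n mod k` blocks get
#' `ceiling(n/k)` subjects, the rest `floor(n/k)`, so sizes differ by at
#' most 1.
#'
#' @param n total subjects.
#' @param k number of blocks, `1 <= k <= n`.
#' @return A `block_partition`: list with `k`, `n`, `boundaries` (length
#'   `k+1`).
#' @export
block_partition <- function(n, k) {
  n <- check_count(n, "n")
  k <- check_count(k, "k")
  if (k > n) stop(sprintf("cannot split %d subjects into %d blocks", n, k), call. = FALSE)
  sizes <- rep.int(n %/% k, k)
  if (n %% k > 0L) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  structure(list(k = k, n = n, boundaries = c(0L, cumsum(sizes))),
            class = "block_partition")
}

#' @export
print.block_partition <- function(x, ...) {
  cat(sprintf("<block_partition> n=%d subjects in k=%d blocks, sizes: %s\n",
              x$n, x$k, paste(diff(x$boundaries), collapse = " ")))
  invisible(x)
}

partition_sizes <- function(p) diff(p$boundaries)

block_rows <- function(p, block_id) {
  (p$boundaries[block_id + 1L] + 1L):p$boundaries[block_id + 2L]
}

#' Split an expression matrix into a block store
#'
#' Writes `k` contiguous row slices of the matrix as delimited block files
#' `block_0 .. block_<k-1>` plus `manifest.json` recording the partition and
#' per-block checksums.  Concatenating the blocks in id order reproduces the
#' matrix exactly.
#'
#' @param m expression matrix (subjects as rows).
#' @param k number of blocks, `1 <= k <= n`.
#' @param store directory to create/fill.
#' @return The `block_partition`, invisibly.
#' @export
split_blocks <- function(m, k, store) {
  validate_expression(m)
  part <- block_partition(nrow(m), k)
  dir.create(store, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("block_%d.csv", 0:(part$k - 1L))
  for (b in 0:(part$k - 1L)) {
    rows <- block_rows(part, b)
    write_expression(m[rows, , drop = FALSE], file.path(store, files[b + 1L]))
  }
  manifest <- list(
    k = part$k, n = part$n, p = ncol(m),
    boundaries = part$boundaries,
    subject_ids = rownames(m),
    files = files,
    block_checksums = vapply(0:(part$k - 1L), function(b)
      value_checksum(m[block_rows(part, b), , drop = FALSE]), character(1L))
  )
  jsonlite::write_json(manifest, file.path(store, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(part)
}

value_checksum <- function(m) {
  s <- sum(m, na.rm = TRUE)
  sprintf("n%d:%.17g", sum(is.na(m)), s)
}

read_manifest <- function(store) {
  mf_path <- file.path(store, "manifest.json")
  if (!file.exists(mf_path))
    stop(sprintf("not a block store (no manifest.json): %s", store), call. = FALSE)
  jsonlite::read_json(mf_path, simplifyVector = TRUE)
}

#' Read the partition recorded in a block store
#'
#' @param store block store directory written by [split_blocks()].
#' @return A `block_partition`.
#' @export
read_partition <- function(store) {
  mf <- read_manifest(store)
  structure(list(k = as.integer(mf$k), n = as.integer(mf$n),
                 boundaries = as.integer(mf$boundaries)),
            class = "block_partition")
}

#' Read one block from a block store
#'
#' Verifies the block file against the manifest (row count and value
#' checksum) before returning it.
#'
#' @param store block store directory.
#' @param block_id 0-based block id.
#' @return An `expr_block`: list with `block_id`, `subject_ids`, `values`.
#' @export
read_block <- function(store, block_id) {
  mf <- read_manifest(store)
  if (length(block_id) != 1L || is.na(block_id) || block_id < 0L || block_id >= mf$k)
    stop(sprintf("block id %s out of range 0..%d", toString(block_id), mf$k - 1L),
         call. = FALSE)
  path <- file.path(store, mf$files[block_id + 1L])
  if (!file.exists(path))
    stop(sprintf("block store is missing %s", basename(path)), call. = FALSE)
  values <- read_expression(path)
  expected_rows <- mf$boundaries[block_id + 2L] - mf$boundaries[block_id + 1L]
  if (nrow(values) != expected_rows ||
      !identical(value_checksum(values), mf$block_checksums[block_id + 1L]))
    stop(sprintf("block %d does not match the manifest (file corrupted or replaced)",
                 block_id), call. = FALSE)
  structure(list(block_id = as.integer(block_id),
                 subject_ids = rownames(values), values = values),
            class = "expr_block")
}

#' Write an assembled coefficient matrix
#'
#' `layout = "square"` writes the full `n x n` matrix with subject ids as
#' header row and first column; `layout = "lower-triangle"` writes the
#' `n(n+1)/2` entries with `i >= j` as `(subject_i, subject_j, value)` rows.
#'
#' @param cm a `corr_matrix` from [run_job()]/[assemble()], or a plain
#'   symmetric matrix with dimnames.
#' @param path output CSV file.
#' @param layout `"square"` or `"lower-triangle"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(cm, path, layout = c("square", "lower-triangle")) {
  layout <- match.arg(layout)
  values <- if (inherits(cm, "corr_matrix")) unclass_corr(cm) else cm
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  ids <- rownames(values)
  if (layout == "square") {
    df <- data.frame(subject_id = ids, values, check.names = FALSE)
    readr::write_csv(df, path, na = "NA", quote = "none", progress = FALSE)
  } else {
    idx <- which(lower.tri(values, diag = TRUE), arr.ind = TRUE)
    df <- data.frame(subject_i = ids[idx[, 1L]],
                     subject_j = ids[idx[, 2L]],
                     value = values[idx])
    readr::write_csv(df, path, na = "NA", quote = "none", progress = FALSE)
  }
  invisible(path)
}

#' Read back a square coefficient matrix
#'
#' @param path CSV written by [write_matrix()] with `layout = "square"`.
#' @param metric optional metric name to attach (restores a `corr_matrix`).
#' @return A symmetric matrix, as a `corr_matrix` when `metric` is given.
#' @export
read_matrix <- function(path, metric = NULL) {
  dt <- data.table::fread(path, header = TRUE, colClasses = list(character = 1L))
  m <- as.matrix(dt[, -1L, with = FALSE])
  rownames(m) <- dt[[1L]]
  storage.mode(m) <- "double"
  if (is.null(metric)) m else new_corr_matrix(m, metric)
}
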
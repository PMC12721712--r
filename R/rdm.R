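#' Representational dissimilarity matrices
#'
#' An `rdm` is a symmetric condition-by-condition matrix of pairwise
#' dissimilarities with a zero diagonal. Three dissimilarity kinds are
#' supported: `"decoding_accuracy"` (cross-validated pairwise classification
#' accuracy, bounded in \[0, 1\]), `"abs_difference"` (absolute difference of a
#' scalar feature) and `"one_minus_pearson"` (1 - Pearson correlation between
#' feature vectors, bounded in \[0, 2\]).
#'
#' Symmetry is enforced to within `tol`. For decoding RDMs only, where
#' cross-validation fold noise can break symmetry when each ordered pair is
#' estimated separately, `symmetrize = TRUE` replaces the matrix by the average
#' of itself and its transpose before validation.
#'
#' @param values Square numeric matrix of dissimilarities.
#' @param ids Character vector of condition identifiers, one per row/column.
#'   Defaults to the matrix dimnames or `cond_1 ... cond_n`.
#' @param kind One of `"decoding_accuracy"`, `"abs_difference"`,
#'   `"one_minus_pearson"`.
#' @param symmetrize Average `values` with its transpose before validation.
#'   Only permitted for decoding RDMs.
#' @param tol Symmetry tolerance (maximum absolute row/column discrepancy).
#' @return An object of class `rdm` with fields `values`, `ids`, `kind`.
#' @export
rdm <- function(values, ids = NULL,
                kind = c("decoding_accuracy", "abs_difference", "one_minus_pearson"),
                symmetrize = FALSE, tol = 1e-10) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values) || nrow(values) != ncol(values)) {
    stop("`values` must be a square numeric matrix.", call. = FALSE)
  }
  n <- nrow(values)
  if (n < 2) stop("an RDM needs at least 2 conditions.", call. = FALSE)
  if (is.null(ids)) ids <- rownames(values)
  if (is.null(ids)) ids <- paste0("cond_", seq_len(n))
  ids <- as.character(ids)
  if (length(ids) != n) stop("`ids` must have one entry per condition.", call. = FALSE)
  if (anyDuplicated(ids)) stop("condition ids must be unique.", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("RDM values must be finite.", call. = FALSE)
  }
  if (symmetrize) {
    if (kind != "decoding_accuracy") {
      stop("`symmetrize` is only permitted for decoding RDMs.", call. = FALSE)
    }
    values <- (values + t(values)) / 2
  }
  asym <- max(abs(values - t(values)))
  if (asym > tol) {
    stop(sprintf("RDM is not symmetric (max |M - t(M)| = %.3g > %.3g).", asym, tol),
         call. = FALSE)
  }
  values <- (values + t(values)) / 2  # remove sub-tolerance asymmetry exactly
  if (any(diag(values) != 0)) {
    if (max(abs(diag(values))) > tol) {
      stop("RDM diagonal must be zero.", call. = FALSE)
    }
    diag(values) <- 0
  }
  if (kind == "decoding_accuracy") {
    off <- values[upper.tri(values)]
    if (any(off < 0 | off > 1)) {
      stop("decoding-accuracy dissimilarities must lie in [0, 1].", call. = FALSE)
    }
  }
  dimnames(values) <- list(ids, ids)
  structure(list(values = values, ids = ids, kind = kind), class = "rdm")
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("<rdm> %d x %d, kind = %s\n", length(x$ids), length(x$ids), x$kind))
  v <- x$values[upper.tri(x$values)]
  cat(sprintf("  off-diagonal range [%.4g, %.4g], mean %.4g\n",
              min(v), max(v), mean(v)))
  invisible(x)
}

#' @export
dim.rdm <- function(x) dim(x$values)

# Fixed pair order shared by every vectorization in the package:
# row-major over (i, j) with i < j, i.e. (1,2), (1,3), ..., (1,n), (2,3), ...
pair_order <- function(n) {
  stopifnot(n >= 2)
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2L:n)
  cbind(i = i, j = j)
}

#' Vectorize the upper triangle of an RDM
#'
#' Extracts the strictly-above-diagonal cells in a fixed row-major pair order
#' ((1,2), (1,3), ..., (2,3), ...), the order used by every vectorized
#' computation in the package so that cell-level resampling indices are
#' comparable across RDMs. For an n-condition RDM the vector has length
#' n(n-1)/2 (19,900 for n = 200).
#'
#' @param x An [rdm].
#' @return An `rdm_vector`: numeric `values` of length n(n-1)/2 plus the
#'   `pairs` index matrix and the condition `ids`.
#' @seealso [rdm_from_vector()] for the exact inverse.
#' @export
vectorize_upper <- function(x) {
  stopifnot(inherits(x, "rdm"))
  po <- pair_order(length(x$ids))
  structure(
    list(values = x$values[po], pairs = po, ids = x$ids, kind = x$kind),
    class = "rdm_vector"
  )
}

#' Rebuild a symmetric RDM from an upper-triangle vector
#'
#' Exact inverse of [vectorize_upper()].
#'
#' @param v An `rdm_vector`, or a bare numeric vector of length n(n-1)/2 (then
#'   `ids` and `kind` must be supplied).
#' @param ids,kind Used when `v` is a bare numeric vector.
#' @return An [rdm].
#' @export
rdm_from_vector <- function(v, ids = NULL, kind = NULL) {
  if (inherits(v, "rdm_vector")) {
    ids <- ids %||% v$ids
    kind <- kind %||% v$kind
    vals <- v$values
  } else {
    vals <- as.numeric(v)
  }
  if (is.null(ids)) stop("`ids` required for a bare numeric vector.", call. = FALSE)
  n <- length(ids)
  if (length(vals) != n * (n - 1L) / 2L) {
    stop(sprintf("vector length %d does not match %d conditions (need %d).",
                 length(vals), n, n * (n - 1L) / 2L), call. = FALSE)
  }
  m <- matrix(0, n, n)
  po <- pair_order(n)
  m[po] <- vals
  m[po[, c(2, 1), drop = FALSE]] <- vals
  rdm(m, ids = ids, kind = kind %||% "abs_difference")
}

#' @export
print.rdm_vector <- function(x, ...) {
  cat(sprintf("<rdm_vector> %d pairs of %d conditions, kind = %s\n",
              length(x$values), length(x$ids), x$kind))
  invisible(x)
}

as_rdm_values <- function(x) {
  if (inherits(x, "rdm_vector")) x$values
  else if (inherits(x, "rdm")) vectorize_upper(x)$values
  else as.numeric(x)
}

#' Absolute-difference RDM from a scalar feature column
#'
#' Dissimilarity between conditions i and j is `|x_i - x_j|` for the named
#' feature column, the construction used for the real-world size, retinal size
#' and real-world depth hypothesis RDMs.
#'
#' @param conditions A condition table (see [condition_set()]) or any data
#'   frame with an `id` column and the named feature column.
#' @param column Name of the feature column.
#' @return An [rdm] of kind `"abs_difference"`.
#' @export
rdm_from_feature_column <- function(conditions, column) {
  stopifnot(is.data.frame(conditions))
  if (!column %in% names(conditions)) {
    stop(sprintf("column '%s' not found in the condition table.", column), call. = FALSE)
  }
  x <- conditions[[column]]
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("column '%s' must be finite numeric.", column), call. = FALSE)
  }
  m <- abs(outer(x, x, "-"))
  rdm(m, ids = conditions$id, kind = "abs_difference")
}

#' Correlation-distance RDM from per-condition feature vectors
#'
#' Dissimilarity between conditions i and j is 1 - Pearson correlation of the
#' corresponding feature rows, the construction used for model feature spaces
#' (network-layer activations, word-embedding vectors).
#'
#' @param ids Condition identifiers, one per matrix row.
#' @param feature_matrix Numeric matrix, one feature vector per condition
#'   (n conditions x d features, d >= 2).
#' @return An [rdm] of kind `"one_minus_pearson"`; values lie in \[0, 2\].
#' @export
rdm_from_feature_vectors <- function(ids, feature_matrix) {
  feature_matrix <- as.matrix(feature_matrix)
  ids <- as.character(ids)
  if (nrow(feature_matrix) != length(ids)) {
    stop("`feature_matrix` needs one row per condition id.", call. = FALSE)
  }
  if (ncol(feature_matrix) < 2) {
    stop("feature vectors need at least 2 dimensions.", call. = FALSE)
  }
  sds <- apply(feature_matrix, 1, stats::sd)
  if (any(bad <- sds == 0 | !is.finite(sds))) {
    stop(sprintf("zero-variance feature row(s): %s",
                 paste(ids[bad], collapse = ", ")), call. = FALSE)
  }
  m <- 1 - stats::cor(t(feature_matrix))
  diag(m) <- 0
  rdm(m, ids = ids, kind = "one_minus_pearson", tol = 1e-8)
}

#' Rank-transform an RDM vector
#'
#' Average ranks with the standard midrank tie convention, the shared
#' primitive behind every Spearman computation in the package.
#'
#' @param v An `rdm_vector` or numeric vector.
#' @return Same type as the input, values replaced by their ranks.
#' @export
rank_transform <- function(v) {
  if (inherits(v, "rdm_vector")) {
    v$values <- rank(v$values, ties.method = "average")
    v
  } else {
    rank(as.numeric(v), ties.method = "average")
  }
}

#' Percentile-equalize an RDM for display
#'
#' Replaces each off-diagonal cell by its percentile rank (0-100 scale) among
#' all off-diagonal cells. A display transform only: it is rank-preserving and
#' is never used in inference.
#'
#' @param x An [rdm].
#' @return An [rdm] with percentile-unit values (kind is preserved).
#' @export
percentile_equalize <- function(x) {
  stopifnot(inherits(x, "rdm"))
  v <- vectorize_upper(x)
  pct <- 100 * rank(v$values, ties.method = "average") / length(v$values)
  out <- x
  po <- v$pairs
  out$values[po] <- pct
  out$values[po[, c(2, 1), drop = FALSE]] <- pct
  out
}

#' @export
tidy.rdm <- function(x, ...) {
  v <- vectorize_upper(x)
  tibble::tibble(
    condition_a = x$ids[v$pairs[, 1]],
    condition_b = x$ids[v$pairs[, 2]],
    value = v$values
  )
}

#' Write / read an RDM as long-format delimited text
#'
#' Plain-text mirror of an RDM: one row per unordered condition pair with
#' columns `condition_a`, `condition_b`, `value`.
#'
#' @param x An [rdm].
#' @param path File path.
#' @param kind Dissimilarity kind to stamp on the re-read RDM.
#' @return `write_rdm_long()` returns `x` invisibly; `read_rdm_long()` an [rdm].
#' @export
write_rdm_long <- function(x, path) {
  readr::write_csv(tidy.rdm(x), path)
  invisible(x)
}

#' @rdname write_rdm_long
#' @export
read_rdm_long <- function(path, kind = "abs_difference") {
  d <- readr::read_csv(path, show_col_types = FALSE)
  ids <- unique(c(d$condition_a, d$condition_b))
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  m[cbind(match(d$condition_a, ids), match(d$condition_b, ids))] <- d$value
  m[cbind(match(d$condition_b, ids), match(d$condition_a, ids))] <- d$value
  rdm(m, ids = ids, kind = kind)
}
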
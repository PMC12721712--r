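#' Hypothesis RDMs for real-world size, retinal size and depth
#'
#' Builds the three absolute-difference hypothesis RDMs from a condition
#' table — one from the real-world size ratings, one from the retinal sizes
#' in pixels, one from the depth index (size/retinal, see [depth_index()]) —
#' together with their 3 x 3 Spearman intercorrelation matrix over vectorized
#' upper triangles. Ratings are used on their published scale without a log
#' transform (the rating task already spans a logarithmic size range, and all
#' downstream statistics are rank-based); the depth RDM uses the raw ratio,
#' whose pairwise differences are not scale-free in general but whose ranks
#' are invariant to a common rescaling of all retinal sizes.
#'
#' @param conditions A [condition_set()] table.
#' @return An object of class `hypothesis_rdms`: a named list of three [rdm]s
#'   (`real_world_size`, `retinal_size`, `real_world_depth`) plus
#'   `intercorrelations`.
#' @export
build_hypothesis_rdms <- function(conditions) {
  conditions <- validate_condition_set(conditions)
  feats <- c("real_world_size", "retinal_size", "real_world_depth")
  rdms <- lapply(feats, function(f) rdm_from_feature_column(conditions, f))
  names(rdms) <- feats
  vecs <- vapply(rdms, function(r) vectorize_upper(r)$values,
                 numeric(nrow(conditions) * (nrow(conditions) - 1) / 2))
  ic <- stats::cor(vecs, method = "spearman")
  structure(c(rdms, list(intercorrelations = ic)), class = "hypothesis_rdms")
}

#' @export
print.hypothesis_rdms <- function(x, ...) {
  cat(sprintf("<hypothesis_rdms> %d conditions\n", length(x$real_world_size$ids)))
  cat("Spearman intercorrelations:\n")
  print(round(x$intercorrelations, 3))
  invisible(x)
}

#' @export
tidy.hypothesis_rdms <- function(x, ...) {
  ic <- x$intercorrelations
  po <- pair_order(nrow(ic))
  tibble::tibble(
    rdm_a = rownames(ic)[po[, 1]],
    rdm_b = colnames(ic)[po[, 2]],
    spearman = ic[po]
  )
}
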
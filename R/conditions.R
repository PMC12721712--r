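#' Condition feature tables
#'
#' A condition table is a tibble with one row per stimulus condition and
#' columns `id`, `real_world_size` (behavioral size rating, on its published
#' 0-519-style scale), `retinal_size` (displayed object size in pixels,
#' bounding-box diagonal) and `real_world_depth` (dimensionless depth index,
#' see [depth_index()]). If `real_world_depth` is omitted it is derived from
#' the other two columns.
#'
#' @param id Unique condition identifiers (coerced to character).
#' @param real_world_size Positive real-world size ratings.
#' @param retinal_size Strictly positive retinal sizes in pixels.
#' @param real_world_depth Optional; computed as size/retinal when `NULL`.
#' @return A tibble of class `condition_set`.
#' @export
condition_set <- function(id, real_world_size, retinal_size, real_world_depth = NULL) {
  out <- tibble::tibble(
    id = as.character(id),
    real_world_size = as.numeric(real_world_size),
    retinal_size = as.numeric(retinal_size),
    real_world_depth = if (is.null(real_world_depth)) {
      depth_index(as.numeric(real_world_size), as.numeric(retinal_size))
    } else {
      as.numeric(real_world_depth)
    }
  )
  validate_condition_set(out)
}

#' @rdname condition_set
#' @param x A data frame to validate.
#' @export
validate_condition_set <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("id", "real_world_size", "retinal_size", "real_world_depth")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("condition table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(x) < 2) stop("need at least 2 conditions.", call. = FALSE)
  if (anyDuplicated(x$id)) stop("condition ids must be unique.", call. = FALSE)
  num <- x[setdiff(need, "id")]
  if (any(!vapply(num, is.numeric, logical(1))) ||
      anyNA(num) || any(!vapply(num, function(v) all(is.finite(v)), logical(1)))) {
    stop("feature columns must be finite numeric.", call. = FALSE)
  }
  if (any(x$retinal_size <= 0)) {
    stop("retinal_size must be strictly positive.", call. = FALSE)
  }
  class(x) <- unique(c("condition_set", class(x)))
  x
}

#' Real-world depth index
#'
#' Under perspective projection at a fixed viewing distance, an object's
#' inferred egocentric depth is proportional to its real-world size divided by
#' its retinal size; the constant viewing distance is absorbed, so the index
#' is a proxy on a ratio scale rather than a metric distance. Only the ranks
#' of pairwise differences of this index are used downstream.
#'
#' @param size_rating Positive real-world size rating(s).
#' @param retinal_px Strictly positive retinal size(s) in pixels.
#' @return `size_rating / retinal_px`, elementwise.
#' @export
depth_index <- function(size_rating, retinal_px) {
  if (any(!is.finite(retinal_px)) || any(retinal_px <= 0)) {
    stop("retinal size must be finite and strictly positive.", call. = FALSE)
  }
  size_rating / retinal_px
}

#' Read / write a condition table
#'
#' Delimited text (CSV) with header columns `id`, `real_world_size`,
#' `retinal_size` and optionally `real_world_depth` (derived when absent).
#'
#' @param path File path.
#' @return A `condition_set` tibble.
#' @export
read_condition_table <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  condition_set(d$id, d$real_world_size, d$retinal_size, d$real_world_depth)
}

#' @rdname read_condition_table
#' @param x A `condition_set`.
#' @export
write_condition_table <- function(x, path) {
  readr::write_csv(validate_condition_set(x), path)
  invisible(x)
}
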
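#' Construct a time-series expression dataset
#'
#' The container consumed by [build_affinities()] and [fit_tsee()]: a
#' cells-by-features matrix of preprocessed expression values in \[0, 1\]
#' together with per-cell experimental stage annotation.  `stage_time` is
#' the normalized collection time of each cell's stage (earliest stage 0,
#' latest 1); `stage_index` is the 1-based rank of that stage.
#'
#' @param expression numeric matrix, cells in rows, features in columns,
#'   values in \[0, 1\].
#' @param stage_time numeric vector, one normalized time per cell, in
#'   \[0, 1\].
#' @param stage_index optional integer vector of stage ranks (1..n).  If
#'   omitted it is derived as the rank of `stage_time` among its sorted
#'   unique values.
#' @param cell_ids,feature_ids optional identifier vectors; default to the
#'   matrix dimnames or generated `cell_1..`/`feat_1..` labels.
#'
#' @return An object of class `"time_series_dataset"`: a list with elements
#'   `expression`, `stage_time`, `stage_index`, `cell_ids`, `feature_ids`.
#' @export
#' @examples
#' expr <- matrix(runif(20), nrow = 4)
#' ds <- time_series_dataset(expr, stage_time = c(0, 0, 1, 1))
#' ds$stage_index
time_series_dataset <- function(expression, stage_time, stage_index = NULL,
                                cell_ids = NULL, feature_ids = NULL) {
  expression <- as.matrix(expression)
  storage.mode(expression) <- "double"
  n <- nrow(expression)
  if (n < 2L) stop("a time_series_dataset needs at least 2 cells")
  if (ncol(expression) < 1L) stop("expression must have at least one feature")
  if (anyNA(expression) || any(!is.finite(expression))) {
    stop("expression contains non-finite values")
  }
  if (length(stage_time) != n) {
    stop("stage_time must have one entry per cell (", n, ")")
  }
  stage_time <- as.numeric(stage_time)
  if (any(stage_time < 0 | stage_time > 1)) {
    stop("stage_time must lie in [0, 1]; run normalize_times() first")
  }
  if (is.null(stage_index)) {
    stage_index <- match(stage_time, sort(unique(stage_time)))
  }
  stage_index <- as.integer(stage_index)
  n_stages <- max(stage_index)
  if (!setequal(unique(stage_index), seq_len(n_stages))) {
    stop("stage_index must cover consecutive integers 1..n with every stage non-empty")
  }
  ord <- order(stage_time)
  if (is.unsorted(stage_index[ord])) {
    stop("stage_index must be non-decreasing in stage_time")
  }
  if (is.null(cell_ids)) {
    cell_ids <- rownames(expression)
    if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(n))
  }
  if (is.null(feature_ids)) {
    feature_ids <- colnames(expression)
    if (is.null(feature_ids)) feature_ids <- paste0("feat_", seq_len(ncol(expression)))
  }
  if (length(cell_ids) != n) stop("cell_ids length does not match cell count")
  if (length(feature_ids) != ncol(expression)) {
    stop("feature_ids length does not match feature count")
  }
  structure(
    list(
      expression = unname(expression),
      stage_time = stage_time,
      stage_index = stage_index,
      cell_ids = as.character(cell_ids),
      feature_ids = as.character(feature_ids)
    ),
    class = "time_series_dataset"
  )
}

#' @export
print.time_series_dataset <- function(x, ...) {
  cat(sprintf(
    "time_series_dataset: %d cells x %d features, %d stages\n",
    nrow(x$expression), ncol(x$expression), max(x$stage_index)
  ))
  invisible(x)
}

#' Number of cells in a dataset
#' @param dataset a [time_series_dataset()].
#' @return integer cell count.
#' @export
n_cells <- function(dataset) nrow(dataset$expression)
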
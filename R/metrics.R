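#' Nearest-neighbor index of each embedded point
#'
#' For each point the index of the closest *other* point in Euclidean
#' distance; ties are broken toward the smallest index.  Duplicate points
#' are legal (distance zero is a valid minimum).
#'
#' @param X N x d coordinate matrix, N >= 2.
#' @return integer vector of length N.
#' @export
nearest_neighbor_index <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 points")
  d2 <- pairwise_sq_distances(X)
  diag(d2) <- Inf
  apply(d2, 1L, which.min)
}

#' In-group proportion (IGP) per group
#'
#' The fraction of a group's members whose nearest neighbor in the
#' embedding carries the same group label.  Singleton groups score 0,
#' since their nearest neighbor is necessarily elsewhere.
#'
#' @param X N x d coordinate matrix.
#' @param group length-N label vector (any comparable type).
#' @return named numeric vector, one value in \[0, 1\] per group, ordered
#'   by sorted unique label.
#' @export
igp <- function(X, group) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 points")
  if (length(group) != nrow(X)) stop("group labels must align with rows of X")
  nn <- nearest_neighbor_index(X)
  same <- group == group[nn]
  vapply(
    split(same, factor(group, levels = sort(unique(group)))),
    mean, numeric(1)
  )
}

check_stage_labels <- function(stage_index, n) {
  if (length(stage_index) != n) stop("stage_index must align with rows of X")
  si <- suppressWarnings(as.integer(stage_index))
  if (anyNA(si) || any(si != stage_index)) {
    stop("stage labels must be integer stage indices (ordinal time stages)")
  }
  u <- sort(unique(si))
  if (!identical(u, seq_len(max(si)))) {
    stop("stage indices must be consecutive integers 1..n, every stage non-empty")
  }
  si
}

#' Time-adjacent in-group proportion (IGP2) per stage
#'
#' Relaxes [igp()] for ordered time stages: a cell counts as in-group when
#' its nearest neighbor lies in the same *or an adjacent* stage
#' (`|stage(j) - stage(j^N)| <= 1`).  Therefore `igp2 >= igp` for every
#' stage.
#'
#' @param X N x d coordinate matrix.
#' @param stage_index length-N vector of consecutive integer stage ranks
#'   1..n.
#' @return named numeric vector per stage, in stage order.
#' @export
igp2 <- function(X, stage_index) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 points")
  si <- check_stage_labels(stage_index, nrow(X))
  nn <- nearest_neighbor_index(X)
  ok <- abs(si - si[nn]) <= 1L
  vapply(split(ok, factor(si, levels = seq_len(max(si)))), mean, numeric(1))
}

#' Sample-weighted mean of per-group scores
#'
#' `sum_u score(u) * size(u) / sum(size)` — the stage-weighted summary used
#' to compare embeddings across parameter settings.
#'
#' @param per_group named numeric vector of per-group scores.
#' @param group_sizes named numeric vector of group sizes (same names).
#' @return scalar in the range of the scores.
#' @export
weighted_mean_igp <- function(per_group, group_sizes) {
  if (length(per_group) == 0L) stop("empty score map")
  if (!setequal(names(per_group), names(group_sizes))) {
    stop("per_group and group_sizes must share the same group names")
  }
  sizes <- group_sizes[names(per_group)]
  sum(per_group * sizes) / sum(sizes)
}

#' Pearson correlation with variance guards
#'
#' Product-moment correlation, used both for comparing a pseudotime
#' against experimental time and (as `1 - PCC`) as a spatial side distance
#' over marker genes.
#'
#' @param a,b numeric vectors of equal length with positive variance.
#' @return scalar in \[-1, 1\].
#' @export
pearson_correlation <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero variance: correlation undefined")
  }
  stats::cor(a, b)
}

#' Misplaced-cell diagnostic
#'
#' Flags each cell whose nearest embedded neighbor lies at least two time
#' stages away — the signature of a point placed among cells of a distant
#' stage.  Per stage, the flagged fraction equals `1 - igp2` exactly.
#'
#' @inheritParams igp2
#' @return logical vector of length N.
#' @export
misplaced_cells <- function(X, stage_index) {
  X <- as.matrix(X)
  si <- check_stage_labels(stage_index, nrow(X))
  nn <- nearest_neighbor_index(X)
  abs(si - si[nn]) >= 2L
}

#' Complete-linkage tree over stage centroids
#'
#' Computes the per-stage centroid of the embedded coordinates and
#' agglomerates the centroids by complete linkage on their Euclidean
#' distances — a compact summary of how the embedding arranges the time
#' stages.  `stats::hclust` merges equal-height candidates in index order,
#' so ties resolve toward the smaller stage.
#'
#' @inheritParams igp2
#' @return an object of class `"hclust"` over the stages (labels are the
#'   stage indices), with the centroid matrix in attribute `"centroids"`.
#' @export
stage_centroid_linkage <- function(X, stage_index) {
  X <- as.matrix(X)
  si <- check_stage_labels(stage_index, nrow(X))
  stages <- seq_len(max(si))
  centroids <- matrix(0, length(stages), ncol(X))
  for (u in stages) {
    centroids[u, ] <- colMeans(X[si == u, , drop = FALSE])
  }
  if (length(stages) < 2L) {
    tree <- list(merge = matrix(numeric(0), 0, 2), height = numeric(0),
                 order = 1L, labels = "1", method = "complete")
    class(tree) <- "hclust"
  } else {
    tree <- stats::hclust(stats::dist(centroids), method = "complete")
    tree$labels <- as.character(stages)
  }
  attr(tree, "centroids") <- centroids
  tree
}

#' Full embedding quality report
#'
#' Bundles the neighbor-purity metrics into one object: per-stage IGP and
#' IGP2, the sample-weighted mean IGP, the misplaced-cell mask, and
#' optionally the Pearson correlation between a caller-supplied pseudotime
#' and the experimental stage time.
#'
#' @param X N x d embedded coordinates (or an `embedding_result`).
#' @param stage_index consecutive integer stage ranks (taken from the
#'   result if `X` is an `embedding_result`).
#' @param pseudotime optional numeric vector; correlated against
#'   `stage_time` when given.
#' @param stage_time optional numeric vector of per-cell stage times, used
#'   only for `pcc_time`.
#' @return list of class `"metric_report"` with `igp_per_group`,
#'   `igp2_per_group`, `weighted_mean_igp`, `pcc_time` (or `NA`),
#'   `misplaced_mask`, `group_sizes`.
#' @export
metric_report <- function(X, stage_index = NULL, pseudotime = NULL,
                          stage_time = NULL) {
  if (inherits(X, "embedding_result")) {
    if (is.null(stage_index)) stage_index <- X$stage_index
    if (is.null(stage_time)) stage_time <- X$stage_time
    X <- X$coordinates
  }
  X <- as.matrix(X)
  si <- check_stage_labels(stage_index, nrow(X))
  igp_g <- igp(X, si)
  igp2_g <- igp2(X, si)
  sizes <- vapply(split(si, factor(si, levels = seq_len(max(si)))),
                  length, integer(1))
  pcc <- NA_real_
  if (!is.null(pseudotime)) {
    if (is.null(stage_time)) stop("stage_time needed to compute pcc_time")
    pcc <- pearson_correlation(pseudotime, stage_time)
  }
  structure(
    list(
      igp_per_group = igp_g,
      igp2_per_group = igp2_g,
      weighted_mean_igp = weighted_mean_igp(igp_g, sizes),
      pcc_time = pcc,
      misplaced_mask = misplaced_cells(X, si),
      group_sizes = sizes
    ),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat("metric_report\n")
  cat("  weighted mean IGP:", format(x$weighted_mean_igp, digits = 4), "\n")
  cat("  IGP  per stage:", paste(format(x$igp_per_group, digits = 3),
                                 collapse = " "), "\n")
  cat("  IGP2 per stage:", paste(format(x$igp2_per_group, digits = 3),
                                 collapse = " "), "\n")
  cat("  misplaced cells:", sum(x$misplaced_mask), "/",
      length(x$misplaced_mask), "\n")
  if (!is.na(x$pcc_time)) cat("  PCC(pseudotime, time):",
                              format(x$pcc_time, digits = 4), "\n")
  invisible(x)
}
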
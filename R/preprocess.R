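#' Preprocessing configuration
#'
#' @param n_variable_genes number of most-variable genes to keep.
#' @param pca_variance_target cumulative explained-variance threshold in
#'   (0, 1] used to pick the number of principal components; ignored when
#'   `pca_components` is given.
#' @param pca_components explicit number of components (overrides the
#'   variance target).
#' @param seed integer, recorded for provenance (the PCA solver used here
#'   is exact and deterministic).
#' @return list of class `"preprocess_config"`.
#' @export
preprocess_config <- function(n_variable_genes = 1000,
                              pca_variance_target = 0.95,
                              pca_components = NULL,
                              seed = 1L) {
  stopifnot(n_variable_genes >= 1)
  if (is.null(pca_components)) {
    stopifnot(pca_variance_target > 0, pca_variance_target <= 1)
  } else {
    stopifnot(pca_components >= 1)
  }
  structure(
    list(
      n_variable_genes = as.integer(n_variable_genes),
      pca_variance_target = pca_variance_target,
      pca_components = if (is.null(pca_components)) NULL else as.integer(pca_components),
      seed = as.integer(seed)
    ),
    class = "preprocess_config"
  )
}

#' Select the most variable genes
#'
#' Per-gene variances across cells are Z-scored and the `n_keep` genes with
#' the largest Z-scores are returned.  Z-scoring is a monotone map of the
#' variances, so the selection equals the top-variance genes; ties are
#' broken toward the lower gene index, making the result for `n_keep = k`
#' a subset of the result for `k + 1`.
#'
#' @param raw cells x genes numeric matrix.
#' @param n_keep number of genes to keep.
#' @return integer vector of column indices, in decreasing variance order.
#' @export
select_variable_genes <- function(raw, n_keep) {
  raw <- as.matrix(raw)
  g <- ncol(raw)
  stopifnot(n_keep >= 1, n_keep <= g)
  v <- apply(raw, 2L, stats::var)
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) {
    warning("all genes have identical variance; keeping the first ", n_keep)
    return(seq_len(n_keep))
  }
  z <- (v - mean(v)) / s
  order(-z, seq_len(g))[seq_len(n_keep)]
}

#' Global min-max normalization
#'
#' Subtracts the matrix-wide minimum and divides by the maximum of the
#' shifted matrix, mapping the whole matrix (not each gene separately) into
#' \[0, 1\] with minimum exactly 0 and maximum exactly 1.
#'
#' @param M numeric matrix with at least two distinct values.
#' @return matrix of the same shape with entries in \[0, 1\].
#' @export
minmax_normalize <- function(M) {
  M <- as.matrix(M)
  lo <- min(M)
  M <- M - lo
  hi <- max(M)
  if (hi == 0) stop("degenerate matrix: all values identical")
  M / hi
}

#' Normalize stage times to the unit interval
#'
#' Affine map sending the earliest stage to 0 and the latest to 1,
#' preserving the ratios of the experimental time intervals.  A single
#' stage maps to all zeros (with a warning: the temporal term then has no
#' effect).
#'
#' @param stage_times numeric vector of per-cell or per-stage times.
#' @return numeric vector in \[0, 1\].
#' @export
normalize_times <- function(stage_times) {
  stage_times <- as.numeric(stage_times)
  rng <- range(stage_times)
  if (rng[1] == rng[2]) {
    warning("single time stage: all normalized times are 0 and the ",
            "temporal repulsive term has no effect")
    return(rep(0, length(stage_times)))
  }
  (stage_times - rng[1]) / (rng[2] - rng[1])
}

#' PCA reduction with a variance-target component choice
#'
#' Centers the columns and computes exact principal-component scores,
#' keeping the smallest number of components whose cumulative explained
#' variance reaches the target (or the explicit `pca_components`, clamped
#' to `min(N - 1, G)` with a warning).  Each loading vector is flipped so
#' its largest-magnitude entry is positive, fixing the sign
#' indeterminacy.
#'
#' @param M cells x genes numeric matrix.
#' @param config a [preprocess_config()].
#' @return N x K score matrix with attributes `"explained_variance_ratio"`
#'   (all components) and `"n_components"`.
#' @export
pca_reduce <- function(M, config = preprocess_config()) {
  M <- as.matrix(M)
  stopifnot(nrow(M) >= 2)
  pc <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  k_max <- ncol(pc$x)
  if (is.null(config$pca_components)) {
    k <- which(cumsum(evr) >= config$pca_variance_target)[1]
    if (is.na(k)) k <- k_max
  } else {
    k <- config$pca_components
    if (k > k_max) {
      warning("pca_components = ", k, " exceeds min(N - 1, G) = ", k_max,
              "; clamping")
      k <- k_max
    }
  }
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- NULL
  attr(scores, "explained_variance_ratio") <- evr
  attr(scores, "n_components") <- k
  scores
}

#' Full preprocessing pipeline for raw time-series expression matrices
#'
#' Applies, in order: variable-gene selection, global min-max scaling,
#' PCA reduction, and a second global min-max scaling of the component
#' scores; stage times are normalized to \[0, 1\].  The result is a
#' [time_series_dataset()] ready for [fit_tsee()].
#'
#' No library-size normalization or log transform is applied — callers
#' decide whether their matrix holds counts, CPM or log values.
#'
#' @param raw cells x genes numeric matrix.
#' @param stage_labels numeric vector of per-cell experimental times
#'   (arbitrary units, e.g. hours post-fertilization), aligned to rows.
#' @param config a [preprocess_config()].
#' @param cell_ids optional cell identifiers (default rownames).
#' @return a [time_series_dataset()]; the selected gene indices are kept
#'   in attribute `"selected_genes"` and the per-component explained
#'   variance in `"explained_variance_ratio"`.
#' @export
preprocess_pipeline <- function(raw, stage_labels, config = preprocess_config(),
                                cell_ids = NULL) {
  raw <- as.matrix(raw)
  if (length(stage_labels) != nrow(raw)) {
    stop("stage_labels must align with the rows of raw (",
         nrow(raw), " cells)")
  }
  n_keep <- min(config$n_variable_genes, ncol(raw))
  keep <- select_variable_genes(raw, n_keep)
  M <- minmax_normalize(raw[, keep, drop = FALSE])
  scores <- pca_reduce(M, config)
  evr <- attr(scores, "explained_variance_ratio")
  M2 <- minmax_normalize(scores)

  stage_time <- normalize_times(stage_labels)
  stage_index <- match(stage_labels, sort(unique(stage_labels)))
  ds <- time_series_dataset(
    M2, stage_time = stage_time, stage_index = stage_index,
    cell_ids = if (is.null(cell_ids)) rownames(raw) else cell_ids,
    feature_ids = paste0("PC", seq_len(ncol(M2)))
  )
  attr(ds, "selected_genes") <- keep
  attr(ds, "explained_variance_ratio") <- evr
  ds
}
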
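#' Pairwise squared Euclidean distances
#'
#' Shared kernel for both the input-space affinities and the per-iteration
#' embedding-space distances.  Uses the expansion
#' \eqn{\|a-b\|^2 = \|a\|^2 + \|b\|^2 - 2 a \cdot b} with a clamp at zero,
#' and an exactly-zero diagonal.
#'
#' @param points numeric matrix (rows are points).
#' @return symmetric non-negative matrix of squared distances.
#' @export
pairwise_sq_distances <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 1L) stop("need at least one row")
  bad <- which(!apply(points, 1L, function(r) all(is.finite(r))))
  if (length(bad)) {
    stop("non-finite values in row(s): ", paste(bad, collapse = ", "))
  }
  sq <- rowSums(points^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(points)
  d2[d2 < 0] <- 0
  d2 <- (d2 + t(d2)) / 2
  diag(d2) <- 0
  d2
}

#' Build the normalized TSEE affinity model
#'
#' Computes the attractive Gaussian weights, the repulsive disparity
#' weights, and the side-information (time-interval) weights, each with the
#' shared normalizers that make the attractive weights sum to one and the
#' combined repulsive weights sum to one over all ordered pairs:
#' \deqn{w^P_{nm} = N^+ \exp(-\|y_n-y_m\|^2 / 2\sigma^2),\quad
#'       w^N_{nm} = N^- \|y_n-y_m\|,\quad
#'       t_{nm}   = N^- s_{nm},}
#' with \eqn{N^+ = 1/\sum_{n \ne m} w^+_{nm}} and
#' \eqn{N^- = 1/\sum_{n \ne m} (w^-_{nm} + \beta s_{nm})}.  The default
#' side distance is the experimental time interval
#' \eqn{s_{nm} = |t(n) - t(m)|}; supplying `side_distance` swaps in any
#' other non-negative symmetric dissimilarity (e.g. `1 - PCC` over spatial
#' marker genes).  Diagonals are zeroed before normalization, so
#' self-affinity never enters the normalizers.
#'
#' @param dataset a [time_series_dataset()].
#' @param beta non-negative weight of the side-information term in the
#'   shared repulsive normalizer.
#' @param sigma positive Gaussian bandwidth for the attractive weights.
#' @param side_distance optional N x N symmetric non-negative matrix
#'   replacing the default time-interval matrix.
#' @return An object of class `"affinity_model"`: list with `w_plus`,
#'   `w_minus`, `t_side` (all N x N, zero diagonal), `beta`, `sigma`.
#' @export
build_affinities <- function(dataset, beta = 10, sigma, side_distance = NULL) {
  stopifnot(inherits(dataset, "time_series_dataset"))
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("sigma must be a single positive number")
  }
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0) {
    stop("beta must be a single non-negative number")
  }
  n <- n_cells(dataset)
  d2 <- pairwise_sq_distances(dataset$expression)

  w_plus_raw <- exp(-d2 / (2 * sigma^2))
  diag(w_plus_raw) <- 0
  w_minus_raw <- sqrt(d2)
  diag(w_minus_raw) <- 0

  if (is.null(side_distance)) {
    side <- abs(outer(dataset$stage_time, dataset$stage_time, "-"))
  } else {
    side <- as.matrix(side_distance)
    if (!identical(dim(side), c(n, n))) {
      stop("side_distance must be ", n, " x ", n)
    }
    if (any(side < 0) || max(abs(side - t(side))) > 1e-12) {
      stop("side_distance must be symmetric and non-negative")
    }
  }
  diag(side) <- 0
  dimnames(side) <- NULL

  n_plus <- sum(w_plus_raw)
  if (n_plus <= 0) stop("degenerate dataset: attractive normalizer undefined")
  n_minus_denom <- sum(w_minus_raw) + beta * sum(side)
  if (n_minus_denom <= 0) {
    stop("degenerate dataset: repulsive normalizer undefined ",
         "(all cells identical and no side information)")
  }

  structure(
    list(
      w_plus = w_plus_raw / n_plus,
      w_minus = w_minus_raw / n_minus_denom,
      t_side = side / n_minus_denom,
      beta = beta,
      sigma = sigma
    ),
    class = "affinity_model"
  )
}

#' @export
print.affinity_model <- function(x, ...) {
  cat(sprintf(
    "affinity_model: %d cells, beta = %g, sigma = %g\n",
    nrow(x$w_plus), x$beta, x$sigma
  ))
  invisible(x)
}

#' Resolve the Gaussian bandwidth for a dataset
#'
#' The `median_distance` policy takes the median of the off-diagonal
#' pairwise Euclidean distances of the expression rows — deterministic and
#' scale-adaptive.  A fixed numeric value is passed through unchanged.
#'
#' @param dataset a [time_series_dataset()].
#' @param sigma_policy `"median_distance"` or a positive number.
#' @return positive scalar bandwidth.
#' @export
resolve_sigma <- function(dataset, sigma_policy = "median_distance") {
  if (is.numeric(sigma_policy)) {
    if (sigma_policy <= 0) stop("fixed sigma must be strictly positive")
    return(as.numeric(sigma_policy))
  }
  if (!identical(sigma_policy, "median_distance")) {
    stop("sigma_policy must be \"median_distance\" or a positive number")
  }
  d2 <- pairwise_sq_distances(dataset$expression)
  d <- sqrt(d2[upper.tri(d2)])
  s <- stats::median(d)
  if (!is.finite(s) || s <= 0) {
    stop("median pairwise distance is zero; supply a fixed sigma")
  }
  s
}
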
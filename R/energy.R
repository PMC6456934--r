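#' TSEE pseudo-potential energy
#'
#' Evaluates
#' \deqn{E[X; \lambda, \beta] = \sum_{n,m} w^P_{nm} \|x_n - x_m\|^2
#'   + \lambda \sum_{n,m} (w^N_{nm} + \beta t_{nm})
#'     \exp(-\|x_n - x_m\|^2),}
#' the elastic-embedding energy with the additional temporal repulsive
#' weight \eqn{\beta t_{nm}}.  Both sums run over all ordered pairs
#' \eqn{n \ne m}; the gradient in [tsee_gradient()] uses the same
#' convention.  Note \eqn{t_{nm}} already carries the shared normalizer
#' \eqn{N^-} (which itself involves \eqn{\beta}) and is multiplied by
#' \eqn{\beta} again here, exactly as the energy is written.
#'
#' @param X numeric N x d coordinate matrix.
#' @param model an [build_affinities()] result.
#' @param lam non-negative trade-off between attraction and repulsion.
#' @return non-negative scalar energy.
#' @export
tsee_energy <- function(X, model, lam = 10) {
  X <- as.matrix(X)
  check_energy_args(X, model, lam)
  d2x <- pairwise_sq_distances(X)
  rep_w <- model$w_minus + model$beta * model$t_side
  sum(model$w_plus * d2x) + lam * sum(rep_w * exp(-d2x))
}

check_energy_args <- function(X, model, lam) {
  if (!inherits(model, "affinity_model")) stop("model must be an affinity_model")
  if (nrow(X) != nrow(model$w_plus)) {
    stop("X has ", nrow(X), " rows but the affinity model holds ",
         nrow(model$w_plus), " cells")
  }
  if (!is.numeric(lam) || length(lam) != 1L || lam < 0) {
    stop("lam must be a single non-negative number")
  }
  invisible(TRUE)
}

#' Combined signed graph Laplacian of the TSEE energy
#'
#' The gradient of the energy factors through the Laplacian `L = D - W` of
#' the combined, X-dependent weight matrix
#' \deqn{w_{nm} = w^P_{nm} - \lambda (w^N_{nm} + \beta t_{nm})
#'   \exp(-\|x_n - x_m\|^2),}
#' where `D` is the diagonal of row sums.  `L` is symmetric with zero row
#' sums; it is generally indefinite because `W` is signed.
#'
#' @inheritParams tsee_energy
#' @return N x N symmetric matrix with zero row sums.
#' @export
combined_laplacian <- function(X, model, lam = 10) {
  X <- as.matrix(X)
  check_energy_args(X, model, lam)
  d2x <- pairwise_sq_distances(X)
  W <- model$w_plus - lam * (model$w_minus + model$beta * model$t_side) * exp(-d2x)
  diag(W) <- 0
  graph_laplacian(W)
}

graph_laplacian <- function(W) {
  L <- -W
  diag(L) <- diag(L) + rowSums(W)
  L
}

#' Gradient of the TSEE energy
#'
#' `4 L X` with `L` from [combined_laplacian()], matching the ordered-pair
#' energy convention of [tsee_energy()] (each unordered pair appears twice
#' in the energy, hence the factor 4 rather than 2).
#'
#' @inheritParams tsee_energy
#' @return N x d gradient matrix.
#' @export
tsee_gradient <- function(X, model, lam = 10) {
  X <- as.matrix(X)
  4 * combined_laplacian(X, model, lam) %*% X
}
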
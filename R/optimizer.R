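#' Embedding configuration
#'
#' Collects every tunable of [fit_tsee()].  Defaults follow the method's
#' recommended settings: `lam = beta = 10`, two embedding dimensions, a
#' global median-distance Gaussian bandwidth, deterministic PCA
#' initialization, and a backtracking (Armijo) line search.
#'
#' @param lam non-negative attraction/repulsion trade-off (lambda).
#' @param beta non-negative weight of the temporal repulsive term.
#' @param dim target dimensionality d.
#' @param sigma_policy `"median_distance"` or a positive number (fixed
#'   bandwidth).
#' @param init_policy `"pca"` (first d principal-component scores, columns
#'   rescaled to variance 1 then multiplied by 1e-2) or `"random"`
#'   (i.i.d. Gaussian with sd 1e-4, driven by `seed`).
#' @param seed integer seed for randomized initialization.
#' @param max_iter iteration cap.
#' @param step_tol convergence threshold on the relative Frobenius
#'   displacement `||X_{k+1} - X_k||_F / max(1, ||X_k||_F)`.
#' @param armijo_c sufficient-decrease constant in (0, 1).
#' @param armijo_shrink backtracking shrink factor in (0, 1).
#' @param armijo_alpha0 initial trial step of the first iteration.
#' @return list of class `"embedding_config"`.
#' @export
embedding_config <- function(lam = 10, beta = 10, dim = 2,
                             sigma_policy = "median_distance",
                             init_policy = c("pca", "random"),
                             seed = 1L, max_iter = 500L, step_tol = 1e-6,
                             armijo_c = 1e-4, armijo_shrink = 0.5,
                             armijo_alpha0 = 1.0) {
  init_policy <- match.arg(init_policy)
  stopifnot(
    lam >= 0, beta >= 0, dim >= 1, max_iter >= 1, step_tol > 0,
    armijo_c > 0, armijo_c < 1, armijo_shrink > 0, armijo_shrink < 1,
    armijo_alpha0 > 0
  )
  if (is.numeric(sigma_policy) && sigma_policy <= 0) {
    stop("fixed sigma must be strictly positive")
  }
  structure(
    list(
      lam = lam, beta = beta, dim = as.integer(dim),
      sigma_policy = sigma_policy, init_policy = init_policy,
      seed = as.integer(seed), max_iter = as.integer(max_iter),
      step_tol = step_tol, armijo_c = armijo_c,
      armijo_shrink = armijo_shrink, armijo_alpha0 = armijo_alpha0
    ),
    class = "embedding_config"
  )
}

#' Factor the attractive Laplacian for the spectral direction
#'
#' The partial-Hessian optimizer replaces the full (indefinite) Hessian by
#' the attractive Hessian \eqn{B = L^P \otimes I_d + \mu I}, where
#' \eqn{L^P} is the Laplacian of the attractive weights.  Because of the
#' Kronecker structure, solving `B p = -g` reduces to d independent solves
#' against `(L^P + mu I)`, so one Cholesky factorization is reused for the
#' whole fit.  The jitter is `mu = 1e-10 * max(diag(L^P))`: a positive,
#' scale-aware shift that makes the semidefinite Laplacian strictly
#' positive definite.
#'
#' @param model an [build_affinities()] result.
#' @return list of class `"optimizer_state"` with the upper-triangular
#'   Cholesky factor, `mu`, `iteration` counter and `warm_alpha`.
#' @export
attractive_laplacian_factor <- function(model) {
  stopifnot(inherits(model, "affinity_model"))
  lp <- graph_laplacian(model$w_plus)
  mu <- 1e-10 * max(diag(lp))
  if (!is.finite(mu) || mu <= 0) {
    stop("attractive Laplacian has no positive diagonal; affinities degenerate")
  }
  shifted <- lp
  diag(shifted) <- diag(shifted) + mu
  fac <- tryCatch(chol(shifted), error = function(e) {
    stop("Cholesky factorization of (L^P + mu I) failed; ",
         "try a larger jitter mu (current mu = ", format(mu), ")")
  })
  structure(
    list(factorization = fac, mu = mu, iteration = 0L, warm_alpha = 1.0),
    class = "optimizer_state"
  )
}

#' Spectral search direction
#'
#' Solves `(L^P + mu I) p_col = -g_col` for each coordinate column via the
#' cached Cholesky factor.  Since the system matrix is positive definite,
#' the returned direction satisfies `<p, g> < 0` whenever `g != 0`.
#'
#' @param state an [attractive_laplacian_factor()] result.
#' @param gradient N x d gradient matrix.
#' @return N x d descent direction.
#' @export
spectral_direction <- function(state, gradient) {
  stopifnot(inherits(state, "optimizer_state"))
  gradient <- as.matrix(gradient)
  if (any(!is.finite(gradient))) stop("non-finite gradient")
  R <- state$factorization
  y <- backsolve(R, -gradient, transpose = TRUE)
  backsolve(R, y)
}

# Generic Armijo backtracking on an arbitrary scalar energy functional.
# Returns list(alpha, X_new, E_new, stalled). alpha = 0 with X unchanged
# signals a stall (no sufficient decrease above the 1e-14 step floor).
armijo_backtrack <- function(energy_fn, X, p, g, E0,
                             c = 1e-4, shrink = 0.5, alpha0 = 1.0) {
  gp <- sum(g * p)
  if (gp >= 0) stop("p is not a descent direction (<p, g> >= 0)")
  alpha <- alpha0
  while (alpha >= 1e-14) {
    X_new <- X + alpha * p
    E_new <- energy_fn(X_new)
    if (is.finite(E_new) && E_new <= E0 + c * alpha * gp) {
      return(list(alpha = alpha, X_new = X_new, E_new = E_new, stalled = FALSE))
    }
    alpha <- alpha * shrink
  }
  list(alpha = 0, X_new = X, E_new = E0, stalled = TRUE)
}

#' One Armijo line-search step of the TSEE energy
#'
#' Backtracks from `warm_alpha`, shrinking by `config$armijo_shrink`, until
#' the sufficient-decrease condition
#' `E(X + alpha p) <= E(X) + c * alpha * <g, p>` holds.  If the step
#' underflows below 1e-14 the search reports a stall (`alpha = 0`, `X`
#' unchanged), which [fit_tsee()] treats as convergence.
#'
#' @param X current N x d iterate.
#' @param p descent direction.
#' @param g gradient at `X`.
#' @param model affinity model.
#' @param lam energy trade-off.
#' @param config an [embedding_config()].
#' @param warm_alpha first trial step size.
#' @return list with `alpha`, `X_new`, `E_new`, `stalled`.
#' @export
armijo_step <- function(X, p, g, model, lam, config, warm_alpha = 1.0) {
  armijo_backtrack(
    function(Z) tsee_energy(Z, model, lam),
    X, p, g, tsee_energy(X, model, lam),
    c = config$armijo_c, shrink = config$armijo_shrink, alpha0 = warm_alpha
  )
}

init_coordinates <- function(dataset, config) {
  n <- n_cells(dataset)
  d <- config$dim
  if (config$init_policy == "pca") {
    pc <- stats::prcomp(dataset$expression, center = TRUE, scale. = FALSE)
    k <- min(d, ncol(pc$x))
    X <- matrix(0, n, d)
    scores <- pc$x[, seq_len(k), drop = FALSE]
    for (j in seq_len(k)) {
      s <- stats::sd(scores[, j])
      X[, j] <- if (s > 0) scores[, j] / s * 1e-2 else 0
    }
    # deterministic sign: largest-|.| score positive
    for (j in seq_len(d)) {
      i <- which.max(abs(X[, j]))
      if (length(i) && X[i, j] < 0) X[, j] <- -X[, j]
    }
    X
  } else {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(config$seed)
    matrix(stats::rnorm(n * d, sd = 1e-4), n, d)
  }
}

#' Fit a time series elastic embedding
#'
#' Resolves the bandwidth, builds the affinities once (they depend only on
#' the input expression and times, not on the embedding), initializes the
#' coordinates, factorizes the attractive Laplacian once, and iterates
#' gradient, spectral direction and Armijo line search until the relative
#' Frobenius displacement drops below `config$step_tol` or `max_iter` is
#' reached.  The accepted-energy trace is non-increasing by construction.
#' The whole procedure is deterministic given `(dataset, config,
#' side_distance)`.
#'
#' @param dataset a [time_series_dataset()].
#' @param config an [embedding_config()].
#' @param side_distance optional replacement for the time-interval side
#'   matrix, forwarded to [build_affinities()].
#' @return An object of class `"embedding_result"`: list with
#'   `coordinates` (N x d), `energy_trace` (initial energy plus one entry
#'   per accepted iterate), `n_iterations`, `converged`, `sigma`,
#'   `config_used`, and the stage annotation copied from the dataset.
#' @export
#' @examples
#' sim <- simulate_timecourse(synthetic_config(n_cells = 60, seed = 1))
#' fit <- fit_tsee(sim$dataset, embedding_config(max_iter = 50))
#' plot(fit$coordinates, col = sim$dataset$stage_index)
fit_tsee <- function(dataset, config = embedding_config(), side_distance = NULL) {
  stopifnot(inherits(dataset, "time_series_dataset"),
            inherits(config, "embedding_config"))
  n <- n_cells(dataset)
  if (n < 2L) stop("need at least 2 cells")
  if (n > 10000L) {
    warning("dense affinities above 10,000 cells: expect O(N^2) memory/time")
  }

  sigma <- resolve_sigma(dataset, config$sigma_policy)
  model <- build_affinities(dataset, beta = config$beta, sigma = sigma,
                            side_distance = side_distance)
  state <- attractive_laplacian_factor(model)
  X <- init_coordinates(dataset, config)

  energy <- tsee_energy(X, model, config$lam)
  trace <- energy
  warm_alpha <- config$armijo_alpha0
  converged <- FALSE
  iter <- 0L

  while (iter < config$max_iter) {
    iter <- iter + 1L
    g <- tsee_gradient(X, model, config$lam)
    gnorm <- sqrt(sum(g^2))
    if (gnorm == 0) { converged <- TRUE; break }
    p <- spectral_direction(state, g)
    step <- armijo_backtrack(
      function(Z) tsee_energy(Z, model, config$lam),
      X, p, g, energy,
      c = config$armijo_c, shrink = config$armijo_shrink, alpha0 = warm_alpha
    )
    if (step$stalled) { converged <- TRUE; break }
    disp <- sqrt(sum((step$X_new - X)^2)) / max(1, sqrt(sum(X^2)))
    X <- step$X_new
    energy <- step$E_new
    trace <- c(trace, energy)
    warm_alpha <- min(step$alpha * 2, 1e2)
    if (disp < config$step_tol) { converged <- TRUE; break }
  }

  structure(
    list(
      coordinates = X,
      energy_trace = trace,
      n_iterations = iter,
      converged = converged,
      sigma = sigma,
      config_used = config,
      stage_time = dataset$stage_time,
      stage_index = dataset$stage_index,
      cell_ids = dataset$cell_ids
    ),
    class = "embedding_result"
  )
}

#' @export
print.embedding_result <- function(x, ...) {
  cat(sprintf(
    "embedding_result: %d cells in %d-D, %d iterations (%s), final energy %.6g\n",
    nrow(x$coordinates), ncol(x$coordinates), x$n_iterations,
    if (x$converged) "converged" else "max_iter reached",
    x$energy_trace[length(x$energy_trace)]
  ))
  invisible(x)
}
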
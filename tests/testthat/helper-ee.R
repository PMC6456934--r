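# Independent plain elastic-embedding (no temporal term) reference fit.
# Written against the published EE objective directly: loop-based energy
# and pairwise-force gradient, dense solve() for the search direction.
# Used to check that the packaged optimizer with beta = 0 reproduces EE
# energies iteration by iteration.

reference_ee_fit <- function(Y, sigma, lam, dim = 2, max_iter = 50,
                             step_tol = 1e-6, c_armijo = 1e-4,
                             shrink = 0.5, alpha0 = 1.0) {
  n <- nrow(Y)
  wp <- matrix(0, n, n); wm <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d2 <- sum((Y[i, ] - Y[j, ])^2)
    wp[i, j] <- exp(-d2 / (2 * sigma^2))
    wm[i, j] <- sqrt(d2)
  }
  wp <- wp / sum(wp)
  wm <- wm / sum(wm)

  energy <- function(X) {
    acc <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      d2 <- sum((X[i, ] - X[j, ])^2)
      acc <- acc + wp[i, j] * d2 + lam * wm[i, j] * exp(-d2)
    }
    acc
  }
  gradient <- function(X) {
    g <- X * 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      diff <- X[i, ] - X[j, ]
      d2 <- sum(diff^2)
      g[i, ] <- g[i, ] + 4 * (wp[i, j] - lam * wm[i, j] * exp(-d2)) * diff
    }
    g
  }

  # same deterministic initialization as the package's pca policy
  pc <- stats::prcomp(Y, center = TRUE, scale. = FALSE)
  k <- min(dim, ncol(pc$x))
  X <- matrix(0, n, dim)
  for (j in seq_len(k)) {
    s <- stats::sd(pc$x[, j])
    X[, j] <- if (s > 0) pc$x[, j] / s * 1e-2 else 0
  }
  for (j in seq_len(dim)) {
    i <- which.max(abs(X[, j]))
    if (length(i) && X[i, j] < 0) X[, j] <- -X[, j]
  }

  lp <- diag(rowSums(wp)) - wp
  mu <- 1e-10 * max(diag(lp))
  B <- lp + diag(mu, n)

  E <- energy(X)
  trace <- E
  warm <- alpha0
  for (k_it in seq_len(max_iter)) {
    g <- gradient(X)
    if (sqrt(sum(g^2)) == 0) break
    p <- solve(B, -g)
    gp <- sum(g * p)
    alpha <- warm
    accepted <- FALSE
    while (alpha >= 1e-14) {
      Xn <- X + alpha * p
      En <- energy(Xn)
      if (is.finite(En) && En <= E + c_armijo * alpha * gp) {
        accepted <- TRUE
        break
      }
      alpha <- alpha * shrink
    }
    if (!accepted) break
    disp <- sqrt(sum((Xn - X)^2)) / max(1, sqrt(sum(X^2)))
    X <- Xn; E <- En
    trace <- c(trace, E)
    warm <- min(alpha * 2, 1e2)
    if (disp < step_tol) break
  }
  list(coordinates = X, energy_trace = trace)
}
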
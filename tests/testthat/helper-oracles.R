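# Independent brute-force oracles. Everything here is written as literal
# double loops over the definitions, deliberately avoiding the package's
# vectorized code paths.

naive_sq_distances <- function(points) {
  n <- nrow(points)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    out[i, j] <- sum((points[i, ] - points[j, ])^2)
  }
  out
}

# Eq.-style energy: full ordered double sum over n != m.
naive_energy <- function(X, w_plus, w_minus, t_side, beta, lam) {
  n <- nrow(X)
  acc <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d2 <- sum((X[i, ] - X[j, ])^2)
    acc <- acc + w_plus[i, j] * d2 +
      lam * (w_minus[i, j] + beta * t_side[i, j]) * exp(-d2)
  }
  acc
}

# Hand-built affinities from printed formulas, double loop.
naive_affinities <- function(Y, stage_time, beta, sigma, side = NULL) {
  n <- nrow(Y)
  wp <- matrix(0, n, n); wm <- matrix(0, n, n); ts <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d2 <- sum((Y[i, ] - Y[j, ])^2)
    wp[i, j] <- exp(-d2 / (2 * sigma^2))
    wm[i, j] <- sqrt(d2)
    ts[i, j] <- if (is.null(side)) abs(stage_time[i] - stage_time[j]) else side[i, j]
  }
  nplus <- 1 / sum(wp)
  nminus <- 1 / (sum(wm) + beta * sum(ts))
  list(w_plus = wp * nplus, w_minus = wm * nminus, t_side = ts * nminus)
}

# Central finite differences of a scalar function of a matrix.
finite_diff_gradient <- function(f, X, h = 1e-5) {
  g <- X * 0
  for (i in seq_len(nrow(X))) for (j in seq_len(ncol(X))) {
    Xp <- X; Xp[i, j] <- Xp[i, j] + h
    Xm <- X; Xm[i, j] <- Xm[i, j] - h
    g[i, j] <- (f(Xp) - f(Xm)) / (2 * h)
  }
  g
}

naive_nearest_neighbor <- function(X) {
  n <- nrow(X)
  out <- integer(n)
  for (i in seq_len(n)) {
    best <- Inf; best_j <- NA_integer_
    for (j in seq_len(n)) {
      if (j == i) next
      d <- sqrt(sum((X[i, ] - X[j, ])^2))
      if (d < best) { best <- d; best_j <- j }
    }
    out[i] <- best_j
  }
  out
}

naive_igp <- function(X, group) {
  nn <- naive_nearest_neighbor(X)
  groups <- sort(unique(group))
  out <- numeric(length(groups)); names(out) <- as.character(groups)
  for (u in groups) {
    members <- which(group == u)
    hits <- sum(vapply(members, function(j) {
      group[j] == u && group[nn[j]] == u
    }, logical(1)))
    out[as.character(u)] <- hits / length(members)
  }
  out
}

naive_igp2 <- function(X, stage) {
  nn <- naive_nearest_neighbor(X)
  stages <- sort(unique(stage))
  out <- numeric(length(stages)); names(out) <- as.character(stages)
  for (u in stages) {
    members <- which(stage == u)
    hits <- sum(vapply(members, function(j) {
      abs(stage[j] - stage[nn[j]]) <= 1
    }, logical(1)))
    out[as.character(u)] <- hits / length(members)
  }
  out
}

# Exhaustive complete-linkage agglomeration over points; returns the
# sorted merge heights.
naive_complete_linkage_heights <- function(points) {
  clusters <- lapply(seq_len(nrow(points)), identity)
  d <- function(a, b) {
    m <- -Inf
    for (i in a) for (j in b) {
      m <- max(m, sqrt(sum((points[i, ] - points[j, ])^2)))
    }
    m
  }
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- Inf; bi <- 1L; bj <- 2L
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dij <- d(clusters[[i]], clusters[[j]])
      if (dij < best) { best <- dij; bi <- i; bj <- j }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  sort(heights)
}

# Small deterministic dataset fixture for unit tests.
make_test_dataset <- function(n = 20, g = 6, n_stages = 4, seed = 42) {
  set.seed(seed)
  t <- sort(runif(n))
  stage <- pmin(n_stages, 1L + as.integer(floor(t * n_stages)))
  stage <- match(stage, sort(unique(stage)))  # consecutive, all non-empty
  expr <- matrix(runif(n * g), n, g)
  time_series_dataset(
    expr,
    stage_time = if (max(stage) > 1) (stage - 1) / (max(stage) - 1) else rep(0, n),
    stage_index = stage
  )
}
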
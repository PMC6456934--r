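#' Synthetic time-course configuration
#'
#' Parameters of the generative model in [simulate_timecourse()].  The
#' defaults describe a moderate 5-stage developmental time course: 300
#' cells along a 1-D latent progression, 50 genes of which 5 oscillate
#' three times over the course, a stage-specific additive batch shift, and
#' light i.i.d. measurement noise (a tenth of the expression dynamic
#' range).  Raising `noise_sd` toward the dynamic range makes stages
#' overlap in expression space — the regime where a purely
#' expression-driven embedding loses stage resolution while the temporal
#' repulsive term retains it.  Note that the per-stage shift alone acts as
#' a stage fingerprint: it scrambles the global stage ordering but makes
#' stages *more* separable locally, so stage overlap is governed by
#' `noise_sd`, not `batch_shift_sd`.
#'
#' @param n_cells number of cells.
#' @param n_stages number of collection stages (>= 2); stage membership is
#'   binned latent time.
#' @param n_genes number of genes.
#' @param n_oscillatory number of genes with sinusoidal (periodic in
#'   latent time) mean profiles; the rest are smooth monotone (sigmoid) or
#'   unimodal (Gaussian bump) trajectory genes.
#' @param n_periods oscillation cycles across the whole time course.
#' @param batch_shift_sd sd of the per-stage additive shift applied to all
#'   cells of a stage — the batch-like confound the temporal repulsive
#'   term is designed to dilute.
#' @param noise_sd sd of i.i.d. Gaussian measurement noise.
#' @param seed integer RNG seed; the full output is reproducible from it.
#' @return list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_cells = 300L, n_stages = 5L, n_genes = 50L,
                             n_oscillatory = 5L, n_periods = 3,
                             batch_shift_sd = 0.2, noise_sd = 0.1,
                             seed = 1L) {
  stopifnot(
    n_cells >= 1, n_stages >= 2, n_cells >= n_stages, n_genes >= 1,
    n_oscillatory >= 0, n_oscillatory <= n_genes, n_periods > 0,
    batch_shift_sd >= 0, noise_sd >= 0
  )
  structure(
    list(
      n_cells = as.integer(n_cells), n_stages = as.integer(n_stages),
      n_genes = as.integer(n_genes), n_oscillatory = as.integer(n_oscillatory),
      n_periods = n_periods, batch_shift_sd = batch_shift_sd,
      noise_sd = noise_sd, seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' Mean profile of an oscillatory gene
#'
#' `(sin(2 * pi * n_periods * t + phase) + 1) / 2`: a sinusoid in latent
#' time rescaled to \[0, 1\], with exactly `n_periods` cycles over
#' `t` in \[0, 1\].
#'
#' @param t latent time in \[0, 1\].
#' @param n_periods cycles over the unit interval.
#' @param phase phase offset in radians.
#' @return numeric vector in \[0, 1\].
#' @export
oscillatory_profile <- function(t, n_periods, phase = 0) {
  (sin(2 * pi * n_periods * t + phase) + 1) / 2
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate a multi-stage single-cell time course
#'
#' Draws a latent 1-D developmental time for each cell, assigns stages by
#' binning latent time into `n_stages` equal-width intervals, and builds
#' gene expression as smooth functions of latent time: oscillatory genes
#' follow [oscillatory_profile()] with a random phase; the remaining genes
#' are random sigmoids (monotone up or down) or Gaussian bumps (unimodal).
#' Every cell of a stage then receives the same additive Gaussian shift
#' vector (sd `batch_shift_sd`) — a stage-confounded distortion — plus
#' i.i.d. Gaussian noise.  The final matrix is globally min-max scaled
#' into \[0, 1\].
#'
#' @param config a [synthetic_config()].
#' @return An object of class `"synthetic_dataset"`: list with
#'   `dataset` (a ready-to-embed [time_series_dataset()]), `raw` (the
#'   unscaled matrix, suitable as [preprocess_pipeline()] input),
#'   `latent_time` (ground truth in \[0, 1\]), `oscillatory_gene_ids`,
#'   `batch_shifts` (n_stages x n_genes), and `config`.
#' @export
#' @examples
#' sim <- simulate_timecourse(synthetic_config(n_cells = 100, seed = 7))
#' table(sim$dataset$stage_index)
simulate_timecourse <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_local_seed(config$seed, {
    n <- config$n_cells
    g <- config$n_genes
    latent <- stats::runif(n)
    stage_index <- pmin(config$n_stages, 1L + as.integer(floor(latent * config$n_stages)))
    # ensure every stage has at least one cell: nudge one cell per empty bin
    for (u in seq_len(config$n_stages)) {
      if (!any(stage_index == u)) {
        j <- which.min(abs(latent - (u - 0.5) / config$n_stages))
        latent[j] <- (u - 0.5) / config$n_stages
        stage_index[j] <- u
      }
    }
    stage_time <- (stage_index - 1) / (config$n_stages - 1)

    osc_ids <- seq_len(config$n_oscillatory)
    profiles <- matrix(0, n, g)
    for (j in seq_len(g)) {
      if (j %in% osc_ids) {
        phase <- stats::runif(1, 0, 2 * pi)
        profiles[, j] <- oscillatory_profile(latent, config$n_periods, phase)
      } else if (stats::runif(1) < 0.5) {
        k <- sample(c(-1, 1), 1) * stats::runif(1, 5, 15)
        t0 <- stats::runif(1, 0.2, 0.8)
        profiles[, j] <- 1 / (1 + exp(-k * (latent - t0)))
      } else {
        t0 <- stats::runif(1, 0.1, 0.9)
        s <- stats::runif(1, 0.08, 0.25)
        profiles[, j] <- exp(-(latent - t0)^2 / (2 * s^2))
      }
    }

    shifts <- matrix(stats::rnorm(config$n_stages * g, sd = config$batch_shift_sd),
                     config$n_stages, g)
    noise <- matrix(stats::rnorm(n * g, sd = config$noise_sd), n, g)
    raw <- profiles + shifts[stage_index, , drop = FALSE] + noise
    rownames(raw) <- paste0("cell_", seq_len(n))
    colnames(raw) <- paste0("gene_", seq_len(g))

    scaled <- if (max(raw) > min(raw)) minmax_normalize(raw) else raw
    ds <- time_series_dataset(
      scaled, stage_time = stage_time, stage_index = stage_index,
      cell_ids = rownames(raw), feature_ids = colnames(raw)
    )
    structure(
      list(
        dataset = ds,
        raw = raw,
        latent_time = latent,
        oscillatory_gene_ids = osc_ids,
        batch_shifts = shifts,
        config = config
      ),
      class = "synthetic_dataset"
    )
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic_dataset: %d cells, %d genes (%d oscillatory), %d stages, seed %d\n",
    x$config$n_cells, x$config$n_genes, x$config$n_oscillatory,
    x$config$n_stages, x$config$seed
  ))
  invisible(x)
}

#' Correlation of an embedding's principal axis with the true latent time
#'
#' Projects the embedded coordinates onto their first principal axis,
#' orients the axis so the correlation with the ground-truth latent time
#' is non-negative, and returns the Pearson correlation — a desk-scale
#' analogue of correlating computed pseudotime with experimental time.
#'
#' @param result an `embedding_result` or an N x d coordinate matrix.
#' @param truth a `synthetic_dataset` (or a numeric latent-time vector).
#' @return scalar in \[0, 1\] (the orientation step folds the sign).
#' @export
ground_truth_pcc <- function(result, truth) {
  X <- if (inherits(result, "embedding_result")) result$coordinates else as.matrix(result)
  latent <- if (inherits(truth, "synthetic_dataset")) truth$latent_time else as.numeric(truth)
  if (nrow(X) != length(latent)) stop("embedding and truth sizes differ")
  if (all(apply(X, 2, stats::sd) == 0)) stop("degenerate embedding: zero variance")
  pc1 <- stats::prcomp(X, center = TRUE, scale. = FALSE)$x[, 1]
  if (stats::sd(pc1) == 0) stop("degenerate embedding: zero variance along PC1")
  r <- pearson_correlation(pc1, latent)
  abs(r)
}
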
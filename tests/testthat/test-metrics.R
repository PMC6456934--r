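test_that("nearest neighbors match geometry and the brute-force search", {
  X <- matrix(c(0, 1, 10), ncol = 1)
  expect_identical(nearest_neighbor_index(X), c(2L, 1L, 2L))

  # coincident points are mutual nearest neighbors
  Y <- matrix(c(0, 0, 5, 9, 0, 0, 5, 9), ncol = 2)
  nn <- nearest_neighbor_index(Y)
  expect_identical(nn[1], 2L)
  expect_identical(nn[2], 1L)

  set.seed(20)
  Z <- matrix(rnorm(40), 20, 2)
  expect_identical(nearest_neighbor_index(Z), naive_nearest_neighbor(Z))
})

test_that("IGP is 1 for separated clusters and 0 for singletons", {
  X <- rbind(matrix(rnorm(10, 0, 0.1), 5, 2),
             matrix(rnorm(10, 10, 0.1), 5, 2))
  g <- rep(c("a", "b"), each = 5)
  expect_equal(unname(igp(X, g)), c(1, 1))

  Xs <- rbind(X, c(20, 20))
  expect_equal(unname(igp(Xs, c(g, "solo"))["solo"]), 0,
               ignore_attr = TRUE)
})

test_that("IGP and IGP2 match their literal definitions on random instances", {
  set.seed(21)
  for (rep in 1:5) {
    X <- matrix(rnorm(30), 15, 2)
    stage <- sort(sample(1:4, 15, replace = TRUE))
    stage <- match(stage, sort(unique(stage)))  # consecutive
    expect_equal(igp(X, stage), naive_igp(X, stage))
    expect_equal(igp2(X, stage), naive_igp2(X, stage))
    expect_true(all(igp2(X, stage) >= igp(X, stage)))
  }
})

test_that("IGP2 relaxes IGP for adjacent stages", {
  # one stage only: every neighbor is within distance 0 of the label
  X <- matrix(rnorm(12), 6, 2)
  expect_equal(unname(igp2(X, rep(1L, 6))), 1)

  # a singleton stage whose neighbor sits in the adjacent stage
  X2 <- rbind(c(0, 0), c(0.1, 0), matrix(rnorm(8, 10), 4, 2))
  s2 <- c(1L, 2L, 3L, 3L, 3L, 3L)
  expect_equal(unname(igp(X2, s2)[1]), 0)
  expect_equal(unname(igp2(X2, s2)[1]), 1)
  expect_error(igp2(X2, c(1.5, 2, 3, 3, 3, 3)), "integer")
  expect_error(igp2(X2, c(1L, 3L, 4L, 4L, 4L, 4L)), "consecutive")
})

test_that("IGP family is invariant under rigid motion and uniform scaling", {
  set.seed(22)
  X <- matrix(rnorm(40), 20, 2)
  stage <- sort(rep(1:4, 5))
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  Xt <- 3.7 * X %*% R + matrix(c(5, -2), 20, 2, byrow = TRUE)
  expect_equal(igp(Xt, stage), igp(X, stage))
  expect_equal(igp2(Xt, stage), igp2(X, stage))
})

test_that("weighted mean IGP is the size-weighted average", {
  expect_equal(weighted_mean_igp(c(a = 0.5, b = 0.7), c(a = 3, b = 3)), 0.6)
  n <- 10
  expect_equal(
    weighted_mean_igp(c(big = 1, solo = 0), c(big = n - 1, solo = 1)),
    (n - 1) / n
  )
  set.seed(23)
  sc <- runif(4); names(sc) <- letters[1:4]
  sz <- sample(1:9, 4); names(sz) <- letters[1:4]
  expect_equal(weighted_mean_igp(sc, sz), sum(sc * sz) / sum(sz))
  expect_gte(weighted_mean_igp(sc, sz), min(sc))
  expect_lte(weighted_mean_igp(sc, sz), max(sc))
  expect_error(weighted_mean_igp(numeric(0), numeric(0)), "empty")
  expect_error(weighted_mean_igp(c(a = 1), c(b = 1)), "names")
})

test_that("pearson correlation matches the textbook formula and guards variance", {
  a <- c(1, 2, 4, 7)
  b <- c(2, 1, 5, 9)
  ref <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_correlation(a, b), ref)
  expect_equal(pearson_correlation(a, a), 1)
  expect_equal(pearson_correlation(a, -a), -1)
  expect_error(pearson_correlation(a, rep(1, 4)), "variance")
})

test_that("misplaced cells are the >= 2-stage-away complement of IGP2", {
  # stage-sorted line: nobody is misplaced
  X <- matrix(seq(0, 10, length.out = 12), ncol = 1)
  stage <- rep(1:4, each = 3)
  expect_false(any(misplaced_cells(X, stage)))

  # a stage-1 cell planted inside the stage-4 cluster is flagged
  X2 <- rbind(matrix(1:9 / 10, ncol = 1), 8, 8.01, 8.02)
  s2 <- c(rep(1L, 3), rep(2L, 3), rep(3L, 3), 4L, 4L, 4L)
  X2[2, 1] <- 8.005
  expect_true(misplaced_cells(X2, s2)[2])

  set.seed(24)
  for (rep in 1:5) {
    Z <- matrix(rnorm(50), 25, 2)
    sz <- sort(sample(1:5, 25, replace = TRUE))
    sz <- match(sz, sort(unique(sz)))
    flagged <- misplaced_cells(Z, sz)
    frac <- vapply(split(flagged, sz), mean, numeric(1))
    expect_equal(unname(frac), unname(1 - igp2(Z, sz)))
  }
})

test_that("stage-centroid complete linkage matches hand arithmetic and the oracle", {
  # collinear centroids at 0, 1, 10: merge {1,2} at 1, then all at 10
  X <- matrix(c(0, 1, 10), ncol = 1)
  tree <- stage_centroid_linkage(X, c(1L, 2L, 3L))
  expect_equal(tree$height, c(1, 10))

  # two stages: single merge at the centroid distance
  X2 <- rbind(c(0, 0), c(0, 2), c(4, 1), c(6, 1))
  tree2 <- stage_centroid_linkage(X2, c(1L, 1L, 2L, 2L))
  expect_equal(tree2$height, sqrt(sum((c(0, 1) - c(5, 1))^2)))

  set.seed(25)
  for (rep in 1:5) {
    cent <- matrix(rnorm(10), 5, 2)
    X3 <- cent[rep(1:5, each = 2), ] + 0  # two coincident cells per stage
    tree3 <- stage_centroid_linkage(X3, rep(1:5, each = 2))
    expect_equal(sort(tree3$height), naive_complete_linkage_heights(cent),
                 tolerance = 1e-10)
  }
})

test_that("metric_report bundles consistent values", {
  sim <- simulate_timecourse(synthetic_config(n_cells = 60, n_genes = 20,
                                              seed = 26))
  fit <- fit_tsee(sim$dataset, embedding_config(max_iter = 100))
  rep <- metric_report(fit, pseudotime = sim$latent_time)
  expect_equal(rep$weighted_mean_igp,
               weighted_mean_igp(rep$igp_per_group, rep$group_sizes))
  expect_true(all(rep$igp2_per_group >= rep$igp_per_group))
  expect_true(is.finite(rep$pcc_time))
  expect_identical(length(rep$misplaced_mask), 60L)
})
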
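test_that("the preprocessing grid enumerates 48 unique pipelines", {
  g <- pipeline_grid()
  expect_equal(nrow(g), 48)
  expect_equal(anyDuplicated(g$pipeline), 0L)
  expect_equal(length(scaler_names()), 6)
  expect_equal(length(measurement_names()), 4)
  expect_equal(length(metric_names()), 2)
})

test_that("scaling transforms satisfy their definitions", {
  set.seed(1)
  s <- make_sdf_set(matrix(rexp(5 * 501, 1 / 20), 5),
                    matrix(rexp(5 * 501, 1 / 20), 5))

  none <- scale_sdf(s, "none")
  expect_equal(none$stim, s$stim)
  expect_equal(none$sacc, s$sacc)

  zb <- scale_sdf(s, "z_baseline")
  bidx <- s$stim_time >= -200 & s$stim_time < -100
  for (i in 1:5) {
    expect_lt(abs(mean(zb$stim[i, bidx])), 1e-9)
    expect_equal(sd(zb$stim[i, bidx]), 1, tolerance = 1e-9)
  }

  zw <- scale_sdf(s, "z_whole")
  for (i in 1:5) {
    v <- c(zw$stim[i, ], zw$sacc[i, ])
    expect_lt(abs(mean(v)), 1e-9)
    expect_equal(sd(v), 1, tolerance = 1e-9)
  }

  mm <- scale_sdf(s, "minmax")
  expect_true(all(mm$stim >= 0 & mm$stim <= 1))
  pk <- scale_sdf(s, "peak_norm")
  expect_equal(unname(apply(cbind(pk$stim, pk$sacc), 1, max)), rep(1, 5))

  # degenerate baseline SD flags the unit instead of dividing by zero
  flat <- make_sdf_set(matrix(5, 2, 501), matrix(5, 2, 501))
  zf <- scale_sdf(flat, "z_baseline")
  expect_equal(attr(zf, "degenerate_units"), c("u1", "u2"))
  expect_true(all(zf$stim == 0))
})

test_that("measurements have the declared dimensions and values", {
  const <- make_sdf_set(matrix(7, 3, 501), matrix(7, 3, 501))
  m <- measure_features(const, "mean")
  expect_equal(dim(m), c(3, 6))
  expect_true(all(m == 7))
  sl <- measure_features(const, "slope")
  expect_true(all(sl == 0))
  ms <- measure_features(const, "mean_and_slope")
  expect_equal(ncol(ms), 12)
  expect_equal(colnames(ms)[1], "mean:baseline")
  expect_equal(colnames(ms)[7], "slope:baseline")
  sdfm <- measure_features(const, "sdf")
  expect_equal(ncol(sdfm), 1002)

  # linear ramp: slope equals the endpoint-window mean difference computed
  # directly on the ramp
  stim_time <- -200:300
  ramp_rate <- 10 / 50   # rises 10 spikes/s across a 50 ms epoch
  v <- 20 + ramp_rate * (stim_time - (-200))
  r <- make_sdf_set(matrix(v, 1, 501, byrow = TRUE),
                    matrix(20, 1, 501))
  sr <- measure_features(r, "slope")
  ep <- epoch_set()[epoch_set()$epoch == "early_visual", ]
  w1 <- v[stim_time >= ep$start & stim_time < ep$start + 10]
  w2 <- v[stim_time >= ep$end - 10 & stim_time < ep$end]
  expect_equal(unname(sr[1, "slope:early_visual"]), mean(w2) - mean(w1))
  expect_equal(unname(sr[1, "slope:early_visual"]),
               ramp_rate * (50 - 10), tolerance = 1e-9)

  # insufficient window coverage is an explicit error
  tiny <- make_sdf_set(matrix(1, 2, 101), matrix(1, 2, 501),
                       stim_time = -50:50)
  expect_error(measure_features(tiny, "mean"), "cover")
})

test_that("cross-sample z-scoring matches a two-pass oracle", {
  set.seed(4)
  X <- cbind(matrix(rnorm(60, sd = 5), 10), constant = rep(3, 10))
  Z <- zscore_across_sample(X)
  for (j in 1:6) {
    expect_lt(abs(mean(Z[, j])), 1e-9)
    expect_equal(sd(Z[, j]), 1, tolerance = 1e-9)
    expect_equal(Z[, j], (X[, j] - mean(X[, j])) / sd(X[, j]))
  }
  expect_true(all(Z[, 7] == 0))
  expect_error(zscore_across_sample(X[1, , drop = FALSE]), "2 units")
})

test_that("distance metrics satisfy their closed forms and axioms", {
  X <- rbind(a = c(0, 0), b = c(3, 4))
  expect_equal(unclass(pairwise_distance(X, "euclidean"))["a", "b"], 5)

  x <- c(1, 2, 3, 5)
  Y <- rbind(x = x, pos = 2 * x + 1, neg = -x)
  dc <- unclass(pairwise_distance(Y, "correlation"))
  expect_equal(dc["x", "pos"], 0, tolerance = 1e-12)
  expect_equal(dc["x", "neg"], 2, tolerance = 1e-12)

  # zero-variance rows are flagged and maximally distant
  Z <- rbind(flat = c(1, 1, 1), mod = c(1, 2, 3), mod2 = c(3, 1, 2))
  dz <- pairwise_distance(Z, "correlation")
  expect_equal(attr(dz, "flagged_units"), "flat")
  expect_equal(unclass(dz)["flat", "mod"], 2)
  expect_equal(diag(unclass(dz)), c(flat = 0, mod = 0, mod2 = 0))

  # triangle inequality and symmetry on random instances
  for (seed in 1:20) {
    set.seed(seed)
    F <- matrix(rnorm(8 * 5), 8)
    d <- unclass(pairwise_distance(F, "euclidean"))
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    for (i in 1:8) for (j in 1:8) for (k in 1:8) {
      expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-9)
    }
  }
  expect_error(pairwise_distance(matrix(c(1, NA, 2, 3), 2), "euclidean"),
               "missing")
})

test_that("per-unit affine scalers leave correlation distances unchanged", {
  set.seed(9)
  s <- make_sdf_set(matrix(rexp(8 * 501, 1 / 15), 8) + 2,
                    matrix(rexp(8 * 501, 1 / 15), 8) + 2)
  d1 <- pairwise_distance(measure_features(scale_sdf(s, "z_baseline"), "sdf"),
                          "correlation")
  d2 <- pairwise_distance(measure_features(scale_sdf(s, "z_whole"), "sdf"),
                          "correlation")
  expect_equal(unclass(d1), unclass(d2), tolerance = 1e-9)
})

test_that("the skewness index reflects cross-unit asymmetry", {
  sym <- make_sdf_set(matrix(rep(c(1, 2, 3), 501), 3, byrow = FALSE),
                      matrix(rep(c(1, 2, 3), 501), 3, byrow = FALSE))
  expect_equal(skewness_index(sym), 0, tolerance = 1e-12)

  set.seed(2)
  ln <- make_sdf_set(matrix(rlnorm(30 * 501, sdlog = 1), 30),
                     matrix(rlnorm(30 * 501, sdlog = 1), 30))
  expect_gt(skewness_index(ln), 0.5)
  expect_equal(skewness_index(ln),
               oracle_skewness_index(cbind(ln$stim, ln$sacc)),
               tolerance = 1e-12)

  expect_error(skewness_index(make_sdf_set(matrix(1, 2, 501),
                                           matrix(1, 2, 501))),
               "3 units")
})

test_that("the pipeline runner produces one matrix per grid row", {
  pop <- small_population()
  sdfs <- compute_sdf_set(pop)
  dists <- compute_pipeline_distances(sdfs)
  expect_length(dists, 48)
  expect_named(dists, pipeline_grid()$pipeline)
  for (d in dists[c(1, 25, 48)]) {
    expect_equal(unclass(d), t(unclass(d)))
    expect_true(all(diag(unclass(d)) == 0))
  }
})
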
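flat_sdf <- function(base = 10, vis = NULL, presacc = NULL, ramp_last20 = 0,
                     noise_seed = 1) {
  # baseline samples get SD 1 around `base`; epochs overridden as requested
  set.seed(noise_seed)
  stim_time <- -200:300
  sacc_time <- -300:200
  stim <- rep(base, 501)
  bidx <- stim_time >= -200 & stim_time < -100
  stim[bidx] <- base + scale(rnorm(sum(bidx)))[, 1]  # mean base, sd exactly 1
  if (!is.null(vis)) stim[stim_time >= 50 & stim_time < 150] <- vis
  sacc <- rep(base, 501)
  if (!is.null(presacc)) sacc[sacc_time >= -100 & sacc_time < 0] <- presacc
  if (ramp_last20 != 0) {
    idx <- sacc_time >= -20 & sacc_time < 0
    sacc[idx] <- sacc[idx] + seq(0, ramp_last20, length.out = sum(idx))
  }
  make_sdf(stim, sacc)
}

test_that("traditional criteria classify constructed profiles exactly", {
  expect_equal(classify_traditional(flat_sdf(10, vis = 20)), "visual")
  expect_equal(classify_traditional(flat_sdf(10, vis = 25, presacc = 25,
                                             ramp_last20 = 5)),
               "visuomovement")
  expect_equal(classify_traditional(flat_sdf(10, presacc = 25,
                                             ramp_last20 = 5)), "movement")
  # elevated but exactly flat presaccadic activity is delay, not movement
  expect_equal(classify_traditional(flat_sdf(10, presacc = 25)),
               "uncategorized")
  expect_equal(classify_traditional(flat_sdf(10)), "uncategorized")

  # zero baseline SD: classification impossible
  s <- make_sdf(rep(10, 501), rep(10, 501))
  expect_true(is.na(classify_traditional(s)))
  set_flat <- make_sdf_set(matrix(10, 2, 501), matrix(10, 2, 501))
  ct <- classify_traditional_set(set_flat)
  expect_equal(attr(ct, "flagged_units"), c("u1", "u2"))
  expect_true(all(ct$label == "uncategorized"))
})

test_that("RoV is zero for perfect categories and guards degenerate means", {
  tmean <- sin(seq(0, 4 * pi, length.out = 40))
  X <- rbind(tmean, tmean, tmean, 2 * tmean, 2 * tmean, 2 * tmean)
  rownames(X) <- paste0("u", 1:6)
  cat <- make_cat(c("a", "a", "a", "b", "b", "b"))
  r <- rov(cat, X)
  expect_equal(r$penalized, 0)
  expect_equal(r$n_categories, 2)

  # constant category mean: undefined ratio with a warning
  Xc <- rbind(X[1:3, ], matrix(5, 3, 40,
                               dimnames = list(paste0("u", 4:6), NULL)))
  expect_warning(rc <- rov(cat, Xc), "time-constant")
  expect_equal(rc$undefined_categories, "b")
  expect_equal(nrow(rc$per_category), 1)
})

test_that("RoV matches the explicit-loop oracle on random sets", {
  for (seed in 1:15) {
    set.seed(seed)
    n <- 10
    X <- matrix(rnorm(n * 30), n,
                dimnames = list(paste0("u", 1:n), NULL))
    labels <- sample(c(rep("a", 4), rep("b", 4), rep("uncategorized", 2)))
    cat <- make_cat(labels)
    r <- rov(cat, X)
    expect_equal(r$penalized, oracle_rov(labels, X), tolerance = 1e-10)
  }
})

test_that("splitting a category into identical halves scales the penalty", {
  set.seed(3)
  half <- matrix(rnorm(2 * 25), 2)
  # the split halves have identical member-to-mean structure, so the mean
  # ratio is unchanged and only the sqrt(Nc) penalty moves
  Xdup <- rbind(half, half)
  rownames(Xdup) <- paste0("u", 1:4)
  whole_cat <- make_cat(rep("b", 4))
  split_cat <- make_cat(c("b1", "b1", "b2", "b2"))
  r_whole <- rov(whole_cat, Xdup)
  r_split <- rov(split_cat, Xdup)
  expect_equal(r_split$grand_mean, r_whole$grand_mean, tolerance = 1e-10)
  expect_equal(r_split$penalized / r_whole$penalized, sqrt(2) / sqrt(1),
               tolerance = 1e-10)
})

test_that("ARI hits its closed-form anchors", {
  a <- make_cat(c(1, 1, 1, 2, 2, 2))
  b <- make_cat(c(1, 1, 2, 2, 3, 3))
  r <- adjusted_rand(a, b, shuffles = 50, seed = 1)
  expect_equal(r$ari, oracle_ari(a$label, b$label), tolerance = 1e-12)
  expect_equal(r$ari, 0.2424, tolerance = 1e-3)

  expect_equal(adjusted_rand(a, a, shuffles = 10, seed = 1)$ari, 1)
  one <- make_cat(rep("x", 6))
  expect_equal(adjusted_rand(a, one, shuffles = 10, seed = 1)$ari, 0)
  expect_true(is.na(adjusted_rand(one, one, shuffles = 10, seed = 1)$ari))
})

test_that("ARI is symmetric, label-invariant, and oracle-exact on random pairs", {
  for (seed in 1:50) {
    set.seed(seed)
    n <- sample(4:10, 1)
    la <- sample(letters[1:3], n, replace = TRUE)
    lb <- sample(LETTERS[1:4], n, replace = TRUE)
    a <- make_cat(la); b <- make_cat(lb)
    r_ab <- adjusted_rand(a, b, shuffles = 2, seed = 1)$ari
    r_ba <- adjusted_rand(b, a, shuffles = 2, seed = 1)$ari
    expect_identical(r_ab, r_ba)
    expect_equal(r_ab, oracle_ari(la, lb), tolerance = 1e-12)
    # permuting label names changes nothing
    perm <- setNames(sample(letters[1:3]), letters[1:3])
    a2 <- make_cat(unname(perm[la]))
    expect_equal(adjusted_rand(a2, b, shuffles = 2, seed = 1)$ari, r_ab,
                 tolerance = 1e-12)
  }
})

test_that("the ARI shuffle p-value counts strict exceedances", {
  demo_a <- make_cat(rep(c("x", "y"), each = 10))
  demo_b <- make_cat(rep(c("p", "q"), each = 10))
  r <- adjusted_rand(demo_a, demo_b, shuffles = 500, seed = 2)
  shuf <- attr(r, "shuffled")
  expect_equal(r$p_value, mean(shuf > r$ari, na.rm = TRUE))
  expect_lt(r$p_value, 0.05)  # identical split structure: highly non-chance
})

test_that("signed chi-square matches direct evaluation and the loop oracle", {
  # two schemes splitting 2m units into matched halves
  m <- 8
  a <- make_cat(rep(c("a1", "a2"), each = m))
  b <- make_cat(rep(c("b1", "b2"), each = m))
  sc <- signed_chi2(a, b, shuffles = 100, seed = 1)
  expect_equal(unname(diag(sc$signed)), c(1, 1))
  expect_equal(unname(sc$signed[1, 2]), -1)
  expect_equal(unname(sc$signed[2, 1]), -1)

  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(8:14, 1)
    la <- sample(c("a", "b"), n, replace = TRUE, prob = c(0.6, 0.4))
    lb <- sample(c("x", "y", "z"), n, replace = TRUE)
    if (length(unique(la)) < 2 || length(unique(lb)) < 3) next
    sc <- signed_chi2(make_cat(la), make_cat(lb), shuffles = 50, seed = 7)
    orc <- oracle_signed_chi2(la, lb)
    expect_equal(unclass(sc$signed), orc, tolerance = 1e-12,
                 ignore_attr = TRUE)
    sc2 <- signed_chi2(make_cat(la), make_cat(lb), shuffles = 50, seed = 7)
    expect_identical(sc$z, sc2$z)  # seeded bootstrap determinism
  }
})

test_that("Kruskal-Wallis tests match a rank oracle and handle edge cases", {
  feats <- tibble::tibble(
    unit_id = paste0("u", 1:9),
    f = c(1.1, 2.3, 0.7, 5.2, 6.1, 4.9, 9.3, 8.8, 10.2),
    all_na = NA_real_)
  cat <- make_cat(rep(c("a", "b", "c"), each = 3), ids = feats$unit_id)
  out <- category_feature_tests(cat, feats)
  h <- out$statistic[out$factor == "f"]
  expect_equal(h, oracle_kruskal_h(feats$f, rep(c("a", "b", "c"), each = 3)),
               tolerance = 1e-10)
  expect_true(is.na(out$statistic[out$factor == "all_na"]))

  # super-group follow-ups restrict to the declared categories
  out2 <- category_feature_tests(cat, feats,
                                 supergroups = list(ab = c("a", "b")))
  expect_true("ab" %in% out2$scope)
  sub <- out2[out2$scope == "ab" & out2$factor == "f", ]
  expect_equal(sub$n, 6)
})
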
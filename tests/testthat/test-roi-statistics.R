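test_that("word-similarity slopes equal closed-form least squares", {
  w <- predictor_enfr()
  # identity fit
  fit <- word_similarity_slope(w, w)
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0)
  # constant betas
  expect_equal(word_similarity_slope(rep(2, 14), w)$slope, 0)
  # perturbed line against independent normal-equations computation
  set.seed(2)
  for (rep in 1:5) {
    betas <- 0.3 + 2.0 * w + rnorm(14, 0, 0.2)
    fit <- word_similarity_slope(betas, w)
    X <- cbind(1, as.numeric(w))
    ref <- solve(t(X) %*% X, t(X) %*% betas)
    expect_equal(fit$intercept, ref[1], tolerance = 1e-10)
    expect_equal(fit$slope, ref[2], tolerance = 1e-10)
    lmref <- summary(lm(betas ~ w))$coefficients
    expect_equal(fit$p, lmref[2, 4], tolerance = 1e-10)
  }
  expect_error(word_similarity_slope(rep(1, 5), rep(0.5, 5)), "constant")
  expect_error(word_similarity_slope(1:2, 1:2), "at least 3")
})

test_that("BH adjustment matches the brute-force step-up rule", {
  got <- fdr_bh(c(0.001, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(got$reject))
  expect_false(any(fdr_bh(rep(1, 6))$reject))
  one <- fdr_bh(0.04, q = 0.05)
  expect_true(one$reject)
  expect_equal(one$qvalues, 0.04)
  set.seed(4)
  for (rep in 1:40) {
    p <- round(runif(sample(1:10, 1)), 3)
    res <- fdr_bh(p, q = 0.05)
    expect_equal(res$reject, brute_bh(p, 0.05))
    expect_true(all(res$qvalues >= p - 1e-12))
    expect_equal(res$reject, res$qvalues <= 0.05)
  }
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("ROI definition finds clusters strictly above the size threshold", {
  g <- array(0.5, c(10, 10, 10))
  g[2:4, 2:4, 2] <- 1e-4
  g[8, 8, 8] <- 1e-4
  r <- define_rois(g, 0.001, 4)
  expect_equal(nrow(r), 1)
  expect_equal(r$size, 9)
  expect_equal(c(r$x, r$y, r$z), c(3, 3, 2))
  # exactly 4 voxels -> excluded (strict inequality)
  g4 <- array(0.5, c(6, 6, 6))
  g4[1:4, 1, 1] <- 1e-4
  expect_equal(nrow(define_rois(g4, 0.001, 4)), 0)
  g5 <- g4
  g5[5, 1, 1] <- 1e-4
  expect_equal(nrow(define_rois(g5, 0.001, 4)), 1)
  # nothing survives
  expect_equal(nrow(define_rois(array(0.5, c(4, 4, 4)), 0.001, 4)), 0)
  # 26-connectivity merges a diagonal pair that 6-connectivity separates
  gd <- array(0.5, c(6, 6, 6))
  gd[2:4, 2, 2] <- 1e-4
  gd[5, 3, 3] <- 1e-4
  gd[5:6, 4, 4] <- 1e-4
  expect_equal(nrow(define_rois(gd, 0.001, 3, connectivity = 26)), 1)
  expect_equal(nrow(define_rois(gd, 0.001, 3, connectivity = 6)), 0)
  # affine maps voxel indices to mm
  aff <- diag(4)
  aff[1:3, 4] <- c(10, 20, 30)
  r2 <- define_rois(g, 0.001, 4, affine = aff)
  expect_equal(c(r2$x, r2$y, r2$z), c(13, 23, 32))
})

test_that("gradient tests recover planted coefficients and exclusions", {
  co <- simulate_cohort(n_participants = 4, rois_per_region = c(VOTC = 5),
                        voxels_per_roi = 5, noise_sd = 0, prop_right = 0,
                        gradient_coef = 0.05, seed = 21)
  st <- cohort_slope_table(co)
  expect_warning(g <- gradient_test(st, hemisphere = "left"),
                 "zero variance")
  expect_equal(unname(g$coefficients), rep(0.05, 4), tolerance = 1e-10)
  expect_equal(g$df, 3)
  # translation invariance in Y
  st2 <- st
  st2$y <- st2$y + 100
  g2 <- suppressWarnings(gradient_test(st2, hemisphere = "left"))
  expect_equal(g$coefficients, g2$coefficients, tolerance = 1e-10)
  # a participant with a single ROI is skipped with a warning (the
  # noiseless fixture also warns about its zero-variance coefficients)
  st3 <- rbind(st, within(st[1, ], participant <- 99L))
  w <- capture_warnings(g3 <- gradient_test(st3, hemisphere = "left"))
  expect_true(any(grepl("skipped", w)))
  expect_length(g3$coefficients, 4)
  expect_error(gradient_test(st[st$participant == 1, ]),
               "fewer than 2 participants")
})

test_that("the frontal axis is the first principal component of (Y, Z)", {
  # collinear ROIs with slope proportional to position: |r| = 1
  d <- data.frame(y = c(0, 10, 20, 30, 40), z = c(0, 5, 10, 15, 20),
                  slope = c(1, 2, 3, 4, 5))
  fa <- frontal_axis_correlation(d)
  expect_equal(abs(fa$r), 1, tolerance = 1e-10)
  # hand PCA on an asymmetric 5-ROI set
  set.seed(8)
  d2 <- data.frame(y = rnorm(5, 0, 10), z = rnorm(5, 0, 3),
                   slope = rnorm(5))
  fa2 <- frontal_axis_correlation(d2)
  cm <- cov(cbind(d2$y, d2$z))
  v1 <- eigen(cm)$vectors[, 1]
  sc <- scale(cbind(d2$y, d2$z), scale = FALSE) %*% v1
  expect_equal(abs(fa2$r), abs(cor(sc[, 1], d2$slope)), tolerance = 1e-10)
  expect_error(frontal_axis_correlation(d[1:2, ]), "at least 3")
  d$slope <- 1
  expect_error(frontal_axis_correlation(d), "undefined")
})

test_that("selectivity index follows the padding rule and stays in [-1, 1]", {
  expect_equal(selectivity_index(c(a = 0.5, b = 0.25), "a", "b"), 1 / 3)
  expect_equal(selectivity_index(c(a = 1, b = 1), "a", "b"), 0)
  # hand application of the padding rule: min = -0.2 is added everywhere
  b <- c(w1 = 0.2, w2 = 0.4, o1 = -0.2, o2 = 0.1, o3 = 0.1, o4 = 0)
  got <- selectivity_index(b, c("w1", "w2"), c("o1", "o2", "o3", "o4"))
  expect_equal(got, (0.5 - 0.2) / (0.5 + 0.2))
  # padding is a no-op when all betas are nonnegative
  bp <- abs(b) + 0.01
  direct <- (mean(bp[1:2]) - mean(bp[3:6])) /
    (mean(bp[1:2]) + mean(bp[3:6]))
  expect_equal(selectivity_index(bp, c("w1", "w2"),
                                 c("o1", "o2", "o3", "o4")), direct)
  # bounded for arbitrary finite inputs
  set.seed(6)
  for (rep in 1:50) {
    v <- stats::setNames(rnorm(6, 0, 5), names(b))
    s <- suppressWarnings(
      selectivity_index(v, c("w1", "w2"), c("o1", "o2", "o3", "o4")))
    expect_gte(s, -1)
    expect_lte(s, 1)
  }
  expect_warning(selectivity_index(c(a = 0, b = 0), "a", "b"), "zero")
  expect_error(selectivity_index(b, "w1", "w1"), "disjoint")
})

test_that("dominance scores follow the reading-count ratio", {
  expect_equal(dominance_score(120, 80), 0.2)
  expect_equal(dominance_score(75, 75), 0)
  expect_equal(dominance_score(100, 0), 1)
  expect_equal(dominance_score(c(120, 75), c(80, 75)), c(0.2, 0))
  expect_error(dominance_score(0, 0), "zero")
  expect_error(dominance_score(-1, 5), "nonnegative")
})

test_that("regional dominance correlations reproduce a planted value exactly", {
  co <- make_dominance_cohort(n_participants = 21, target_r = -0.550,
                              seed = 7)
  res <- suppressWarnings(region_dominance_correlation(co))
  r <- res$r[res$pair == "WEmWF"]
  expect_equal(r, -0.550, tolerance = 1e-12)
  expect_equal(res$df[res$pair == "WEmWF"], 19)
  # a different seed still plants the exact correlation
  co2 <- make_dominance_cohort(n_participants = 21, target_r = -0.550,
                               seed = 99)
  res2 <- suppressWarnings(region_dominance_correlation(co2))
  expect_equal(res2$r[res2$pair == "WEmWF"], -0.550, tolerance = 1e-12)
  # null association: correlations stay small on average over seeds
  rs <- vapply(1:10, function(s) {
    co0 <- simulate_cohort(n_participants = 21,
                           rois_per_region = c(VOTC = 3),
                           voxels_per_roi = 10, noise_sd = 0.1, seed = s)
    out <- suppressWarnings(region_dominance_correlation(
      co0, regions = "VOTC"))
    out$r[out$pair == "WEmWF"]
  }, 0)
  expect_lt(abs(mean(rs)), 0.25)
})

test_that("voxel overlap percentages follow set arithmetic", {
  expect_equal(voxel_overlap(1:5, 1:10), 100)
  expect_equal(voxel_overlap(1:4, 11:20), 0)
  expect_equal(voxel_overlap(1:8, 3:30), 75)
  expect_error(voxel_overlap(integer(0), 1:3), "empty")
})
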
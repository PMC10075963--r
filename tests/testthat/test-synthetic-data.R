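test_that("synthetic lexica are deterministic and respect overlap", {
  a <- make_synthetic_lexica(n_words = 300, seed = 5)
  b <- make_synthetic_lexica(n_words = 300, seed = 5)
  expect_identical(a[[1]]$words, b[[1]]$words)
  expect_identical(a[[2]]$words, b[[2]]$words)
  expect_false(identical(
    a[[1]]$words, make_synthetic_lexica(n_words = 300, seed = 6)[[1]]$words))
  # overlap 0: vocabularies disjoint
  z <- make_synthetic_lexica(n_words = 200, overlap = 0, seed = 2)
  expect_length(intersect(z[[1]]$words, z[[2]]$words), 0)
  # frequencies are Zipf: strictly decreasing, positive
  expect_true(all(diff(a[[1]]$freq) < 0))
  expect_gt(min(a[[1]]$freq), 0)
  expect_error(make_synthetic_lexica(n_words = 10, alphabet = c("A", "B")),
               "alphabet too small")
})

test_that("full vocabulary overlap yields matching letter statistics", {
  lx <- make_synthetic_lexica(n_words = 1000, divergence = 0,
                              pair_divergence = 0, overlap = 1, seed = 3)
  tE <- build_ngram_table(lx[[1]], 1)
  tF <- build_ngram_table(lx[[2]], 1)
  common <- intersect(names(tE$logfreq), names(tF$logfreq))
  expect_gt(length(common), 15)
  expect_gt(cor(tE$logfreq[common], tF$logfreq[common]), 0.999)
  # higher divergence lowers the cross-language letter agreement
  hi <- make_synthetic_lexica(n_words = 1000, divergence = 2,
                              pair_divergence = 2, overlap = 0, seed = 3)
  tEh <- build_ngram_table(hi[[1]], 1)
  tFh <- build_ngram_table(hi[[2]], 1)
  ch <- intersect(names(tEh$logfreq), names(tFh$logfreq))
  expect_lt(cor(tEh$logfreq[ch], tFh$logfreq[ch]),
            cor(tE$logfreq[common], tF$logfreq[common]))
})

test_that("noiseless cohorts reproduce their planted slopes exactly", {
  co <- simulate_cohort(n_participants = 3, rois_per_region = c(VOTC = 4),
                        voxels_per_roi = 6, noise_sd = 0, seed = 11)
  st <- cohort_slope_table(co)
  gt <- co$ground_truth$rois
  expect_equal(st$slope, gt$planted_slope, tolerance = 1e-10)
  # zero gradient coefficient: group mean coefficient is essentially zero
  co0 <- simulate_cohort(n_participants = 5, rois_per_region = c(VOTC = 6),
                         voxels_per_roi = 10, gradient_coef = 0,
                         noise_sd = 0.05, prop_right = 0, seed = 12)
  g <- gradient_test(cohort_slope_table(co0), hemisphere = "left")
  expect_lt(abs(g$mean), 0.003)
})

test_that("language patches carry the planted offset and face response", {
  co <- simulate_cohort(n_participants = 4, rois_per_region = c(VOTC = 8),
                        voxels_per_roi = 40, noise_sd = 0.05,
                        labels = condition_labels("encn"),
                        scenario = "logographic-split",
                        patch_fraction = 0.5, patch_effect = 0.5,
                        face_amplitude = 1, seed = 13)
  tab <- cohort_roi_table(co, "main")
  gt <- co$ground_truth$rois
  second <- c("S", "SG", "RI", "RP", "CP", "WL", "WH")
  first <- c("L-", "L+", "B-", "B+", "Q-", "Q+", "WE")
  diffs <- rowMeans(tab[, second]) - rowMeans(tab[, first])
  expect_gt(sum(gt$patch), 0)
  # hierarchy ramp adds patch_effect/2 on average on top of the offset
  expect_equal(mean(diffs[gt$patch]) - mean(diffs[!gt$patch]), 0.75,
               tolerance = 0.1)
  loc <- cohort_roi_table(co, "localizer")
  expect_equal(mean(loc$faces[gt$patch]) - mean(loc$faces[!gt$patch]), 1,
               tolerance = 0.1)
  expect_error(simulate_cohort(scenario = "nope"), "arg")
})

test_that("simulated time courses are seeded and carry the set noise", {
  stim <- random_stimuli(60, seed = 21)
  sch <- build_main_run(stim, seed = 21)
  betas <- stats::setNames(rep(0, 14), condition_labels("enfr"))
  y1 <- simulate_roi_timecourses(betas, sch, noise_sd = 1, seed = 4)
  y2 <- simulate_roi_timecourses(betas, sch, noise_sd = 1, seed = 4)
  expect_identical(y1, y2)
  # all-zero betas: pure AR(0) noise with roughly the configured sd
  pct <- 100 * (y1 - mean(y1)) / mean(y1)
  expect_equal(sd(pct), 1, tolerance = 0.15)
})

test_that("cohorts survive a serialization round trip", {
  co <- simulate_cohort(n_participants = 2, rois_per_region = c(VOTC = 2),
                        voxels_per_roi = 4, seed = 31)
  d <- withr::local_tempdir()
  write_cohort(co, d)
  co2 <- read_cohort(d)
  expect_equal(length(co2$participants), 2)
  r1 <- co$participants[[1]]$rois[[1]]
  r2 <- co2$participants[[1]]$rois[[1]]
  expect_equal(r1$betas, r2$betas, tolerance = 1e-12)
  expect_equal(r1$loc_betas, r2$loc_betas, tolerance = 1e-12)
  expect_equal(r1$centroid, r2$centroid, tolerance = 1e-12)
  expect_equal(co$participants[[2]]$dominance,
               co2$participants[[2]]$dominance)
})

test_that("exact correlations can be planted by orthogonalize-and-rescale", {
  set.seed(9)
  x <- rnorm(21)
  for (r in c(-0.55, 0, 0.3, 0.99)) {
    y <- plant_correlation(x, r, helper = rnorm(21))
    expect_equal(cor(x, y), r, tolerance = 1e-12)
  }
  expect_error(plant_correlation(rep(1, 10), 0.5), "constant")
})
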
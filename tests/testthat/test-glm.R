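# small run for GLM tests: one block per condition keeps fits fast
small_run <- function(seed = 1) {
  stim <- random_stimuli(12, seed = seed)
  build_main_run(stim, reps_per_condition = 1, catch_per_condition = 0,
                 seed = seed)
}

test_that("noiseless simulation and GLM are exact inverses", {
  sch <- small_run(3)
  set.seed(5)
  betas <- stats::setNames(runif(14, 0, 2), condition_labels("enfr"))
  y <- simulate_roi_timecourses(betas, sch, noise_sd = 0)
  fit <- roi_glm(y, sch)
  expect_lt(max(abs(fit$coef[fit$conditions] - betas[fit$conditions])),
            1e-6)
  # AR(2) path recovers the same betas at zero noise
  fit2 <- roi_glm(y, sch, ar_order = 2)
  expect_lt(max(abs(fit2$coef[fit2$conditions] - betas[fit2$conditions])),
            1e-4)
})

test_that("GLM inputs are validated", {
  sch <- small_run(4)
  y <- simulate_roi_timecourses(
    stats::setNames(rep(0, 14), condition_labels("enfr")), sch,
    noise_sd = 1, seed = 1)
  expect_error(roi_glm(y[-1], sch), "volumes")
  expect_error(roi_glm(y, sch, ar_order = 1), "0 or 2")
  # duplicated confound column makes the design rank deficient
  X <- glm_design_matrix(sch)
  expect_error(roi_glm(y, sch, confounds = cbind(a = X[, 1], b = X[, 1])),
               "collinear")
  fit <- roi_glm(y, sch)
  expect_error(glm_contrast(fit, stats::setNames(numeric(2),
                                                 c("L-", "L+"))),
               "all zero")
  expect_error(glm_contrast(fit, c(nope = 1)), "condition labels")
  expect_error(percent_transform(c(-1, 1)), "nonzero")
})

test_that("contrast p-values are calibrated on white noise", {
  sch <- small_run(6)
  X <- glm_design_matrix(sch)
  w <- contrast_definitions("enfr")$lexicality
  set.seed(33)
  nv <- nrow(X)
  ps <- vapply(1:300, function(i) {
    y <- 100 + rnorm(nv, 0, 0.5)
    glm_contrast(roi_glm(y, sch), w)$p
  }, 0)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.04)
})

test_that("the contrast battery evaluates its hand-checked values", {
  labels <- condition_labels("enfr")
  # words only: lexicality positive, frequency contrasts zero
  b1 <- stats::setNames(rep(0, 14), labels)
  b1[c("WE", "WF")] <- 1
  cb1 <- contrast_battery(b1, "enfr")
  expect_equal(cb1$estimate[cb1$contrast == "lexicality"], 1)
  expect_equal(cb1$estimate[cb1$contrast == "freq_letters"], 0)
  expect_equal(cb1$estimate[cb1$contrast == "freq_quadrigrams"], 0)
  # betas equal to the predictor weights: adjacent level differences
  # vanish (equal one-step increments); the lexicality-level difference
  # equals 0.2 - 2 * 0.2 = -0.2 by direct evaluation
  cb2 <- contrast_battery(predictor_enfr(), "enfr")
  est <- stats::setNames(cb2$estimate, cb2$contrast)
  expect_equal(unname(est["level_big_vs_let"]), 0, tolerance = 1e-12)
  expect_equal(unname(est["level_quad_vs_big"]), 0, tolerance = 1e-12)
  expect_equal(unname(est["level_lex_vs_quad"]), -0.2, tolerance = 1e-12)
  expect_equal(unname(est["freq_letters"]), 0.2, tolerance = 1e-12)
  # 2x2 main effects and interaction on a constructed letter block
  b3 <- stats::setNames(rep(0, 14), labels)
  b3[c("L-", "LE", "LF", "L+")] <- c(0, 1, 2, 3)
  cb3 <- contrast_battery(b3, "enfr")
  est3 <- stats::setNames(cb3$estimate, cb3$contrast)
  expect_equal(unname(est3["main_f_letters"]), 2)
  expect_equal(unname(est3["main_e_letters"]), 1)
  expect_equal(unname(est3["interaction_letters"]), 0)
  # logographic design: planted character-pair step recovered
  encn <- condition_labels("encn")
  b4 <- stats::setNames(rep(0.1, 14), encn)
  b4["CP"] <- b4["RP"] + 0.4
  cb4 <- contrast_battery(b4, "encn")
  expect_equal(cb4$estimate[cb4$contrast == "cp_vs_rp"], 0.4)
  expect_error(contrast_battery(b4, "enfr"), "condition labels")
})

test_that("GLM contrasts agree with lm on the same design", {
  sch <- small_run(9)
  set.seed(10)
  betas <- stats::setNames(runif(14), condition_labels("enfr"))
  y <- simulate_roi_timecourses(betas, sch, noise_sd = 0.4, seed = 2)
  fit <- roi_glm(y, sch)
  X <- glm_design_matrix(sch)
  ref <- lm(percent_transform(y) ~ X)
  expect_equal(unname(fit$coef[fit$conditions]),
               unname(coef(ref)[-1]), tolerance = 1e-8)
  w <- stats::setNames(c(1, -1), c("Q+", "Q-"))
  cr <- glm_contrast(fit, w)
  # the same contrast via lm's covariance matrix
  cvec <- numeric(length(coef(ref)))
  names(cvec) <- names(coef(ref))
  cvec[paste0("X", "Q+")] <- 1
  cvec[paste0("X", "Q-")] <- -1
  est <- sum(cvec * coef(ref))
  se <- sqrt(drop(t(cvec) %*% vcov(ref) %*% cvec))
  expect_equal(cr$estimate, est, tolerance = 1e-8)
  expect_equal(cr$se, se, tolerance = 1e-8)
})
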
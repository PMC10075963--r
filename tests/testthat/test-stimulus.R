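mk_thresholds <- function(lo = -1, hi = 1) {
  out <- data.frame(stat = design_stat_cols <- c("letE", "bigE", "quadE",
                                                 "letF", "bigF", "quadF"),
                    low_max = lo, high_min = hi)
  class(out) <- c("band_thresholds", "data.frame")
  out
}

stats_row <- function(...) {
  v <- c(...)
  as.data.frame(as.list(v))
}

test_that("candidates are classified into the 2x2 cells per level", {
  thr <- mk_thresholds()
  # low letters in both languages, neutral elsewhere
  s1 <- stats_row(letE = -2, bigE = 0, quadE = 0,
                  letF = -2, bigF = 0, quadF = 0)
  expect_equal(classify_candidate(s1, thr), "L-")
  # high letters first language only
  s2 <- stats_row(letE = 2, bigE = 0, quadE = 0,
                  letF = -2, bigF = 0, quadF = 0)
  expect_equal(classify_candidate(s2, thr), "LE")
  s3 <- stats_row(letE = -2, bigE = 0, quadE = 0,
                  letF = 2, bigF = 0, quadF = 0)
  expect_equal(classify_candidate(s3, thr), "LF")
  # high letters AND high quadrigrams violates the decorrelation rule
  s4 <- stats_row(letE = 2, bigE = 0, quadE = 2,
                  letF = 2, bigF = 0, quadF = 2)
  expect_true(is.na(classify_candidate(s4, thr)))
  # quadrigram cell
  s5 <- stats_row(letE = 0, bigE = 0, quadE = 2,
                  letF = 0, bigF = 0, quadF = -2)
  expect_equal(classify_candidate(s5, thr), "QE")
  # degenerate thresholds error
  bad <- mk_thresholds(1, 1)
  expect_error(classify_candidate(s1, bad), "low >= high")
})

test_that("band thresholds use the above-floor sub-population", {
  set.seed(1)
  st <- data.frame(letE = rnorm(200, 4), bigE = rnorm(200, 3),
                   quadE = c(rep(-2, 80), rnorm(120)),
                   letF = rnorm(200, 4), bigF = rnorm(200, 3),
                   quadF = c(rnorm(120), rep(-2, 80)))
  thr <- band_thresholds(st, floor = -2)
  # low cutoff sits above the floor even with a 40% floor pile-up
  expect_gt(thr$high_min[thr$stat == "quadE"],
            thr$low_max[thr$stat == "quadE"])
  expect_gt(thr$low_max[thr$stat == "quadE"], -2)
  expect_error(band_thresholds(st, probs = c(0.8, 0.2)), "increasing")
})

test_that("greedy selection is deterministic and limits cross-level correlation", {
  set.seed(3)
  n <- 600
  # target-level stat correlated with a non-target stat in the pool
  z <- rnorm(n)
  st <- data.frame(letE = z + rnorm(n),
                   bigE = z + rnorm(n),
                   quadE = rnorm(n),
                   letF = rnorm(n), bigF = rnorm(n), quadF = rnorm(n))
  sel1 <- select_category_items(st, seq_len(n), "let", 40, seed = 9)
  sel2 <- select_category_items(st, seq_len(n), "let", 40, seed = 9)
  expect_identical(sel1$idx, sel2$idx)
  expect_length(sel1$idx, 40)
  r_pool <- abs(cor(st$letE, st$bigE))
  r_sel <- abs(cor(st$letE[sel1$idx], st$bigE[sel1$idx]))
  expect_lt(r_sel, r_pool)
  expect_lt(r_sel, 0.25)
  expect_error(select_category_items(st, 1:10, "let", 50), "infeasible")
})

test_that("word matching selects within-tolerance words and reports deltas", {
  cols <- c("letE", "bigE", "quadE", "letF", "bigF", "quadF")
  tgt <- stats::setNames(rep(0, 6), cols)
  ws <- data.frame(string = c("W1", "W2", "W3", "W4"),
                   letE = c(0.1, -0.1, 1, -1), bigE = c(0.1, -0.1, 1, -1),
                   quadE = c(0.1, -0.1, 1, -1), letF = c(0.1, -0.1, 1, -1),
                   bigF = c(0.1, -0.1, 1, -1), quadF = c(0.1, -0.1, 1, -1))
  mw <- match_words(ws, tgt, 2, tolerance = 0.2)
  expect_setequal(ws$string[mw$idx], c("W1", "W2"))
  expect_true(all(abs(mw$deltas) <= 0.2))
  # identity match
  ws0 <- ws
  ws0[, cols] <- 0
  mw0 <- match_words(ws0, tgt, 2, tolerance = 0.1)
  expect_equal(unname(mw0$deltas), rep(0, 6))
  # impossible tolerance errors with achieved deltas in the message
  ws1 <- ws
  ws1[, cols] <- 1
  expect_error(match_words(ws1, tgt, 2, tolerance = 0),
               "best achievable")
})

test_that("condition label sets match the two designs", {
  enfr <- condition_labels("enfr")
  expect_length(enfr, 14)
  expect_length(setdiff(enfr, c("WE", "WF")), 12)
  encn <- condition_labels("encn")
  expect_length(encn, 14)
  expect_true(all(c("S", "SG", "RI", "RP", "CP", "WL", "WH") %in% encn))
})
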
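test_that("block item ordering avoids repeated letter positions", {
  # trivial: disjoint letter sets, any order valid
  expect_setequal(order_block_items(c("AAAAAA", "BBBBBB"), seed = 1),
                  c("AAAAAA", "BBBBBB"))
  # property: random item sets, constraint always satisfied
  set.seed(5)
  for (rep in 1:20) {
    items <- unique(replicate(12, paste(sample(LETTERS[1:10], 6,
                                               replace = TRUE),
                                        collapse = "")))
    out <- tryCatch(order_block_items(items, seed = rep),
                    error = function(e) NULL)
    if (is.null(out)) next
    m <- do.call(rbind, strsplit(out, ""))
    for (i in seq_len(nrow(m) - 1))
      expect_false(any(m[i, ] == m[i + 1, ]))
    expect_setequal(out, items)
  }
  # twelve strings all sharing position 1 are pairwise conflicting
  bad <- paste0("A", c("BCDEF", "CDEFB", "DEFBC", "EFBCD", "FBCDE",
                       "BCDFE", "CDEBF", "DEFCB", "EFBDC", "FBCED",
                       "BCEDF", "CDFEB"))
  expect_error(order_block_items(bad, seed = 1), "no ordering")
})

test_that("a main run reproduces the printed block and volume counts", {
  stim <- random_stimuli(180, seed = 2)
  sch <- build_main_run(stim, seed = 7)
  ev <- sch$events
  expect_equal(sum(ev$kind == "stimulus"), 70)
  expect_equal(sum(ev$duration), 798)
  expect_equal(ceiling(sum(ev$duration) / sch$timing$tr), 399)
  # events tile the run exactly: no gaps, no overlaps, onset 0
  expect_equal(ev$onset[1], 0)
  expect_equal(ev$onset[-1],
               head(ev$onset, -1) + head(ev$duration, -1))
  # every condition five times, no immediate repetition
  expect_true(all(table(sch$meta$conditions) == 5))
  expect_false(any(head(sch$meta$conditions, -1) ==
                     tail(sch$meta$conditions, -1)))
  # jitter multiset mean is exactly 5.8 s
  expect_equal(mean(sch$meta$iti_s), 5.8)
  expect_equal(sum(sch$meta$fixation_durations_s), 68)
  # catch targets only after the fifth item
  cp <- sch$meta$catch_pos
  expect_equal(sum(!is.na(cp)), 28)
  expect_true(all(cp[!is.na(cp)] >= 6))
  expect_true(all(vapply(which(!is.na(cp)), function(b)
    sch$items[[b]][cp[b]] == "######", TRUE)))
})

test_that("the three-run session uses every stimulus exactly once", {
  stim <- random_stimuli(180, seed = 3)
  ses <- build_main_session(stim, seed = 4)
  expect_length(ses, 3)
  shown <- unlist(lapply(ses, function(s) unlist(s$items)))
  shown <- shown[shown != "######"]
  expect_false(any(duplicated(shown)))
  expect_true(all(shown %in% stim$string))
  # 84 catch replacements: 2520 - 84 unique strings shown
  expect_equal(length(shown), 2520 - 3 * 28)
  smry <- schedule_summary(ses)
  expect_equal(smry$pooled$catch_pct, 40)
  expect_equal(smry$pooled$n_volumes, 3 * 399)
  expect_true(all(smry$condition_counts == 5))
})

test_that("the localizer run reproduces its printed duration", {
  loc <- build_localizer_run(seed = 6)
  ev <- loc$events
  expect_equal(sum(ev$kind == "stimulus"), 45)
  expect_equal(sum(ev$duration), 552)
  expect_equal(ceiling(sum(ev$duration) / loc$timing$tr), 276)
  expect_true(all(table(loc$meta$conditions) == 5))
  # checkerboard blocks carry no catch targets
  cb <- which(loc$meta$conditions == "checkerboard")
  expect_true(all(is.na(loc$meta$catch_pos[cb])))
  expect_equal(sum(!is.na(loc$meta$catch_pos)), 8 * 2)
  expect_equal(mean(loc$meta$iti_s), 6)
})

test_that("schedules are deterministic given the seed", {
  stim <- random_stimuli(60, seed = 8)
  a <- build_main_run(stim, reps_per_condition = 5, seed = 12)
  b <- build_main_run(stim, reps_per_condition = 5, seed = 12)
  expect_identical(a$events, b$events)
  expect_identical(a$items, b$items)
  c2 <- build_main_run(stim, reps_per_condition = 5, seed = 13)
  expect_false(identical(a$items, c2$items))
})

test_that("summaries and writers behave on edge cases", {
  expect_error(schedule_summary(list()), "no schedules")
  stim <- random_stimuli(60, seed = 9)
  sch <- build_main_run(stim, seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_events_tsv(sch, f)
  got <- utils::read.delim(f)
  expect_equal(nrow(got), nrow(sch$events))
  expect_true(all(c("onset", "duration", "trial_type", "stim_file",
                    "catch") %in% names(got)))
  fj <- withr::local_tempfile(fileext = ".json")
  write_session_manifest(sch, fj)
  man <- jsonlite::read_json(fj)
  expect_equal(man[[1]]$seed, sch$meta$seed)
})
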
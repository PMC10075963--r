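test_that("n-gram tables match a brute-force counter on toy lexica", {
  lex <- toy_lexicon()
  t2 <- build_ngram_table(lex, 2)
  expect_equal(t2$logfreq[["AB"]], 1)
  expect_equal(t2$logfreq[["BC"]], log10(30))
  t1 <- build_ngram_table(lex, 1)
  expect_equal(t1$logfreq[["B"]], log10(40))

  set.seed(42)
  for (rep in 1:5) {
    nw <- sample(3:20, 1)
    words <- unique(replicate(nw, paste(sample(c("A", "B", "C"),
                                               sample(4:7, 1),
                                               replace = TRUE),
                                        collapse = "")))
    freq <- runif(length(words), 0.5, 100)
    lx <- lexicon(words, freq, alphabet = c("A", "B", "C"))
    for (n in c(1L, 2L, 4L)) {
      tab <- build_ngram_table(lx, n)
      ref <- brute_ngram_counts(words, freq, n)
      expect_equal(sort(names(tab$logfreq)), sort(names(ref)))
      expect_equal(tab$logfreq[names(ref)], log10(ref), tolerance = 1e-12)
      # type weighting against the same brute counter
      tabt <- build_ngram_table(lx, n, weighting = "type")
      reft <- brute_ngram_counts(words, freq, n, weighting = "type")
      expect_equal(tabt$logfreq[names(reft)], log10(reft),
                   tolerance = 1e-12)
    }
  }
})

test_that("unattested n-grams return the floor and errors are raised", {
  lex <- toy_lexicon()
  t2 <- build_ngram_table(lex, 2, floor = -3)
  expect_equal(ngram_lookup(t2, "ZZ"), -3)
  expect_true(all(t2$logfreq >= t2$floor))
  expect_error(build_ngram_table(lex, 3), "1, 2 or 4")
  expect_error(build_ngram_table(lex, 4), "shorter")
  expect_error(lexicon(character(0), numeric(0)), "length|empty")
  expect_error(lexicon(c("AB", "AB"), c(1, 2)), "duplicated")
  expect_error(lexicon("A1", 1), "alphabet")
})

test_that("component stats average contiguous n-grams with the floor", {
  lexE <- lexicon(c("ABAB", "BABA"), c(5, 5), "E", c("A", "B"))
  tabs <- list(E = lapply(c(1, 2, 4),
                          function(n) build_ngram_table(lexE, n)))
  big <- structure(list(language_id = "E", n = 2L,
                        logfreq = c(AB = 1.0, BA = 0.5), floor = -2,
                        alphabet = c("A", "B")), class = "ngram_table")
  tabs$E[[2]] <- big
  st <- string_component_stats("ABAB", tabs)
  expect_equal(st$bigE, (1.0 + 0.5 + 1.0) / 3)

  # string with every n-gram unattested -> mean equals the floor
  lexC <- lexicon("CCCC", 1, "E", c("A", "B", "C"))
  tabsC <- list(E = lapply(c(1, 2, 4),
                           function(n) build_ngram_table(lexC, n)))
  st2 <- string_component_stats("ABAB", tabsC)
  expect_equal(st2$letE, -2)
  expect_equal(st2$quadE, -2)

  expect_error(string_component_stats("AB", tabs), "length >= 4")
  expect_error(string_component_stats("ABXB", tabs), "alphabet")
})

test_that("component stats are invariant to lexicon entry order", {
  set.seed(7)
  words <- c("ABCA", "BCAB", "CABC", "AABB", "BBCC")
  freq <- c(3, 9, 1, 4, 2)
  mk <- function(ord) {
    lx <- lexicon(words[ord], freq[ord], alphabet = c("A", "B", "C"))
    tabs <- list(L = lapply(c(1, 2, 4),
                            function(n) build_ngram_table(lx, n)))
    string_component_stats(c("ABCABC", "CCCCAB"), tabs)
  }
  a <- mk(1:5)
  b <- mk(5:1)
  expect_equal(a, b)
})

test_that("candidate enumeration equals the exhaustive filter on small alphabets", {
  # minimal contract cases
  expect_equal(enumerate_candidates(c("A", "B"), 4, "ABAB"), "ABAB")
  expect_equal(enumerate_candidates(c("A", "B"), 6, character(0)),
               character(0))
  lex5 <- lexicon("ABABA", 5, alphabet = c("A", "B"))
  expect_false("ABABAB" %in%
                 enumerate_candidates(c("A", "B"), 6, "ABAB", list(lex5)))

  set.seed(11)
  for (rep in 1:4) {
    alpha <- c("A", "B", "C")[seq_len(sample(2:3, 1))]
    len <- sample(4:5, 1)
    quads <- unique(replicate(3, paste(sample(alpha, 4, replace = TRUE),
                                       collapse = "")))
    words <- unique(replicate(4, paste(sample(alpha, sample(4:5, 1),
                                              replace = TRUE),
                                       collapse = "")))
    lx <- list(lexicon(words, rep(1, length(words)), alphabet = alpha))
    got <- enumerate_candidates(alpha, len, quads, lx)
    want <- brute_candidates(alpha, len, quads, lx)
    expect_equal(got, want)
  }
})

test_that("lexicon and n-gram table TSV round trips preserve content", {
  lx <- lexicon(c("ABCD", "BCDE"), c(5, 2.5), "t")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon(lx, f)
  lx2 <- read_lexicon(f, "t")
  expect_identical(lx2$words, lx$words)
  expect_equal(lx2$freq, lx$freq)
  # comment lines and missing header are tolerated
  writeLines(c("# a comment", "ABCD\t5", "BCDE\t2.5"), f)
  lx3 <- read_lexicon(f, "t")
  expect_identical(lx3$words, lx$words)
  tab <- build_ngram_table(lx, 2)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_ngram_table(tab, f2)
  got <- utils::read.delim(f2)
  expect_equal(nrow(got), length(tab$logfreq))
})
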
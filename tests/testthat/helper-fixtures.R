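# shared fixtures, all built in code

toy_lexicon <- function() {
  lexicon(c("AB", "BC"), c(10, 30), "toy", alphabet = c("A", "B", "C"))
}

# brute-force n-gram counter independent of build_ngram_table
brute_ngram_counts <- function(words, freq, n, weighting = "token") {
  acc <- list()
  for (i in seq_along(words)) {
    w <- words[i]
    wt <- if (weighting == "token") freq[i] else 1
    for (s in seq_len(nchar(w) - n + 1L)) {
      g <- substr(w, s, s + n - 1L)
      acc[[g]] <- (acc[[g]] %||% 0) + wt
    }
  }
  unlist(acc)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive candidate filter, independent of enumerate_candidates
brute_candidates <- function(alphabet, len, quads, lexica,
                             embed_min_len = 5L) {
  all_str <- do.call(paste0, rev(expand.grid(rep(list(alphabet), len),
                                             stringsAsFactors = FALSE)))
  words <- unlist(lapply(lexica, `[[`, "words"))
  keep <- vapply(all_str, function(s) {
    has_q <- any(vapply(seq_len(len - 3L), function(p)
      substr(s, p, p + 3L) %in% quads, TRUE))
    if (!has_q) return(FALSE)
    if (s %in% words) return(FALSE)
    for (wl in seq(embed_min_len, len))
      for (p in seq_len(len - wl + 1L))
        if (substr(s, p, p + wl - 1L) %in% words[nchar(words) == wl])
          return(FALSE)
    TRUE
  }, TRUE)
  sort(unname(all_str[keep]))
}

# brute-force BH step-up, independent of fdr_bh / p.adjust
brute_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  thresh <- q * seq_len(m) / m
  passed <- which(p[o] <= thresh)
  reject <- logical(m)
  if (length(passed)) reject[o[seq_len(max(passed))]] <- TRUE
  reject
}

# random stimulus table: 14 categories x n unique 6-letter strings
random_stimuli <- function(n_per_cat = 180L, seed = 1L) {
  set.seed(seed)
  labels <- condition_labels("enfr")
  n <- n_per_cat * length(labels)
  pool <- character(0)
  while (length(pool) < n) {
    pool <- unique(c(pool, replicate(n, paste(sample(LETTERS, 6L,
                                                     replace = TRUE),
                                              collapse = ""))))
  }
  data.frame(string = pool[seq_len(n)],
             category = rep(labels, each = n_per_cat))
}

# planted 3-component mixture with heavy-tailed weights
planted_mixture <- function(v = 3000L, cond = 14L, k = 3L, noise = 0.01,
                            seed = 1L) {
  set.seed(seed)
  P <- qr.Q(qr(matrix(rnorm(cond * k), cond)))
  rlap <- function(n) {
    u <- runif(n) - 0.5
    -sign(u) * log(1 - 2 * abs(u)) / sqrt(2)
  }
  W <- matrix(rlap(v * k), v, k) %*% diag(c(3, 2, 1.5))
  list(X = W %*% t(P) + matrix(rnorm(v * cond, 0, noise), v, cond),
       profiles = t(P), weights = W)
}
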
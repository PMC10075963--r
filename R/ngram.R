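#' Build an n-gram frequency table from a lexicon
#'
#' Counts every contiguous n-gram of every word (overlapping occurrences all
#' count) and converts the totals to log10 occurrences per million. By
#' default counts are token-weighted: each occurrence contributes the word's
#' corpus frequency, so the table reflects how often a reader encounters the
#' n-gram in text. Type weighting (each word counts once) is available for
#' comparison.
#'
#' @param lex a \code{\link{lexicon}}.
#' @param n component order: 1 (letters), 2 (bigrams) or 4 (quadrigrams).
#' @param floor log10 value returned for unattested n-grams; default
#'   \code{log10(0.01)} = -2 per million, finite but well below any attested
#'   n-gram of a realistic corpus.
#' @param weighting "token" (occurrences times word frequency, default) or
#'   "type" (occurrences only).
#' @return An object of class \code{ngram_table}: list with
#'   \code{language_id}, \code{n}, \code{logfreq} (named numeric vector),
#'   \code{floor}, \code{alphabet}.
#' @examples
#' lex <- lexicon(c("AB", "BC"), c(10, 30), alphabet = c("A", "B", "C"))
#' tab <- build_ngram_table(lex, 2)
#' tab$logfreq[["AB"]]  # log10(10) = 1
#' @export
build_ngram_table <- function(lex, n, floor = log10(0.01),
                              weighting = c("token", "type")) {
  stopifnot(inherits(lex, "lexicon"))
  weighting <- match.arg(weighting)
  if (!n %in% c(1L, 2L, 4L)) stop("n must be 1, 2 or 4")
  n <- as.integer(n)
  len <- nchar(lex$words)
  if (any(len < n))
    stop("word shorter than n=", n, ": ", lex$words[which(len < n)[1L]])
  wt <- if (weighting == "token") lex$freq else rep(1, length(lex$words))
  grams <- character(0); wts <- numeric(0)
  kmax <- max(len) - n + 1L
  for (i in seq_len(kmax)) {
    keep <- len >= i + n - 1L
    grams <- c(grams, substr(lex$words[keep], i, i + n - 1L))
    wts <- c(wts, wt[keep])
  }
  raw <- rowsum(wts, grams)
  logfreq <- log10(raw[, 1L])
  names(logfreq) <- rownames(raw)
  if (any(logfreq < floor))
    logfreq[logfreq < floor] <- floor  # keep the >= floor invariant
  structure(list(language_id = lex$language_id, n = n, logfreq = logfreq,
                 floor = floor, alphabet = lex$alphabet),
            class = "ngram_table")
}

#' @export
print.ngram_table <- function(x, ...) {
  cat("<ngram_table>", x$language_id, " n=", x$n, ": ",
      length(x$logfreq), " attested n-grams, floor ", x$floor, "\n", sep = "")
  invisible(x)
}

#' Look up log10 frequencies of n-grams
#'
#' Unattested n-grams return the table's floor value.
#'
#' @param tab an \code{\link{build_ngram_table}} result.
#' @param grams character vector of n-grams (each of length \code{tab$n}).
#' @return numeric vector of log10 per-million frequencies.
#' @export
ngram_lookup <- function(tab, grams) {
  stopifnot(inherits(tab, "ngram_table"))
  if (any(nchar(grams) != tab$n))
    stop("all queried n-grams must have length ", tab$n)
  v <- unname(tab$logfreq[grams])
  v[is.na(v)] <- tab$floor
  v
}

#' Write an n-gram table to TSV
#' @param tab an \code{ngram_table}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_ngram_table <- function(tab, path) {
  stopifnot(inherits(tab, "ngram_table"))
  utils::write.table(
    data.frame(ngram = names(tab$logfreq), log10_freq = unname(tab$logfreq)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Mean component log-frequencies of letter strings
#'
#' For each string and each language/level, computes the arithmetic mean of
#' the log10 frequencies of all contiguous n-grams of the string (a string of
#' length L has L - n + 1 of them); unattested n-grams contribute the table
#' floor. These are the per-string orthographic statistics on which the
#' stimulus design is built.
#'
#' @param strings character vector, each of length >= 4.
#' @param tables named list per language; each element a list of
#'   \code{ngram_table}s for n = 1, 2, 4 (any order).
#' @return data.frame with column \code{string} and one column
#'   \code{<level><language_id>} per language/level, levels labelled
#'   \code{let}, \code{big}, \code{quad}. Units: log10 counts per million.
#' @examples
#' lexE <- lexicon(c("ABAB", "BABA"), c(5, 5), "E", c("A", "B"))
#' tabs <- list(E = lapply(c(1, 2, 4), function(n) build_ngram_table(lexE, n)))
#' string_component_stats("ABAB", tabs)
#' @export
string_component_stats <- function(strings, tables) {
  strings <- toupper(strings)
  if (any(nchar(strings) < 4L)) stop("all strings must have length >= 4")
  alpha <- tables[[1L]][[1L]]$alphabet
  bad <- !grepl(paste0("^[", paste(alpha, collapse = ""), "]+$"), strings)
  if (any(bad))
    stop("strings outside the declared alphabet: ",
         paste(utils::head(strings[bad], 3), collapse = ", "))
  out <- data.frame(string = strings, stringsAsFactors = FALSE)
  lvl_name <- c(`1` = "let", `2` = "big", `4` = "quad")
  L <- nchar(strings)
  if (length(unique(L)) != 1L)
    stop("all strings must have the same length")  # vectorized contract
  L <- L[1L]
  for (lang in names(tables)) {
    tabs <- tables[[lang]]
    ns <- vapply(tabs, `[[`, 0L, "n")
    if (!all(c(1L, 2L, 4L) %in% ns))
      stop("tables for language ", lang, " must cover n = 1, 2, 4")
    for (tab in tabs) {
      n <- tab$n
      k <- L - n + 1L
      g <- unlist(lapply(seq_len(k),
                         function(i) substr(strings, i, i + n - 1L)),
                  use.names = FALSE)
      vals <- unname(tab$logfreq)
      v <- vals[match(g, names(tab$logfreq))]
      v[is.na(v)] <- tab$floor
      m <- rowMeans(matrix(v, nrow = length(strings), ncol = k))
      out[[paste0(lvl_name[[as.character(n)]], lang)]] <- m
    }
  }
  out
}

#' Enumerate candidate nonword strings
#'
#' Emits, in lexicographic order, every string of the requested length over
#' the alphabet that (i) contains at least one attested quadrigram, (ii)
#' contains no embedded word of length >= \code{embed_min_len} from either
#' lexicon, and (iii) is not itself a word in either lexicon. Internally the
#' stream is produced by extending attested quadrigrams with all possible
#' flanking letters, which is equivalent to filtering the full enumeration
#' (every survivor of filter (i) contains an attested quadrigram) but avoids
#' materialising \code{|alphabet|^length} strings.
#'
#' @param alphabet character vector of letters.
#' @param length string length (the bilingual design uses 6).
#' @param quadrigrams character vector of attested quadrigrams (typically the
#'   union over both languages' tables).
#' @param lexica list of \code{\link{lexicon}} objects (may be empty).
#' @param embed_min_len minimum length of embedded words to exclude
#'   (default 5).
#' @param max_candidates optional cap; if the expanded pool exceeds it, a
#'   deterministic seeded subsample of that size is returned (still sorted).
#'   The subsample's flanking letters are importance-sampled from the
#'   lexica's pooled letter frequencies (uniform if no lexica are given), so
#'   the capped pool is dense in orthographically plausible strings rather
#'   than dominated by implausible uniform-random flanks; with an unlimited
#'   cap the enumeration is exhaustive and this plays no role.
#' @param seed integer seed used only when subsampling.
#' @return sorted character vector (possibly empty).
#' @export
enumerate_candidates <- function(alphabet, length = 6L, quadrigrams,
                                 lexica = list(), embed_min_len = 5L,
                                 max_candidates = Inf, seed = 1L) {
  length <- as.integer(length)
  if (length < 4L) stop("length must be >= 4")
  quadrigrams <- unique(toupper(quadrigrams))
  if (!length(quadrigrams)) return(character(0))
  if (any(nchar(quadrigrams) != 4L)) stop("quadrigrams must have length 4")
  nfill <- length - 4L
  fills <- if (nfill == 0L) "" else
    do.call(paste0, rev(expand.grid(rep(list(alphabet), nfill),
                                    stringsAsFactors = FALSE)))
  npos <- length - 3L
  # cap before expansion when the full pool would be too large
  est <- as.numeric(base::length(quadrigrams)) * npos * base::length(fills)
  sample_fills <- is.finite(max_candidates) && est > max_candidates
  cand <- vector("list", npos)
  if (sample_fills) {
    rs <- local_seed(seed)
    on.exit(restore_seed(rs), add = TRUE)
    # flanks grow from the seed quadrigram through the lexica's pooled
    # bigram transition structure (forward after it, backward before it),
    # so sampled candidates are as orthographically plausible as words;
    # uniform transitions when no lexica are given
    A <- base::length(alphabet)
    Tf <- matrix(1, A, A, dimnames = list(alphabet, alphabet))
    if (base::length(lexica)) {
      cnt <- matrix(0, A, A, dimnames = list(alphabet, alphabet))
      for (lx in lexica) {
        tab <- build_ngram_table(lx, 2L, floor = -Inf)
        lf <- tab$logfreq
        a1 <- substr(names(lf), 1L, 1L)
        a2 <- substr(names(lf), 2L, 2L)
        cnt[cbind(a1, a2)] <- cnt[cbind(a1, a2)] + 10^lf
      }
      if (sum(cnt) > 0) Tf <- cnt + sum(cnt) / (A * A) * 0.01
    }
    Tfwd <- Tf / rowSums(Tf)           # next letter given previous
    Tbwd <- t(Tf) / colSums(Tf)        # previous letter given next
    step <- function(P, from_idx) {
      out <- integer(base::length(from_idx))
      for (a in seq_len(A)) {
        rows <- which(from_idx == a)
        if (base::length(rows))
          out[rows] <- sample.int(A, base::length(rows), replace = TRUE,
                                  prob = P[a, ])
      }
      out
    }
    ai <- stats::setNames(seq_len(A), alphabet)
    per_pos <- ceiling(1.6 * max_candidates / npos)
    for (p in seq_len(npos)) {
      q <- sample(quadrigrams, per_pos, replace = TRUE)
      n_pre <- p - 1L
      n_suf <- nfill - n_pre
      pre <- rep("", per_pos); suf <- rep("", per_pos)
      cur <- ai[substr(q, 1L, 1L)]
      for (i in seq_len(n_pre)) {
        cur <- step(Tbwd, cur)
        pre <- paste0(alphabet[cur], pre)
      }
      cur <- ai[substr(q, 4L, 4L)]
      for (i in seq_len(n_suf)) {
        cur <- step(Tfwd, cur)
        suf <- paste0(suf, alphabet[cur])
      }
      cand[[p]] <- paste0(pre, q, suf)
    }
  } else {
    for (p in seq_len(npos)) {
      pre <- substr(fills, 1L, p - 1L)
      suf <- substr(fills, p, nfill)
      nq <- base::length(quadrigrams)
      nf <- base::length(fills)
      cand[[p]] <- paste0(rep(pre, times = nq),
                          rep(quadrigrams, each = nf),
                          rep(suf, times = nq))
    }
  }
  cand <- sort(unique(unlist(cand, use.names = FALSE)))
  # embedded-word and whole-word filters
  all_words <- unlist(lapply(lexica, `[[`, "words"), use.names = FALSE)
  if (base::length(all_words)) {
    cand <- cand[!cand %in% all_words]
    for (wl in seq(embed_min_len, length)) {
      wset <- all_words[nchar(all_words) == wl]
      if (!base::length(wset)) next
      for (s in seq_len(length - wl + 1L)) {
        if (!base::length(cand)) break
        cand <- cand[!substr(cand, s, s + wl - 1L) %in% wset]
      }
    }
  }
  if (is.finite(max_candidates) && base::length(cand) > max_candidates) {
    rs <- local_seed(seed + 1L)
    on.exit(restore_seed(rs), add = TRUE)
    cand <- sort(sample(cand, max_candidates))
  }
  cand
}
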
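#' Condition labels of the bilingual designs
#'
#' The alphabetic two-language design crosses component level (letters L,
#' bigrams B, quadrigrams Q) with per-language frequency: "-" low in both
#' languages, "E" high in the first language only, "F" high in the second
#' only, "+" high in both; plus two real-word categories WE and WF. The
#' logographic design pairs six alphabetic component conditions and real
#' words of the first language with a seven-step character hierarchy
#' (strokes S, stroke groups SG, radicals in impossible RI and possible RP
#' positions, character pairs CP, low- and high-frequency real words WL,
#' WH).
#'
#' @param design "enfr" (alphabetic-alphabetic) or "encn"
#'   (alphabetic-logographic).
#' @return character vector of condition labels in canonical order.
#' @export
condition_labels <- function(design = c("enfr", "encn")) {
  design <- match.arg(design)
  if (design == "enfr")
    c("L-", "LE", "LF", "L+",
      "B-", "BE", "BF", "B+",
      "Q-", "QE", "QF", "Q+",
      "WE", "WF")
  else
    c("L-", "L+", "B-", "B+", "Q-", "Q+", "WE",
      "S", "SG", "RI", "RP", "CP", "WL", "WH")
}

# stat column names for the two language roles, in canonical order
design_stat_cols <- function() {
  c("letE", "bigE", "quadE", "letF", "bigF", "quadF")
}

#' Quantile band thresholds for candidate statistics
#'
#' Defines, per language and component level, a low band (at or below the
#' lower quantile), a high band (at or above the upper quantile) and a
#' neutral band (the open interval between them). Quantiles are computed
#' over the informative sub-population — candidates whose statistic lies
#' above the unattested floor. This matters only for levels with a floor
#' pile-up (in practice quadrigrams, where a candidate seeded from one
#' language's quadrigram is frequently all-unattested in the other): such
#' all-floor candidates belong to the low band by definition, and without
#' the restriction the lower quartile degenerates onto the floor itself,
#' emptying the low-low cell.
#'
#' @param stats data.frame from \code{\link{string_component_stats}} with
#'   columns \code{letE, bigE, quadE, letF, bigF, quadF}.
#' @param probs length-2 vector of quantile probabilities; default outer
#'   quartiles \code{c(0.25, 0.75)}.
#' @param floor the n-gram tables' floor value; statistics at or below it
#'   are excluded from the quantile computation (set to \code{-Inf} to use
#'   the full population).
#' @return object of class \code{band_thresholds}: data.frame with columns
#'   \code{stat}, \code{low_max}, \code{high_min}.
#' @export
band_thresholds <- function(stats, probs = c(0.25, 0.75),
                            floor = log10(0.01)) {
  if (length(probs) != 2L || probs[1L] >= probs[2L])
    stop("probs must be two increasing probabilities")
  cols <- design_stat_cols()
  if (!all(cols %in% names(stats)))
    stop("stats must contain columns ", paste(cols, collapse = ", "))
  qs <- vapply(cols, function(cl) {
    x <- stats[[cl]]
    xa <- x[x > floor + 1e-9]
    if (length(xa) < 10L) xa <- x
    stats::quantile(xa, probs, names = FALSE)
  }, numeric(2L))
  out <- data.frame(stat = cols, low_max = qs[1L, ], high_min = qs[2L, ],
                    row.names = NULL)
  if (any(out$low_max >= out$high_min))
    stop("degenerate thresholds: low band meets high band for ",
         paste(out$stat[out$low_max >= out$high_min], collapse = ", "))
  class(out) <- c("band_thresholds", "data.frame")
  out
}

# band codes (-1 low, 0 neutral, +1 high) per statistic
band_matrix <- function(stats, thresholds) {
  cols <- design_stat_cols()
  band <- matrix(0L, nrow = nrow(stats), ncol = length(cols),
                 dimnames = list(NULL, cols))
  for (cl in cols) {
    th <- thresholds[thresholds$stat == cl, ]
    x <- stats[[cl]]
    band[x <= th$low_max, cl] <- -1L
    band[x >= th$high_min, cl] <- 1L
  }
  band
}

#' Classify candidate strings into design cells
#'
#' A string is assigned to the 2 x 2 cell of a target component level when
#' its statistic at that level falls in the required band in BOTH languages
#' and its statistics at the two other levels fall in the neutral band in
#' both languages (the decorrelation constraint). Strings meeting no cell's
#' requirements are unclassified (NA). A string can match at most one level:
#' qualifying at one level forces non-neutral bands there, which disqualifies
#' every other level.
#'
#' @param stats data.frame of candidate statistics (see
#'   \code{\link{string_component_stats}}), columns \code{letE ... quadF}.
#' @param thresholds a \code{\link{band_thresholds}} object.
#' @return character vector of cell labels ("L-", "LE", ..., "Q+") or NA,
#'   one per row of \code{stats}.
#' @export
classify_candidate <- function(stats, thresholds) {
  stopifnot(inherits(thresholds, "band_thresholds"))
  if (any(thresholds$low_max >= thresholds$high_min))
    stop("thresholds with low >= high")
  band <- band_matrix(stats, thresholds)
  levels <- c(let = "L", big = "B", quad = "Q")
  out <- rep(NA_character_, nrow(stats))
  for (lv in names(levels)) {
    others <- setdiff(names(levels), lv)
    neutral <- rowSums(abs(band[, paste0(rep(others, each = 2L),
                                         c("E", "F")), drop = FALSE])) == 0L
    be <- band[, paste0(lv, "E")]
    bf <- band[, paste0(lv, "F")]
    cell <- rep(NA_character_, nrow(stats))
    cell[be == -1L & bf == -1L] <- paste0(levels[[lv]], "-")
    cell[be ==  1L & bf == -1L] <- paste0(levels[[lv]], "E")
    cell[be == -1L & bf ==  1L] <- paste0(levels[[lv]], "F")
    cell[be ==  1L & bf ==  1L] <- paste0(levels[[lv]], "+")
    hit <- neutral & !is.na(cell)
    out[hit] <- cell[hit]
  }
  out
}

#' Greedy decorrelated selection of category items
#'
#' From the eligible candidates of one design cell, selects exactly
#' \code{n_items} strings by greedy optimization: after a seeded random pair
#' of starting items, each step adds the candidate minimizing the summed
#' absolute Pearson correlation, within the growing category, between the
#' target-level statistics (both languages) and every non-target-level
#' statistic. This keeps, e.g., quadrigram frequency flat across a
#' letter-frequency cell.
#'
#' @param stats data.frame of candidate statistics (all candidates).
#' @param eligible integer indices (rows of \code{stats}) eligible for the
#'   cell.
#' @param target_level "let", "big" or "quad".
#' @param n_items number of items to select.
#' @param seed integer seed (starting pair).
#' @param target_means optional named vector over the six statistics; when
#'   given, the greedy objective adds \code{target_weight} times the worst
#'   absolute deviation of the growing category's means from it (used to
#'   pull the quadrigram cells toward the statistics real words can match).
#' @param target_weight weight of the mean-targeting term.
#' @return list with \code{idx} (selected rows of \code{stats}, sorted) and
#'   \code{achieved} (data.frame of cross-level correlations within the
#'   selection).
#' @export
select_category_items <- function(stats, eligible, target_level, n_items,
                                  seed = 1L, target_means = NULL,
                                  target_weight = 2) {
  if (length(eligible) < n_items)
    stop("infeasible cell (", target_level, "): ", length(eligible),
         " eligible candidates for ", n_items, " items")
  stopifnot(target_level %in% c("let", "big", "quad"))
  tcols <- paste0(target_level, c("E", "F"))
  ocols <- setdiff(design_stat_cols(), tcols)
  X <- as.matrix(stats[eligible, design_stat_cols()])
  m <- nrow(X)
  rs <- local_seed(seed)
  on.exit(restore_seed(rs), add = TRUE)
  chosen <- logical(m)
  first <- sample.int(m, min(2L, n_items))
  chosen[first] <- TRUE
  pairs <- expand.grid(t = tcols, o = ocols, stringsAsFactors = FALSE)
  cols <- design_stat_cols()
  # running sums over the chosen set, updated incrementally
  S <- colSums(X[first, , drop = FALSE])
  SS <- crossprod(X[first, , drop = FALSE])
  n_chosen <- length(first)
  while (n_chosen < n_items) {
    rem <- which(!chosen)
    n1 <- n_chosen + 1L
    obj <- numeric(length(rem))
    for (k in seq_len(nrow(pairs))) {
      tc <- pairs$t[k]; oc <- pairs$o[k]
      xt <- X[rem, tc]; xo <- X[rem, oc]
      Sx <- S[tc] + xt; Sy <- S[oc] + xo
      Sxx <- SS[tc, tc] + xt * xt
      Syy <- SS[oc, oc] + xo * xo
      Sxy <- SS[tc, oc] + xt * xo
      num <- n1 * Sxy - Sx * Sy
      den2 <- pmax(n1 * Sxx - Sx^2, 0) * pmax(n1 * Syy - Sy^2, 0)
      r <- ifelse(den2 > 0, num / sqrt(den2), 0)
      obj <- obj + abs(r)
    }
    if (!is.null(target_means)) {
      dev <- abs((S[cols[1L]] + X[rem, cols[1L]]) / n1 -
                   target_means[[cols[1L]]])
      for (cl in cols[-1L])
        dev <- pmax(dev, abs((S[cl] + X[rem, cl]) / n1 -
                               target_means[[cl]]))
      obj <- obj + target_weight * dev
    }
    j <- rem[which.min(obj)]
    chosen[j] <- TRUE
    S <- S + X[j, ]
    SS <- SS + tcrossprod(X[j, ])
    n_chosen <- n1
  }
  Xc <- X[chosen, , drop = FALSE]
  ach <- pairs
  ach$r <- mapply(function(tc, oc) {
    if (stats::sd(Xc[, tc]) == 0 || stats::sd(Xc[, oc]) == 0) return(NA_real_)
    stats::cor(Xc[, tc], Xc[, oc])
  }, ach$t, ach$o)
  list(idx = sort(eligible[chosen]), achieved = ach)
}

#' Select real words matching a nonword category's statistics
#'
#' Greedily picks \code{n_items} words whose category-mean letter, bigram
#' and quadrigram statistics (in both languages) come as close as possible
#' to a target vector of category means, then errors if any per-statistic
#' absolute difference exceeds \code{tolerance}. Deterministic: each step
#' adds the word minimizing the worst post-addition deviation of the running
#' mean from the target.
#'
#' @param word_stats data.frame with column \code{string} and the six stat
#'   columns, one row per candidate word.
#' @param target_means named numeric vector of category means over
#'   \code{letE ... quadF} (e.g. the means of a quadrigram cell).
#' @param n_items number of words to select.
#' @param tolerance maximum allowed absolute difference per statistic on
#'   category means (log10 units, default 0.1).
#' @param enforce error when the tolerance is not met (default); with
#'   \code{FALSE}, return the best-effort selection and its deltas.
#' @return list with \code{idx} (rows of \code{word_stats}), \code{deltas}
#'   (named per-statistic achieved mean differences).
#' @export
match_words <- function(word_stats, target_means, n_items, tolerance = 0.1,
                        enforce = TRUE) {
  cols <- design_stat_cols()
  if (!all(cols %in% names(target_means)))
    stop("target_means must be named over ", paste(cols, collapse = ", "))
  if (nrow(word_stats) < n_items)
    stop("only ", nrow(word_stats), " candidate words for ", n_items,
         " items")
  X <- as.matrix(word_stats[, cols])
  tgt <- target_means[cols]
  m <- nrow(X)
  chosen <- logical(m)
  S <- numeric(length(cols))
  for (k in seq_len(n_items)) {
    rem <- which(!chosen)
    dev <- abs(sweep(X[rem, , drop = FALSE], 2L, S, `+`) / k -
                 matrix(tgt, length(rem), length(cols), byrow = TRUE))
    score <- apply(dev, 1L, max)
    j <- rem[which.min(score)]
    chosen[j] <- TRUE
    S <- S + X[j, ]
  }
  deltas <- S / n_items - tgt
  if (enforce && max(abs(deltas)) > tolerance)
    stop("no word selection within tolerance ", tolerance,
         "; best achievable per-statistic deltas: ",
         paste(sprintf("%s=%.3f", cols, deltas), collapse = ", "))
  list(idx = which(chosen), deltas = deltas)
}

# Importance-sampled proposals for one design cell. Every proposal embeds
# an attested quadrigram by construction: quadrigrams are sampled with
# weights matching the cell's band signature (letter- or bigram-level tilt
# toward high/low in each language, shaped toward the neutral quadrigram
# band for letter/bigram cells), then extended with flanking letters drawn
# from a tilted transition chain. Proposals then pass the same filters and
# fixed thresholds as every other candidate — the proposal distribution
# only concentrates the search; eligibility is unchanged.
enrich_cell <- function(label, tables, thr, quads, lexica, alphabet,
                        string_length, batch_size = 1e5L, z = 0.9) {
  level <- c(L = "let", B = "big", Q = "quad")[[substr(label, 1L, 1L)]]
  cell <- substr(label, 2L, 2L)
  sE <- switch(cell, `-` = -1, `+` = 1, E = 1, F = -1)
  sF <- switch(cell, `-` = -1, `+` = 1, E = -1, F = 1)
  A <- length(alphabet)
  l1E <- ngram_lookup(tables$E[[1L]], alphabet)
  l1F <- ngram_lookup(tables$F[[1L]], alphabet)
  prs <- as.vector(outer(alphabet, alphabet,
                         function(a, b) paste0(a, b)))
  l2E <- matrix(ngram_lookup(tables$E[[2L]], prs), A, A)
  l2F <- matrix(ngram_lookup(tables$F[[2L]], prs), A, A)
  plaus <- (l2E + l2F) / 2           # cross-language log plausibility
  band_mid <- function(stat) {
    th <- thr[thr$stat == stat, ]
    c(mid = (th$low_max + th$high_min) / 2,
      bw = (th$high_min - th$low_max) / 2)
  }
  # per-quadrigram scores at the cell's target level
  gram_rows <- function(q, n) {
    k <- 4L - n + 1L
    vapply(seq_len(k), function(i) substr(q, i, i + n - 1L),
           character(length(q)))
  }
  q4E <- ngram_lookup(tables$E[[3L]], quads)
  q4F <- ngram_lookup(tables$F[[3L]], quads)
  if (level == "let") {
    ai <- stats::setNames(seq_len(A), alphabet)
    lets <- gram_rows(quads, 1L)
    scE <- rowMeans(matrix(l1E[ai[lets]], nrow = length(quads)))
    scF <- rowMeans(matrix(l1F[ai[lets]], nrow = length(quads)))
  } else {
    pi_ <- stats::setNames(seq_along(prs), prs)
    bgs <- gram_rows(quads, 2L)
    scE <- rowMeans(matrix(as.vector(l2E)[pi_[bgs]], nrow = length(quads)))
    scF <- rowMeans(matrix(as.vector(l2F)[pi_[bgs]], nrow = length(quads)))
  }
  lw <- z * (sE * scE + sF * scF)
  if (level != "quad") {
    # shape toward the neutral quadrigram band in both languages
    bE <- band_mid("quadE"); bF <- band_mid("quadF")
    lw <- lw - ((q4E - bE[["mid"]]) / (2 * bE[["bw"]]))^2 -
      ((q4F - bF[["mid"]]) / (2 * bF[["bw"]]))^2
  } else {
    lw <- lw + 0.5 * pmax(q4E, q4F)  # favor attested, frequent quadrigrams
  }
  wq <- exp(lw - max(lw))
  # flank transition chain with the same tilt
  logw <- 0.5 * plaus + z * (sE * l2E + sF * l2F)
  logw <- logw - max(logw)
  Tfwd <- exp(logw); Tfwd <- Tfwd / rowSums(Tfwd)
  Tbwd <- t(exp(logw)); Tbwd <- Tbwd / rowSums(Tbwd)
  step <- function(P, from) {
    o <- order(from)
    cnt <- tabulate(from, A)
    out <- integer(length(from))
    pos <- 1L
    for (a in seq_len(A)) {
      if (cnt[a] > 0L) {
        out[o[pos:(pos + cnt[a] - 1L)]] <-
          sample.int(A, cnt[a], replace = TRUE, prob = P[a, ])
        pos <- pos + cnt[a]
      }
    }
    out
  }
  ai <- stats::setNames(seq_len(A), alphabet)
  nfill <- string_length - 4L
  npos <- string_length - 3L
  per_pos <- ceiling(batch_size / npos)
  cand <- vector("list", npos)
  for (p in seq_len(npos)) {
    q <- sample(quads, per_pos, replace = TRUE, prob = wq)
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
  cand <- filter_candidates(unique(unlist(cand)), quads, lexica,
                            string_length)
  if (!length(cand)) return(NULL)
  st <- string_component_stats(cand, tables)
  st[classify_candidate(st, thr) %in% label, , drop = FALSE]
}

# Local-search repair proposals for one design cell: pool strings that
# violate at most `max_viol` of the cell's six band requirements are
# perturbed by single-letter substitutions at every position; variants
# frequently fix the violated band while keeping the others, so accepted
# proposals concentrate near the cell's feasible corner. Acceptance runs
# through the same filters and fixed thresholds as all candidates.
repair_cell <- function(label, pool, thr, tables, quads, lexica, alphabet,
                        string_length, n_base = 1500L, max_viol = 2L) {
  level <- c(L = "let", B = "big", Q = "quad")[[substr(label, 1L, 1L)]]
  cell <- substr(label, 2L, 2L)
  sE <- switch(cell, `-` = -1L, `+` = 1L, E = 1L, F = -1L)
  sF <- switch(cell, `-` = -1L, `+` = 1L, E = -1L, F = 1L)
  req <- stats::setNames(integer(6L), design_stat_cols())
  req[paste0(level, "E")] <- sE
  req[paste0(level, "F")] <- sF
  nviol <- function(st) {
    b <- band_matrix(st, thr)
    rowSums(b != matrix(req, nrow(b), 6L, byrow = TRUE))
  }
  near <- which(nviol(pool) <= max_viol)  # members seed further variants
  if (!length(near)) return(NULL)
  if (length(near) > n_base) near <- sample(near, n_base)
  base <- pool$string[near]
  vars <- vector("list", string_length)
  for (p in seq_len(string_length)) {
    pre <- substr(base, 1L, p - 1L)
    suf <- substr(base, p + 1L, string_length)
    vars[[p]] <- paste0(rep(pre, length(alphabet)),
                        rep(alphabet, each = length(base)),
                        rep(suf, length(alphabet)))
  }
  cand <- unique(unlist(vars, use.names = FALSE))
  cand <- filter_candidates(cand, quads, lexica, string_length)
  cand <- setdiff(cand, pool$string)
  if (!length(cand)) return(NULL)
  st <- string_component_stats(cand, tables)
  lab <- classify_candidate(st, thr)
  frontier <- st[is.na(lab) & nviol(st) <= 1L, , drop = FALSE]
  list(classified = st[!is.na(lab), , drop = FALSE],
       classified_labels = lab[!is.na(lab)],
       frontier = frontier)
}

# Word-mutation proposals for the quadrigram cells: replace the first or
# last letter of a real word of the cell's high-frequency language with
# every other letter. Such "word-looking pseudo-words" keep two of their
# three quadrigrams at word-level frequencies while the usual filters
# (not a word, no embedded word, attested quadrigram present) and the
# fixed thresholds decide acceptance exactly as for any other candidate.
word_mutation_candidates <- function(lex_own, alphabet, string_length = 6L,
                                     max_base = 3000L) {
  keep <- nchar(lex_own$words) == string_length
  base <- lex_own$words[keep]
  if (!length(base)) return(character(0))
  if (length(base) > max_base)
    base <- base[order(lex_own$freq[keep],
                       decreasing = TRUE)[seq_len(max_base)]]
  first <- substr(base, 1L, 1L)
  last <- substr(base, string_length, string_length)
  body_head <- substr(base, 2L, string_length)
  body_tail <- substr(base, 1L, string_length - 1L)
  out <- c(
    paste0(rep(alphabet, each = length(base)), body_head),
    paste0(body_tail, rep(alphabet, each = length(base))))
  keep <- c(rep(alphabet, each = length(base)) != first,
            rep(alphabet, each = length(base)) != last)
  unique(out[keep])
}

# apply the enumeration filters to an arbitrary set of proposal strings
filter_candidates <- function(cand, quads, lexica, string_length = 6L,
                              embed_min_len = 5L) {
  if (!length(cand)) return(character(0))
  has_quad <- rep(FALSE, length(cand))
  for (p in seq_len(string_length - 3L))
    has_quad <- has_quad | substr(cand, p, p + 3L) %in% quads
  cand <- cand[has_quad]
  all_words <- unlist(lapply(lexica, `[[`, "words"), use.names = FALSE)
  if (length(all_words) && length(cand)) {
    cand <- cand[!cand %in% all_words]
    for (wl in seq(embed_min_len, string_length)) {
      wset <- all_words[nchar(all_words) == wl]
      if (!length(wset)) next
      for (s in seq_len(string_length - wl + 1L)) {
        if (!length(cand)) break
        cand <- cand[!substr(cand, s, s + wl - 1L) %in% wset]
      }
    }
  }
  cand
}

#' Build the full 14-category bilingual stimulus design
#'
#' Runs the whole generation pipeline on two lexica sharing an alphabet:
#' n-gram tables (letters, bigrams, quadrigrams) for both languages;
#' enumeration of candidate six-letter nonwords containing an attested
#' quadrigram, free of embedded words; quantile-band classification into the
#' 12 nonword cells; greedy decorrelated selection of
#' \code{items_per_category} items per cell; and selection of real-word
#' categories WE and WF matched to the corresponding quadrigram cells (QE
#' and QF) on all six component statistics.
#'
#' @param lex_e,lex_f \code{\link{lexicon}} objects for the two languages
#'   (first plays the "E" role, second the "F" role).
#' @param items_per_category items per condition (study value 180).
#' @param floor log10 floor for unattested n-grams.
#' @param weighting n-gram count weighting, "token" or "type".
#' @param band_probs quantile probabilities for low/high bands.
#' @param match_tolerance word-matching tolerance on category means.
#' @param word_freq_range allowed per-million frequency range of the real
#'   words.
#' @param string_length stimulus length (6).
#' @param max_candidates cap on the candidate pool (deterministic subsample
#'   above it).
#' @param max_enrich_batches maximum importance-sampling batches per
#'   thinly covered cell (0 disables enrichment). Proposal strings come
#'   from a chain tilted toward the cell's band signature but are accepted
#'   only through the same filters and fixed thresholds as every other
#'   candidate.
#' @param seed integer seed governing subsampling and greedy starts.
#' @return list with \code{design} (class \code{condition_design}: labels,
#'   thresholds, diagnostics) and \code{stimuli} (data.frame: string,
#'   category, six statistic columns).
#' @export
build_design <- function(lex_e, lex_f, items_per_category = 180L,
                         floor = log10(0.01),
                         weighting = c("token", "type"),
                         band_probs = c(0.25, 0.75),
                         match_tolerance = 0.1,
                         word_freq_range = c(7, 761),
                         string_length = 6L,
                         max_candidates = 2e5,
                         max_enrich_batches = 20L,
                         seed = 1L) {
  stopifnot(inherits(lex_e, "lexicon"), inherits(lex_f, "lexicon"))
  weighting <- match.arg(weighting)
  if (!identical(lex_e$alphabet, lex_f$alphabet))
    stop("the two lexica must share an alphabet")
  tables <- list(
    E = lapply(c(1L, 2L, 4L), function(n)
      build_ngram_table(lex_e, n, floor = floor, weighting = weighting)),
    F = lapply(c(1L, 2L, 4L), function(n)
      build_ngram_table(lex_f, n, floor = floor, weighting = weighting)))
  quads <- unique(c(names(tables$E[[3L]]$logfreq),
                    names(tables$F[[3L]]$logfreq)))
  cand <- enumerate_candidates(lex_e$alphabet, string_length, quads,
                               list(lex_e, lex_f),
                               max_candidates = max_candidates, seed = seed)
  if (!length(cand)) stop("candidate enumeration produced no strings")
  stats <- string_component_stats(cand, tables)
  thr <- band_thresholds(stats, probs = band_probs, floor = floor)
  labels <- classify_candidate(stats, thr)
  # word-mutation proposals give the quadrigram cells candidates with
  # word-level quadrigram statistics (so the real-word categories can be
  # matched later); same filters and thresholds as all other candidates
  for (qlab in c("QE", "QF")) {
    lex_own <- if (qlab == "QE") lex_e else lex_f
    prop <- word_mutation_candidates(lex_own, lex_e$alphabet, string_length)
    prop <- filter_candidates(prop, quads, list(lex_e, lex_f),
                              string_length)
    prop <- setdiff(prop, stats$string)
    if (length(prop)) {
      ps <- string_component_stats(prop, tables)
      pl <- classify_candidate(ps, thr)
      keep <- pl %in% qlab
      if (any(keep)) {
        stats <- rbind(stats, ps[keep, , drop = FALSE])
        labels <- c(labels, pl[keep])
      }
    }
  }
  nonword_labels <- setdiff(condition_labels("enfr"), c("WE", "WF"))
  counts <- table(factor(labels, levels = nonword_labels))
  # importance-sampled proposals for cells the uniform pool covers thinly
  target <- ceiling(1.25 * items_per_category)
  deficient <- nonword_labels[counts < target]
  if (length(deficient) && max_enrich_batches > 0L) {
    rs <- local_seed(seed + 7777L)
    on.exit(restore_seed(rs), add = TRUE)
    for (lab in deficient) {
      batch <- 0L
      stalled <- 0L
      frontier <- stats[0L, , drop = FALSE]
      while (counts[[lab]] < target && batch < max_enrich_batches &&
             stalled < 6L) {
        batch <- batch + 1L
        gained <- 0L
        if (substr(lab, 1L, 1L) == "Q") {
          extra <- enrich_cell(lab, tables, thr, quads,
                               list(lex_e, lex_f), lex_e$alphabet,
                               string_length,
                               z = c(0.6, 0.9, 1.2, 1.5)[(batch - 1L) %%
                                                           4L + 1L])
          if (!is.null(extra))
            extra <- extra[!extra$string %in% stats$string, , drop = FALSE]
          if (!is.null(extra) && nrow(extra)) {
            stats <- rbind(stats, extra)
            labels <- c(labels, rep(lab, nrow(extra)))
            counts[[lab]] <- counts[[lab]] + nrow(extra)
            gained <- nrow(extra)
          }
        } else {
          # local-search repair over the pool plus the unaccepted frontier
          pool <- rbind(stats, frontier)
          rep_out <- repair_cell(lab, pool, thr, tables, quads,
                                 list(lex_e, lex_f), lex_e$alphabet,
                                 string_length,
                                 n_base = 1500L + 700L * stalled,
                                 max_viol = if (batch > 6L) 3L else 2L)
          if (!is.null(rep_out)) {
            cl <- rep_out$classified
            keep <- !cl$string %in% stats$string
            cl <- cl[keep, , drop = FALSE]
            cl_lab <- rep_out$classified_labels[keep]
            if (nrow(cl)) {
              stats <- rbind(stats, cl)
              labels <- c(labels, cl_lab)
              hit <- table(factor(cl_lab, levels = nonword_labels))
              counts <- counts + hit
              gained <- hit[[lab]]
            }
            fr <- rep_out$frontier
            fr <- fr[!fr$string %in% frontier$string, , drop = FALSE]
            if (nrow(fr)) frontier <- rbind(frontier, fr)
            if (nrow(frontier) > 20000L)
              frontier <- frontier[seq(nrow(frontier) - 20000L + 1L,
                                       nrow(frontier)), , drop = FALSE]
          }
        }
        stalled <- if (gained > 0L) 0L else stalled + 1L
      }
    }
  }
  deficient <- nonword_labels[counts < items_per_category]
  if (length(deficient))
    stop("infeasible cells (fewer than ", items_per_category,
         " eligible candidates): ",
         paste(sprintf("%s=%d", deficient, counts[deficient]),
               collapse = ", "))
  # statistics of the eligible real-word pools, for co-targeting the
  # quadrigram cells toward means that words can actually match
  eligible_words <- function(lex_own, lex_other) {
    w <- lex_own$words
    keep <- nchar(w) == string_length &
      !w %in% lex_other$words &
      lex_own$freq >= word_freq_range[1L] &
      lex_own$freq <= word_freq_range[2L]
    if (!any(keep)) stop("no eligible real words in ", lex_own$language_id)
    string_component_stats(w[keep], tables)
  }
  ws_e <- eligible_words(lex_e, lex_f)
  ws_f <- eligible_words(lex_f, lex_e)
  level_of <- c(L = "let", B = "big", Q = "quad")
  sel <- list()
  achieved <- list()
  for (i in seq_along(nonword_labels)) {
    lab <- nonword_labels[i]
    elig <- which(labels == lab)
    if (lab %in% c("QE", "QF")) {
      # alternate the quadrigram cell and its word category toward each
      # other: words are pulled to the cell's achievable means and the
      # cell re-selected against the achievable word means
      ws <- if (lab == "QE") ws_e else ws_f
      tm <- apply(ws[, design_stat_cols()], 2L, stats::median)
      res <- select_category_items(stats, elig, "quad",
                                   items_per_category, seed = seed + i,
                                   target_means = tm, target_weight = 12)
      qmeans <- colMeans(stats[res$idx, design_stat_cols()])
      mw <- match_words(ws, qmeans, items_per_category, enforce = FALSE)
      wmeans <- colMeans(ws[mw$idx, design_stat_cols()])
      res <- select_category_items(stats, elig, "quad",
                                   items_per_category, seed = seed + i,
                                   target_means = wmeans,
                                   target_weight = 12)
    } else {
      res <- select_category_items(stats, elig,
                                   level_of[[substr(lab, 1L, 1L)]],
                                   items_per_category, seed = seed + i)
    }
    sel[[lab]] <- res$idx
    res$achieved$category <- lab
    achieved[[lab]] <- res$achieved
  }
  stim <- do.call(rbind, lapply(nonword_labels, function(lab) {
    d <- stats[sel[[lab]], , drop = FALSE]
    d$category <- lab
    d
  }))
  # real-word categories, matched to the quadrigram cells
  word_cat <- function(ws, q_label) {
    tmeans <- colMeans(stats[sel[[q_label]], design_stat_cols()])
    mw <- match_words(ws, tmeans, items_per_category,
                      tolerance = match_tolerance)
    list(stats = ws[mw$idx, , drop = FALSE], deltas = mw$deltas)
  }
  we <- word_cat(ws_e, "QE")
  wf <- word_cat(ws_f, "QF")
  we$stats$category <- "WE"
  wf$stats$category <- "WF"
  stim <- rbind(stim, we$stats, wf$stats)
  rownames(stim) <- NULL
  stim <- stim[, c("string", "category", design_stat_cols())]
  if (anyDuplicated(stim$string))
    stop("internal error: duplicated strings across categories")
  design <- structure(
    list(labels = condition_labels("enfr"),
         items_per_category = as.integer(items_per_category),
         thresholds = thr,
         languages = c(E = lex_e$language_id, F = lex_f$language_id),
         achieved_correlations = do.call(rbind, achieved),
         word_match_deltas = list(WE = we$deltas, WF = wf$deltas),
         floor = floor, weighting = weighting,
         band_probs = band_probs, string_length = as.integer(string_length),
         seed = as.integer(seed)),
    class = "condition_design")
  list(design = design, stimuli = stim)
}

#' @export
print.condition_design <- function(x, ...) {
  cat("<condition_design>", length(x$labels), "conditions x",
      x$items_per_category, "items; languages:",
      paste(sprintf("%s=%s", names(x$languages), x$languages),
            collapse = ", "), "\n")
  invisible(x)
}

#' Write a stimulus set and its design manifest
#'
#' Emits `stimuli.tsv` (string, category, six statistic columns) and
#' `design.json` (labels, thresholds, seeds, achieved cross-level
#' correlations, word-matching deltas) into a directory.
#'
#' @param design a \code{condition_design}.
#' @param stimuli the stimulus data.frame from \code{\link{build_design}}.
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_design <- function(design, stimuli, dir) {
  stopifnot(inherits(design, "condition_design"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(stimuli, file.path(dir, "stimuli.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(
    labels = design$labels,
    items_per_category = design$items_per_category,
    languages = as.list(design$languages),
    thresholds = as.data.frame(unclass(design$thresholds)),
    achieved_correlations = design$achieved_correlations,
    word_match_deltas = lapply(design$word_match_deltas, as.list),
    floor = design$floor, weighting = design$weighting,
    band_probs = design$band_probs, seed = design$seed)
  jsonlite::write_json(manifest, file.path(dir, "design.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
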
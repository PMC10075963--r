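#' Generate a pair of synthetic bilingual lexica
#'
#' Emulates two word-frequency lexica of languages sharing an alphabet,
#' with Zipf-distributed word frequencies and controllable divergence of
#' their orthographic statistics. Each language has an inventory of
#' morpheme-like letter chunks ("morphs") sampled from a first-order letter
#' chain; words are concatenations of two or three morphs drawn by
#' Zipf-weighted popularity. The chunk structure reproduces a key property
#' of real lexica that a plain letter chain lacks: quadrigram frequency
#' mass concentrates on recurring morph-internal sequences (think of
#' suffixes like -TION or -MENT), so words can carry very frequent
#' quadrigrams while their bigram statistics stay unremarkable — the two
#' levels of component statistics decouple as they do in natural
#' orthographies.
#'
#' Language divergence has two knobs: \code{divergence} perturbs each
#' language's letter propensities and \code{pair_divergence} its letter
#' transitions, on top of a shared core whose strength is
#' \code{concentration}. A fraction of the morph inventory
#' (\code{morph_shared}) is common to both languages (cognate morphology),
#' which gives the languages a shared pool of attested quadrigrams; a
#' fraction of whole words (\code{overlap}) can also be shared verbatim.
#'
#' @param n_words words per language.
#' @param alphabet character vector of letters (default A-Z).
#' @param zipf_exponent exponent s of the word rank-frequency law
#'   freq(r) = C / r^s.
#' @param top_freq frequency per million of the most frequent word.
#' @param concentration sd of the shared chain log-weights; larger values
#'   concentrate both languages on the same preferred letters and
#'   transitions.
#' @param divergence nonnegative sd of language-specific log-weight noise
#'   on letter propensities; 0 = identical letter statistics up to
#'   sampling error.
#' @param pair_divergence nonnegative sd of language-specific log-weight
#'   noise on the transition matrix (bigram preferences).
#' @param n_morphs morph inventory size per language.
#' @param morph_shared fraction of the inventory shared between the two
#'   languages.
#' @param morph_zipf Zipf exponent of morph popularity (how strongly word
#'   formation reuses the same few chunks).
#' @param min_len,max_len word length bounds (concatenations outside the
#'   bounds are resampled).
#' @param overlap fraction of words copied verbatim from language E into
#'   language F (0 = disjoint vocabularies).
#' @param language_ids labels of the two languages.
#' @param seed integer seed; output is fully deterministic given it.
#' @return list of two \code{\link{lexicon}} objects, named by
#'   \code{language_ids}.
#' @examples
#' lx <- make_synthetic_lexica(n_words = 200, seed = 1)
#' sapply(lx, function(l) length(l$words))
#' @export
make_synthetic_lexica <- function(n_words = 2000L,
                                  alphabet = LETTERS,
                                  zipf_exponent = 1.0,
                                  top_freq = 40000,
                                  concentration = 0.8,
                                  divergence = 0.4,
                                  pair_divergence = 0.6,
                                  n_morphs = 400L,
                                  morph_shared = 0.05,
                                  morph_zipf = 1.0,
                                  min_len = 4L, max_len = 8L,
                                  overlap = 0.02,
                                  language_ids = c("synthE", "synthF"),
                                  seed = 1L) {
  if (n_words < 1L) stop("n_words must be >= 1")
  if (overlap < 0 || overlap > 1) stop("overlap must be in [0, 1]")
  if (morph_shared < 0 || morph_shared > 1)
    stop("morph_shared must be in [0, 1]")
  if (divergence < 0 || pair_divergence < 0)
    stop("divergence parameters must be >= 0")
  A <- length(alphabet)
  if (A^4 < 8 * n_words)
    stop("alphabet too small to honor ", n_words, " unique words")
  rs <- local_seed(seed)
  on.exit(restore_seed(rs), add = TRUE)

  shared_init <- stats::rnorm(A, sd = concentration)
  shared_trans <- matrix(stats::rnorm(A * A, sd = concentration), A, A)
  make_chain <- function(tilt_init, tilt_trans) {
    init <- exp(shared_init + tilt_init)
    trans <- exp(shared_trans + tilt_trans)
    list(init = init / sum(init), trans = trans / rowSums(trans))
  }
  chain_string <- function(mod, L) {
    idx <- integer(L)
    idx[1L] <- sample.int(A, 1L, prob = mod$init)
    for (i in seq_len(L - 1L))
      idx[i + 1L] <- sample.int(A, 1L, prob = mod$trans[idx[i], ])
    paste(alphabet[idx], collapse = "")
  }
  morph_lens <- c(2L, 3L, 4L)
  morph_len_probs <- c(0.3, 0.45, 0.25)
  sample_morphs <- function(mod, n, exclude = character(0)) {
    out <- character(0)
    while (length(out) < n) {
      L <- sample(morph_lens, 1L, prob = morph_len_probs)
      m <- chain_string(mod, L)
      if (!m %in% out && !m %in% exclude) out <- c(out, m)
    }
    out
  }
  shared_chain <- make_chain(0, 0)
  chain_e <- make_chain(divergence * stats::rnorm(A),
                        pair_divergence * matrix(stats::rnorm(A * A), A, A))
  chain_f <- make_chain(divergence * stats::rnorm(A),
                        pair_divergence * matrix(stats::rnorm(A * A), A, A))
  n_sh <- round(morph_shared * n_morphs)
  morphs_sh <- sample_morphs(shared_chain, n_sh)
  morphs_e <- c(morphs_sh, sample_morphs(chain_e, n_morphs - n_sh,
                                         exclude = morphs_sh))
  morphs_f <- c(morphs_sh, sample_morphs(chain_f, n_morphs - n_sh,
                                         exclude = morphs_sh))
  sample_words <- function(morphs, n) {
    # Zipf-weighted morph popularity, language-specific rank order
    w <- 1 / sample(seq_along(morphs))^morph_zipf
    words <- character(0)
    while (length(words) < n) {
      need <- n - length(words) + ceiling(n / 4) + 8L
      k <- sample(c(2L, 3L), need, replace = TRUE, prob = c(0.7, 0.3))
      m3 <- character(need)
      m3[k == 3L] <- sample(morphs, sum(k == 3L), replace = TRUE, prob = w)
      new <- paste0(sample(morphs, need, replace = TRUE, prob = w),
                    sample(morphs, need, replace = TRUE, prob = w), m3)
      new <- new[nchar(new) >= min_len & nchar(new) <= max_len]
      words <- unique(c(words, new))
    }
    words[seq_len(n)]
  }
  words_e <- sample_words(morphs_e, n_words)
  words_f <- sample_words(morphs_f, n_words)
  n_shared <- round(overlap * n_words)
  if (n_shared > 0L) {
    # shared words keep their relative frequency order, so full overlap
    # reproduces the first lexicon exactly
    shared <- words_e[sort(sample.int(n_words, n_shared))]
    pool <- setdiff(words_f, shared)
    words_f <- c(shared, pool)[seq_len(n_words)]
  } else {
    clash <- words_f %in% words_e
    while (any(clash)) {
      repl <- sample_words(morphs_f, 2L * sum(clash) + 20L)
      repl <- setdiff(repl, c(words_e, words_f))
      words_f <- unique(c(words_f[!clash], repl))[seq_len(n_words)]
      clash <- words_f %in% words_e
    }
  }
  zipf <- top_freq / seq_len(n_words)^zipf_exponent
  out <- list(
    lexicon(words_e, zipf, language_id = language_ids[1L],
            alphabet = alphabet),
    lexicon(words_f, zipf, language_id = language_ids[2L],
            alphabet = alphabet))
  names(out) <- language_ids
  out
}
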
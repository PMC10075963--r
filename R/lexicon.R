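#' Construct a word-frequency lexicon
#'
#' A lexicon pairs uppercase words over a declared alphabet with corpus
#' frequencies in occurrences per million. It is the input to n-gram
#' frequency tables and to real-word stimulus selection.
#'
#' @param words character vector of words; coerced to uppercase.
#' @param freq numeric vector of occurrences per million, strictly positive.
#' @param language_id short label for the language (e.g. "eng", "fra").
#' @param alphabet character vector of allowed letters. Defaults to A-Z;
#'   accented letters are deliberately not included.
#' @return An object of class \code{lexicon}: a list with elements
#'   \code{language_id}, \code{words}, \code{freq} and \code{alphabet}.
#' @examples
#' lex <- lexicon(c("ab", "bc"), c(10, 30), "toy", alphabet = c("A", "B", "C"))
#' lex$words
#' @export
lexicon <- function(words, freq, language_id = "lang", alphabet = LETTERS) {
  words <- toupper(as.character(words))
  freq <- as.numeric(freq)
  if (length(words) != length(freq))
    stop("'words' and 'freq' must have the same length")
  if (length(words) == 0L) stop("empty lexicon")
  if (anyDuplicated(words))
    stop("duplicated words in lexicon: ",
         paste(unique(words[duplicated(words)])[1:3], collapse = ", "))
  if (any(!is.finite(freq)) || any(freq <= 0))
    stop("all frequencies must be finite and > 0")
  bad <- !grepl(paste0("^[", paste(alphabet, collapse = ""), "]+$"), words)
  if (any(bad))
    stop("words outside the declared alphabet: ",
         paste(utils::head(words[bad], 3), collapse = ", "))
  structure(list(language_id = language_id, words = words, freq = freq,
                 alphabet = alphabet),
            class = "lexicon")
}

#' @export
print.lexicon <- function(x, ...) {
  cat("<lexicon>", x$language_id, ":", length(x$words), "words, alphabet of",
      length(x$alphabet), "letters\n")
  invisible(x)
}

#' Read a lexicon from a two-column TSV file
#'
#' Expects `word<TAB>freq_per_million`, UTF-8. A header line is detected
#' automatically (second field not numeric); lines starting with `#` are
#' ignored.
#'
#' @param path file path.
#' @inheritParams lexicon
#' @return A \code{\link{lexicon}}.
#' @export
read_lexicon <- function(path, language_id = NULL, alphabet = LETTERS) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no data lines in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L))
    stop("expected two tab-separated columns in ", path)
  first_freq <- suppressWarnings(as.numeric(fields[[1L]][2L]))
  if (is.na(first_freq)) fields <- fields[-1L]  # header
  w <- vapply(fields, `[[`, "", 1L)
  f <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  if (anyNA(f)) stop("non-numeric frequency values in ", path)
  if (is.null(language_id))
    language_id <- sub("\\.[^.]*$", "", basename(path))
  lexicon(w, f, language_id = language_id, alphabet = alphabet)
}

#' Write a lexicon to TSV
#'
#' @param lex a \code{\link{lexicon}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_lexicon <- function(lex, path) {
  stopifnot(inherits(lex, "lexicon"))
  utils::write.table(
    data.frame(word = lex$words, freq_per_million = lex$freq),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
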
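# Transcript -> token sequence stage.
#
# Tokenization convention: lowercase, split on whitespace and on any
# punctuation except word-internal hyphens and apostrophes, which are part of
# the token ("guarda-chuva", "d'agua"). No lemmatization or canonical-form
# conversion is applied anywhere in the package.

#' Create a transcript object
#'
#' @param raw_text Transcript text (UTF-8 character scalar).
#' @param subject_id Identifier for the speaker; any string.
#' @return An object of class `transcript`.
#' @export
transcript <- function(raw_text, subject_id = "subject") {
  stopifnot(is.character(raw_text), length(raw_text) >= 1)
  raw_text <- paste(raw_text, collapse = "\n")
  structure(list(subject_id = as.character(subject_id), raw_text = raw_text),
            class = "transcript")
}

#' Read a transcript file
#'
#' One plain-text UTF-8 file per subject; the filename stem is used as the
#' subject identifier.
#'
#' @param path Path to a text file.
#' @return A `transcript` object.
#' @export
read_transcript <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  transcript(lines, subject_id = sub("\\.[^.]*$", "", basename(path)))
}

#' Read all transcripts in a directory
#'
#' @param dir Directory containing one `.txt` file per subject.
#' @return A named list of `transcript` objects (names = subject ids).
#' @export
read_transcripts <- function(dir) {
  paths <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  if (length(paths) == 0L) stop("no .txt transcripts found in ", dir)
  out <- lapply(paths, read_transcript)
  names(out) <- vapply(out, function(t) t$subject_id, character(1))
  out
}

#' Construct a token sequence
#'
#' @param tokens Character vector of cleaned, lowercase word tokens.
#' @param subject_id Identifier carried through the pipeline.
#' @param raw_token_count Token count before stop-word removal; defaults to
#'   `length(tokens)`.
#' @return An object of class `token_sequence`.
#' @export
token_sequence <- function(tokens, subject_id = "subject",
                           raw_token_count = length(tokens)) {
  stopifnot(is.character(tokens), raw_token_count >= length(tokens))
  structure(list(subject_id = as.character(subject_id),
                 tokens = tokens,
                 raw_token_count = as.integer(raw_token_count)),
            class = "token_sequence")
}

#' @export
print.token_sequence <- function(x, ...) {
  cat(sprintf("<token_sequence '%s': %d tokens (%d before stop-word removal)>\n",
              x$subject_id, length(x$tokens), x$raw_token_count))
  invisible(x)
}

#' Tokenize a transcript
#'
#' Lowercases the text, replaces every character that is not a letter, digit,
#' hyphen or apostrophe with a space, splits on whitespace, and strips any
#' leading/trailing hyphens or apostrophes left on token boundaries. Numerals
#' are retained at this stage (they are removed together with stop-words).
#'
#' @param x A `transcript`, or a character scalar of raw text.
#' @param subject_id Used when `x` is a bare string.
#' @return A `token_sequence`; `raw_token_count` equals the number of tokens.
#' @export
tokenize <- function(x, subject_id = "subject") {
  if (inherits(x, "transcript")) {
    subject_id <- x$subject_id
    x <- x$raw_text
  }
  stopifnot(is.character(x), length(x) == 1L)
  txt <- tolower(x)
  # keep letters, digits, hyphen-minus and (typographic) apostrophes; every
  # other character is a separator (em dashes, ellipses, CJK punctuation, ...)
  txt <- gsub("[^\\p{L}\\p{N}'’-]+", " ", txt, perl = TRUE)
  toks <- strsplit(trimws(txt), "[[:space:]]+")[[1]]
  toks <- gsub("^['’-]+|['’-]+$", "", toks)
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0L) {
    stop("empty transcript for subject '", subject_id,
         "': no word tokens after cleaning")
  }
  token_sequence(toks, subject_id = subject_id)
}

#' Construct a stop-word list
#'
#' @param words Character vector of stop words (lowercased on input).
#' @param language_tag Free-form language label, e.g. "pt".
#' @return An object of class `stopword_list`.
#' @export
stopword_list <- function(words, language_tag = "custom") {
  words <- unique(tolower(trimws(words)))
  words <- words[nzchar(words)]
  structure(list(language_tag = language_tag, words = words),
            class = "stopword_list")
}

#' Read a stop-word list from file
#'
#' One token per line; blank lines and lines starting with `#` are ignored.
#'
#' @param path Path to the list file.
#' @param language_tag Label stored on the result.
#' @return A `stopword_list`.
#' @export
read_stopwords <- function(path, language_tag = basename(path)) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  stopword_list(lines, language_tag = language_tag)
}

#' Bundled default stop-word lists
#'
#' Function-word lists for Portuguese (the default, matching the elicitation
#' language of the narrative task this package models) and English. Lists are
#' shipped as plain text under `inst/extdata/stopwords/` and cover articles,
#' prepositions, conjunctions, pronouns and other liaison terms with no
#' specific meaning in oral speech.
#'
#' @param language "pt" or "en".
#' @return A `stopword_list`.
#' @export
default_stopwords <- function(language = c("pt", "en")) {
  language <- match.arg(language)
  path <- system.file("extdata", "stopwords", paste0(language, ".txt"),
                      package = "narragraph", mustWork = TRUE)
  read_stopwords(path, language_tag = language)
}

#' Remove stop-words (and numerals) from a token sequence
#'
#' Order of the surviving tokens is preserved and `raw_token_count` is carried
#' through unchanged, so the pre-removal verbosity of the narrative remains
#' available. Purely numeric tokens are treated as stop-words by a regular
#' expression rather than by list membership, keeping stop-word files purely
#' lexical.
#'
#' @param seq A `token_sequence`.
#' @param stops A `stopword_list` (or character vector).
#' @param drop_numerals Remove tokens consisting entirely of digits
#'   (default `TRUE`).
#' @return A `token_sequence` with the filtered tokens. An empty result is
#'   legal; downstream stages guard against it.
#' @export
remove_stopwords <- function(seq, stops, drop_numerals = TRUE) {
  stopifnot(inherits(seq, "token_sequence"))
  if (inherits(stops, "stopword_list")) stops <- stops$words
  keep <- !(seq$tokens %in% stops)
  if (drop_numerals) keep <- keep & !grepl("^[0-9]+$", seq$tokens)
  token_sequence(seq$tokens[keep], subject_id = seq$subject_id,
                 raw_token_count = seq$raw_token_count)
}
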
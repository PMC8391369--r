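#' Tokenize a string on whitespace
#'
#' Splits on runs of whitespace and drops empty tokens. Shared by the
#' knowledge-base matcher and the word-error-rate alignment so that both
#' operate on the same token alphabet.
#'
#' @param text A character scalar (may be empty).
#' @return Character vector of tokens; `character(0)` for empty input.
#' @examples
#' tokenize("hola  buenos   días")
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text)) return(character(0))
  toks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

#' Normalize a transcribed utterance
#'
#' Cleans text ahead of pattern matching, in this fixed order: Unicode NFC
#' normalization, replacement of every character that is not a Unicode letter
#' or digit by a separator (Spanish diacritics and ñ/ü are letters and are
#' preserved), full lowercasing, whitespace tokenization, and collapse of
#' runs of identical consecutive tokens to a single token — the typical
#' false-start artifact of spontaneous-speech recognition ("este este",
#' "um um", "ee ee").
#'
#' The collapse rule applies to single tokens only; multi-token repeats
#' ("no sé no sé") are left intact.
#'
#' @param text A character scalar, UTF-8 (may be empty).
#' @return An object of class `rt_utterance` with fields `raw` (the input),
#'   `tokens` (character vector) and `text` (tokens joined by single spaces).
#' @examples
#' normalize_utterance("este este um um ee ee")$tokens
#' normalize_utterance("¿Cómo estás?")$text
#' @export
normalize_utterance <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  raw <- text
  if (is.na(text)) text <- ""
  x <- enc2utf8(text)
  x <- stringi_nfc(x)
  # keep Unicode letters, digits and combining marks (marks ride on their
  # base letter); everything else separates tokens
  x <- gsub("[^\\p{L}\\p{N}\\p{M}]+", " ", x, perl = TRUE)
  # locale-independent lowercase for the Spanish alphabet, then generic tolower
  x <- chartr("\u00c1\u00c9\u00cd\u00d3\u00da\u00dc\u00d1",
              "\u00e1\u00e9\u00ed\u00f3\u00fa\u00fc\u00f1", x)
  x <- tolower(x)
  toks <- tokenize(x)
  if (length(toks) > 1L) {
    keep <- c(TRUE, toks[-1L] != toks[-length(toks)])
    toks <- toks[keep]
  }
  structure(
    list(raw = raw, tokens = toks, text = paste(toks, collapse = " ")),
    class = "rt_utterance"
  )
}

# NFC normalization without extra dependencies: iconv on glibc composes
# via translit round-trip only partially, so do targeted composition of the
# Spanish combining sequences we must guarantee (vowel/n/u + combining
# acute/diaeresis/tilde). Other scripts pass through unchanged.
stringi_nfc <- function(x) {
  comb <- c(
    "a\u0301" = "\u00e1", "e\u0301" = "\u00e9", "i\u0301" = "\u00ed",
    "o\u0301" = "\u00f3", "u\u0301" = "\u00fa",
    "A\u0301" = "\u00c1", "E\u0301" = "\u00c9", "I\u0301" = "\u00cd",
    "O\u0301" = "\u00d3", "U\u0301" = "\u00da",
    "n\u0303" = "\u00f1", "N\u0303" = "\u00d1",
    "u\u0308" = "\u00fc", "U\u0308" = "\u00dc"
  )
  for (i in seq_along(comb)) {
    x <- gsub(names(comb)[i], comb[[i]], x, fixed = TRUE)
  }
  x
}

#' @export
print.rt_utterance <- function(x, ...) {
  cat("<utterance> ", encodeString(x$text, quote = '"'), "  [",
      length(x$tokens), " tokens]\n", sep = "")
  invisible(x)
}
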
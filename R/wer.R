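#' Word error rate with S/I/D decomposition
#'
#' Both transcripts pass through the utterance normalizer (punctuation
#' stripped, lowercased, consecutive repeats collapsed) so the metric is
#' case- and punctuation-insensitive, the usual convention when scoring
#' speech recognizers. A unit-cost Levenshtein alignment of the token
#' sequences yields substitutions `S`, insertions `I` and deletions `D`, and
#'
#'   WER = (S + I + D) / N
#'
#' with `N` the reference token count. `S + I + D` equals the edit distance;
#' the decomposition canonicalizes alignment ties by preferring substitution
#' over deletion over insertion. WER is 0 for a perfect transcription and
#' may exceed 1 when the hypothesis inserts more than the reference holds.
#'
#' @param reference Reference (ground-truth) transcript string.
#' @param hypothesis Recognizer output string.
#' @return Object of class `rt_wer`: list with `N`, `S`, `I`, `D`, `wer`.
#' @examples
#' word_error_rate("a b c d", "a x c")
#' @export
word_error_rate <- function(reference, hypothesis) {
  ref <- normalize_utterance(reference)$tokens
  hyp <- normalize_utterance(hypothesis)$tokens
  if (!length(ref)) {
    rt_empty_reference_error("reference normalizes to zero tokens")
  }
  sid <- .sid_counts(ref, hyp)
  res <- list(N = length(ref), S = unname(sid["S"]), I = unname(sid["I"]),
              D = unname(sid["D"]))
  res$wer <- (res$S + res$I + res$D) / res$N
  structure(res, class = "rt_wer")
}

#' @export
print.rt_wer <- function(x, ...) {
  cat(sprintf("WER = %.3f  (S=%d I=%d D=%d over N=%d reference words)\n",
              x$wer, x$S, x$I, x$D, x$N))
  invisible(x)
}

#' Average WER over a set of results
#'
#' @param results A list of `rt_wer` objects, or a numeric vector of WER
#'   values.
#' @return The arithmetic mean WER.
#' @examples
#' aggregate_wer(c(0.39, 0.27, 0.43, 0.34, 0.50, 0.37, 0.41, 0.45))
#' @export
aggregate_wer <- function(results) {
  if (is.list(results)) {
    results <- vapply(results, function(r) {
      if (inherits(r, "rt_wer")) r$wer else as.numeric(r)
    }, 0)
  }
  if (!length(results)) rt_empty_input_error("no WER values to aggregate")
  mean(as.numeric(results))
}

#' Score a table of transcript pairs
#'
#' @param pairs A data.frame with columns `reference` and `hypothesis`
#'   (e.g. from [read_transcript_pairs()] or
#'   [generate_transcript_pairs()]).
#' @return A data.frame with per-pair `N`, `S`, `I`, `D`, `wer`, plus the
#'   average as attribute `"average"`.
#' @export
wer_table <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("reference", "hypothesis") %in% names(pairs)))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    r <- word_error_rate(pairs$reference[i], pairs$hypothesis[i])
    data.frame(pair = i, N = r$N, S = r$S, I = r$I, D = r$D, wer = r$wer)
  })
  out <- do.call(rbind, rows)
  attr(out, "average") <- mean(out$wer)
  out
}

#' Read reference/hypothesis transcript pairs
#'
#' Accepts either a single 2-column TSV (`reference<TAB>hypothesis`, no
#' header) or two parallel plain-text files, one transcript per line.
#'
#' @param ref_path TSV path, or the reference file when `hyp_path` is given.
#' @param hyp_path Optional hypothesis file.
#' @return data.frame with columns `reference`, `hypothesis`.
#' @export
read_transcript_pairs <- function(ref_path, hyp_path = NULL) {
  if (is.null(hyp_path)) {
    tab <- utils::read.delim(ref_path, header = FALSE, sep = "\t",
                             quote = "", stringsAsFactors = FALSE,
                             encoding = "UTF-8")
    if (ncol(tab) < 2L) {
      rt_length_mismatch_error("TSV must have reference and hypothesis columns")
    }
    return(data.frame(reference = tab[[1]], hypothesis = tab[[2]],
                      stringsAsFactors = FALSE))
  }
  ref <- readLines(ref_path, warn = FALSE, encoding = "UTF-8")
  hyp <- readLines(hyp_path, warn = FALSE, encoding = "UTF-8")
  if (length(ref) != length(hyp)) {
    rt_length_mismatch_error(sprintf(
      "reference has %d lines but hypothesis has %d", length(ref),
      length(hyp)))
  }
  data.frame(reference = ref, hypothesis = hyp, stringsAsFactors = FALSE)
}

# round half-up at `digits` decimals (printed-table convention)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
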
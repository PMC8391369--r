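# Speech adapter contracts. The engine is text-mode by default; cloud ASR
# and TTS back ends plug in out-of-tree by supplying objects with the same
# shape. The engine itself never imports a cloud client.

#' Text-mode ASR adapter
#'
#' The identity adapter: the "transcription" of typed text is the text
#' itself. Mirrors the call shape a cloud speech-to-text adapter must
#' provide (`transcribe(audio) -> character`, plus a BCP-47 `language`).
#'
#' @param language BCP-47 language tag; Spanish by default.
#' @return A list of class `rt_asr` with a `transcribe` function and the
#'   `language` tag.
#' @examples
#' asr <- text_mode_asr()
#' asr$transcribe("hola")
#' @export
text_mode_asr <- function(language = "es") {
  structure(list(transcribe = function(x) x, language = language),
            class = "rt_asr")
}

#' Null TTS adapter
#'
#' Records what would be spoken instead of producing audio. The default
#' speaking rate is 0.8 relative to normal speed — deliberately slow, clear
#' speech for listeners with cognitive impairment.
#'
#' @param rate Relative speaking rate, must be positive; default `0.8`.
#' @return A list of class `rt_tts` with a `synthesize(text, rate)` function
#'   returning a synthesis record `list(text, rate)`, and the default
#'   `rate`.
#' @examples
#' tts <- null_tts()
#' tts$synthesize("hola")$rate
#' @export
null_tts <- function(rate = 0.8) {
  check_rate <- function(r) {
    if (!is.numeric(r) || length(r) != 1L || is.na(r) || r <= 0) {
      rt_range_error("TTS rate must be a positive number")
    }
    r
  }
  check_rate(rate)
  structure(list(
    synthesize = function(text, rate. = rate) {
      list(text = text, rate = check_rate(rate.))
    },
    rate = rate), class = "rt_tts")
}
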
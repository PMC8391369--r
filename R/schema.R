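#' Load and validate a profile questionnaire schema
#'
#' The schema defines the slots that personalize dialogue templates. It is a
#' JSON document with exactly three ordered topic blocks —
#' `personal_information`, `family_relationships` and
#' `life_history_lifestyle` — holding 11, 4 and 17 question definitions
#' respectively (32 in total). Each question carries a unique `slot_name`, a
#' Spanish `prompt_text`, a `value_kind` (`free_text`, `date` or `enum`) and
#' a `required` flag.
#'
#' @param path Path to a schema JSON document. Defaults to the questionnaire
#'   shipped with the package.
#' @return An object of class `rt_schema`: list with `schema_id`, `topics`
#'   (list of blocks, each with `topic_id` and a data.frame `questions`) and
#'   `slots` (character vector of all 32 slot names, in order).
#' @examples
#' sch <- load_schema()
#' length(sch$slots)
#' @export
load_schema <- function(path = system.file("extdata", "schema",
                                           "questionnaire_es.json",
                                           package = "recuerda")) {
  if (!file.exists(path)) {
    rt_schema_error(sprintf("schema document not found: %s", path))
  }
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
    error = function(e) rt_schema_error(paste("schema does not parse:",
                                              conditionMessage(e)))
  )
  topics <- doc$topics
  if (is.null(topics) || length(topics) != 3L) {
    rt_schema_error("schema must contain exactly 3 topic blocks")
  }
  expected <- c(personal_information = 11L,
                family_relationships = 4L,
                life_history_lifestyle = 17L)
  ids <- vapply(topics, function(t) t$topic_id %||% "", "")
  if (!identical(ids, names(expected))) {
    rt_schema_error(sprintf(
      "topic blocks must be %s in order; got %s",
      paste(names(expected), collapse = ", "), paste(ids, collapse = ", ")))
  }
  blocks <- lapply(topics, function(t) {
    qs <- t$questions
    if (is.null(qs) || !length(qs)) {
      rt_schema_error(sprintf("topic %s has no questions", t$topic_id))
    }
    qdf <- do.call(rbind, lapply(qs, function(q) {
      for (f in c("slot_name", "prompt_text", "value_kind")) {
        if (is.null(q[[f]]) || !nzchar(q[[f]])) {
          rt_schema_error(sprintf("question in %s missing field %s",
                                  t$topic_id, f))
        }
      }
      if (!q$value_kind %in% c("free_text", "date", "enum")) {
        rt_schema_error(sprintf("unknown value_kind %s for slot %s",
                                q$value_kind, q$slot_name))
      }
      data.frame(slot_name = q$slot_name, prompt_text = q$prompt_text,
                 value_kind = q$value_kind,
                 required = isTRUE(q$required),
                 context = q$context %||% NA_character_,
                 stringsAsFactors = FALSE)
    }))
    list(topic_id = t$topic_id, title = t$title %||% t$topic_id,
         questions = qdf)
  })
  counts <- vapply(blocks, function(b) nrow(b$questions), 0L)
  if (!identical(counts, unname(expected))) {
    rt_schema_error(sprintf(
      "question counts per block must be 11/4/17 (32 total); got %s",
      paste(counts, collapse = "/")))
  }
  slots <- unlist(lapply(blocks, function(b) b$questions$slot_name),
                  use.names = FALSE)
  if (anyDuplicated(slots)) {
    rt_schema_error(sprintf("duplicate slot name(s): %s",
                            paste(unique(slots[duplicated(slots)]),
                                  collapse = ", ")))
  }
  structure(list(schema_id = doc$schema_id %||% "schema",
                 language = doc$language %||% "es",
                 topics = blocks, slots = slots),
            class = "rt_schema")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rt_schema <- function(x, ...) {
  cat("<profile schema> ", x$schema_id, "\n", sep = "")
  for (b in x$topics) {
    cat(sprintf("  %-24s %2d questions\n", b$topic_id, nrow(b$questions)))
  }
  cat("  total:", length(x$slots), "slots\n")
  invisible(x)
}
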
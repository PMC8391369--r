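# The dialogue manager: turn-taking, context tracking, response selection,
# stall handling and session logging.

#' Start a therapy session
#'
#' Opens a session for a patient, sets the active context to
#' `beginning_conversation` and renders the opening greeting (personalized
#' with `patient_name` when the profile has one). The session object is an
#' environment: the dialogue manager mutates it in place across turns.
#'
#' @param kb An `rt_kb`.
#' @param profile An `rt_profile`.
#' @param seed Integer seed driving every response draw in the session;
#'   identical (profile, seed, scripted inputs) reproduce the transcript
#'   byte for byte (given the same `clock`).
#' @param store Optional `rt_profile_store`; when given, the session log is
#'   written under `<store>/sessions/` on close so that profile deletion can
#'   also remove it.
#' @param clock A zero-argument function returning a timestamp string;
#'   injectable for deterministic tests. Defaults to UTC wall time.
#' @param memory_k Non-repetition memory per context (recent responses a
#'   category may not reuse).
#' @param n_stall Consecutive fallbacks after which the manager proposes a
#'   new context drawn from profile-populated topics.
#' @return An `rt_session` environment; its `$last_response` holds the
#'   opening greeting.
#' @examples
#' kb <- load_kb()
#' prof <- generate_profile(seed = 7)
#' s <- start_session(kb, prof, seed = 1, clock = function() "t0")
#' s$last_response
#' @export
start_session <- function(kb, profile, seed = 0L, store = NULL,
                          clock = function() format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC"),
                          memory_k = 3L, n_stall = 2L) {
  stopifnot(inherits(kb, "rt_kb"), inherits(profile, "rt_profile"))
  if (!is.null(store)) {
    # session must belong to a stored patient
    get_profile(store, profile$patient_id)
  }
  s <- new.env(parent = emptyenv())
  s$session_id <- sprintf("s-%s-%d", profile$patient_id, as.integer(seed))
  s$patient_id <- profile$patient_id
  s$profile <- profile
  s$kb <- kb
  s$store <- store
  s$clock <- clock
  s$seed <- as.integer(seed)
  s$rng_counter <- 0L
  s$memory_k <- as.integer(memory_k)
  s$n_stall <- as.integer(n_stall)
  s$stall_count <- 0L
  s$active_context <- "beginning_conversation"
  s$contexts_visited <- "beginning_conversation"
  s$turn_index <- 0L
  s$recent <- list()
  s$predicates <- list()
  s$transcript <- list()
  s$closed <- FALSE
  class(s) <- "rt_session"

  opening <- render_entry(s, "beginning_conversation")
  if (is.null(opening)) opening <- default_fallback_text()
  push_turn(s, "system", opening, context_id = "beginning_conversation")
  s$last_response <- opening
  s
}

render_entry <- function(s, context_id) {
  ctx <- s$kb$contexts[[context_id]]
  if (is.null(ctx)) return(NULL)
  for (cat in ctx$categories) {
    if (isTRUE(cat$entry)) {
      out <- render_category(s$kb, cat, s$profile, session = s)
      if (!is.null(out)) return(out)
    }
  }
  NULL
}

render_context_fallback <- function(s, context_id) {
  ctx <- s$kb$contexts[[context_id]]
  if (!is.null(ctx)) {
    for (cat in ctx$categories) {
      if (isTRUE(cat$fallback)) {
        out <- render_category(s$kb, cat, s$profile, session = s)
        if (!is.null(out)) return(out)
      }
    }
  }
  default_fallback_text()
}

default_fallback_text <- function() {
  "Qué interesante. ¿Me cuentas un poco más?"
}

push_turn <- function(s, speaker, raw_text, normalized_text = NULL,
                      context_id = s$active_context) {
  s$transcript[[length(s$transcript) + 1L]] <- list(
    speaker = speaker, raw_text = raw_text,
    normalized_text = normalized_text,
    context_id = context_id, t = s$clock())
  invisible(s)
}

#' Advance the session by one user turn
#'
#' Runs the normalize-match-render pipeline: the utterance is normalized,
#' matched against the knowledge base (active context first, then
#' context-switch triggers, then global categories) and the winning
#' category is rendered with profile personalization. A trigger match
#' switches the active context; matching the farewell context renders the
#' farewell and closes the session. When nothing matches, or every template
#' of the match skips on missing slots, the active context's fallback
#' prompt is used; after `n_stall` consecutive fallbacks the manager itself
#' proposes a new profile-populated context.
#'
#' @param session An open `rt_session`.
#' @param user_text Raw user utterance.
#' @return The system response (non-empty character scalar).
#' @export
step_session <- function(session, user_text) {
  stopifnot(inherits(session, "rt_session"))
  if (session$closed) rt_session_closed_error("session is closed")
  u <- normalize_utterance(user_text)
  push_turn(session, "user", user_text, normalized_text = u$text)

  response <- NULL
  closing <- FALSE
  m <- kb_match(session$kb, u, session$active_context)
  if (!is.null(m)) {
    target <- m$context_id
    if (identical(m$tier, "trigger") &&
        identical(target, "beginning_conversation")) {
      # the opening context is never revisited after turn 0
      m <- NULL
    }
  }
  if (!is.null(m)) {
    if (length(m$bindings)) session$predicates$star <- m$bindings[[1]]
    response <- render_category(session$kb, m$category, session$profile,
                                session = session)
    if (!is.null(response)) {
      if (identical(m$tier, "trigger")) {
        session$active_context <- m$context_id
        session$contexts_visited <- union(session$contexts_visited,
                                          m$context_id)
      }
      session$stall_count <- 0L
      if (identical(m$context_id, "leave_conversation")) closing <- TRUE
    }
  }
  if (is.null(response)) {
    session$stall_count <- session$stall_count + 1L
    proposed <- NULL
    if (session$stall_count >= session$n_stall) {
      proposed <- propose_context(session)
    }
    if (!is.null(proposed)) {
      session$active_context <- proposed$context_id
      session$contexts_visited <- union(session$contexts_visited,
                                        proposed$context_id)
      session$stall_count <- 0L
      response <- proposed$text
    } else {
      response <- render_context_fallback(session, session$active_context)
    }
  }
  push_turn(session, "system", response)
  session$turn_index <- session$turn_index + 1L
  session$last_response <- response
  if (closing) close_session(session)
  response
}

# pick an unvisited context whose entry template renders for this profile
propose_context <- function(s) {
  candidates <- setdiff(names(s$kb$contexts),
                        c(s$contexts_visited,
                          "beginning_conversation", "leave_conversation"))
  for (cid in candidates) {
    txt <- render_entry(s, cid)
    if (!is.null(txt)) {
      return(list(context_id = cid, text = txt))
    }
  }
  NULL
}

close_session <- function(s) {
  s$closed <- TRUE
  if (!is.null(s$store)) {
    path <- file.path(s$store$dir, "sessions",
                      paste0(s$session_id, ".jsonl"))
    header <- jsonlite::toJSON(list(session_id = s$session_id,
                                    patient_id = s$patient_id),
                               auto_unbox = TRUE)
    writeLines(c(header, transcript_lines(s)), path, useBytes = TRUE)
  }
  invisible(s)
}

#' Close a session and summarize it
#'
#' @param session An open `rt_session`.
#' @return Summary list: `session_id`, `patient_id`, `turns` (completed
#'   user/system exchanges), `contexts_visited`, `responses_per_context`.
#' @export
end_session <- function(session) {
  stopifnot(inherits(session, "rt_session"))
  if (session$closed) rt_session_closed_error("session already closed")
  close_session(session)
  session_summary(session)
}

session_summary <- function(session) {
  sys_ctx <- vapply(Filter(function(t) t$speaker == "system",
                           session$transcript),
                    function(t) t$context_id, "")
  list(session_id = session$session_id,
       patient_id = session$patient_id,
       turns = session$turn_index,
       contexts_visited = session$contexts_visited,
       responses_per_context = table(sys_ctx))
}

transcript_lines <- function(session) {
  vapply(session$transcript, function(t) {
    obj <- list(speaker = t$speaker, raw_text = t$raw_text)
    if (!is.null(t$normalized_text)) obj$normalized_text <- t$normalized_text
    obj$context_id <- t$context_id
    obj$t <- t$t
    as.character(jsonlite::toJSON(obj, auto_unbox = TRUE))
  }, "")
}

#' Export a session transcript as JSONL
#'
#' One JSON object per line: `speaker`, `raw_text`, `normalized_text` (user
#' turns only), `context_id`, `t`. The document embeds the patient id
#' nowhere — transcripts stay shareable without the profile.
#'
#' @param session An `rt_session`.
#' @param path Optional file path; when `NULL` the lines are returned.
#' @return Character vector of JSONL lines (invisibly when written).
#' @export
export_transcript <- function(session, path = NULL) {
  lines <- transcript_lines(session)
  if (!is.null(path)) {
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(lines))
  }
  lines
}

#' Import a JSONL transcript
#'
#' @param x Path to a JSONL file, or a character vector of JSONL lines.
#' @return List of turns (named lists), the inverse of
#'   [export_transcript()].
#' @export
import_transcript <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) {
    readLines(x, warn = FALSE, encoding = "UTF-8")
  } else x
  lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
}

#' @export
print.rt_session <- function(x, ...) {
  cat("<session> ", x$session_id, if (x$closed) " (closed)" else " (open)",
      "\n  context: ", x$active_context,
      "; exchanges: ", x$turn_index, "\n", sep = "")
  invisible(x)
}
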
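# Pattern matching against the knowledge base.
#
# Wildcards "*" and "_" each consume one or more tokens. Priority follows
# graphmaster convention: at every input position an "_" edge beats an exact
# token, which beats a "*" edge, and stretching an already-open wildcard
# over a further token ranks below taking any edge, all resolved left to
# right. Matching a single category yields, per consumed input token, a
# choice code (0 = "_", 1 = exact, 2 = "*", 3 = wildcard continuation); the
# winning category is the one whose code sequence is lexicographically
# smallest, ties broken by authoring order.

# Best (lexicographically minimal) choice-code sequence for one pattern on
# one token vector, or NULL when the pattern does not match. Also returns
# wildcard bindings (list of consumed token spans in pattern order).
match_pattern <- function(pattern, tokens) {
  np <- length(pattern); nt <- length(tokens)
  memo <- new.env(parent = emptyenv())
  rec <- function(pi, ti) {
    key <- paste0(pi, ",", ti)
    if (!is.null(memo[[key]])) {
      res <- memo[[key]]
      return(if (identical(res, FALSE)) NULL else res)
    }
    res <- NULL
    if (pi > np) {
      if (ti > nt) res <- list(seq = integer(0), binds = list())
    } else if (ti <= nt) {
      p <- pattern[pi]
      if (p %in% c("_", "*")) {
        code <- if (p == "_") 0L else 2L
        # consume k >= 1 tokens: the first carries the edge code, each
        # further token a continuation code; the minimum over k is the
        # graphmaster (shortest-continuation-first) choice
        best <- NULL
        for (k in seq_len(nt - ti + 1L)) {
          tail_ <- rec(pi + 1L, ti + k)
          if (!is.null(tail_)) {
            cand <- list(
              seq = c(code, rep(3L, k - 1L), tail_$seq),
              binds = c(list(tokens[ti:(ti + k - 1L)]), tail_$binds))
            if (is.null(best) || seq_lt(cand$seq, best$seq)) best <- cand
          }
        }
        res <- best
      } else if (identical(p, tokens[ti])) {
        tail_ <- rec(pi + 1L, ti + 1L)
        if (!is.null(tail_)) {
          res <- list(seq = c(1L, tail_$seq), binds = tail_$binds)
        }
      }
    }
    memo[[key]] <- if (is.null(res)) FALSE else res
    res
  }
  rec(1L, 1L)
}

# lexicographic less-than on integer vectors
seq_lt <- function(a, b) {
  n <- min(length(a), length(b))
  if (n > 0L) {
    d <- a[seq_len(n)] != b[seq_len(n)]
    if (any(d)) {
      i <- which(d)[1]
      return(a[i] < b[i])
    }
  }
  length(a) < length(b)
}

# best matching category within a list, or NULL
best_category <- function(categories, tokens) {
  best <- NULL
  for (cat in categories) {
    if (isTRUE(cat$fallback)) next
    m <- match_pattern(cat$pattern, tokens)
    if (is.null(m)) next
    if (is.null(best) || seq_lt(m$seq, best$seq) ||
        (identical(m$seq, best$seq) && cat$order < best$category$order)) {
      best <- list(category = cat, seq = m$seq, binds = m$binds)
    }
  }
  best
}

#' Match a normalized utterance against the knowledge base
#'
#' Search proceeds in three tiers: (1) categories of the active context,
#' (2) context-switch trigger categories of every other context, (3) global
#' (topic-less) categories. Within a tier the winner is decided by wildcard
#' priority (`_` beats an exact token, which beats `*`, left to right), with
#' authoring order breaking exact ties. Fallback categories never match
#' directly; they are reserved for the dialogue manager.
#'
#' @param kb An `rt_kb`.
#' @param utterance An `rt_utterance` from [normalize_utterance()] (a plain
#'   string is normalized on the fly).
#' @param active_context Context id currently in focus, or `NA` for none.
#' @return `NULL` when nothing matches, else class `rt_match`: list with
#'   `context_id` (the matched category's context — for a trigger this is
#'   the context to switch into), `category`, `bindings` (wildcard token
#'   spans) and `tier` (`"active"`, `"trigger"` or `"global"`).
#' @examples
#' kb <- load_kb()
#' kb_match(kb, normalize_utterance("hola"), "beginning_conversation")
#' @export
kb_match <- function(kb, utterance, active_context = NA_character_) {
  stopifnot(inherits(kb, "rt_kb"))
  if (is.character(utterance)) utterance <- normalize_utterance(utterance)
  tokens <- utterance$tokens
  if (!length(tokens)) return(NULL)

  if (!is.na(active_context) && !is.null(kb$contexts[[active_context]])) {
    hit <- best_category(kb$contexts[[active_context]]$categories, tokens)
    if (!is.null(hit)) {
      return(new_match(hit, active_context, "active"))
    }
  }
  triggers <- list()
  for (ctx in kb$contexts) {
    if (identical(ctx$context_id, active_context)) next
    for (cat in ctx$categories) if (isTRUE(cat$trigger)) {
      triggers <- c(triggers, list(cat))
    }
  }
  hit <- best_category(triggers, tokens)
  if (!is.null(hit)) {
    return(new_match(hit, hit$category$context_id, "trigger"))
  }
  hit <- best_category(kb$globals, tokens)
  if (!is.null(hit)) {
    return(new_match(hit, active_context, "global"))
  }
  NULL
}

new_match <- function(hit, context_id, tier) {
  structure(list(context_id = context_id, category = hit$category,
                 bindings = hit$binds, seq = hit$seq, tier = tier),
            class = "rt_match")
}

#' @export
print.rt_match <- function(x, ...) {
  cat("<match> pattern [", paste(x$category$pattern, collapse = " "),
      "] in context ", x$context_id, " (", x$tier, ")\n", sep = "")
  invisible(x)
}
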
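# Template rendering with profile slot substitution, presence conditions,
# srai redirection, and seeded non-repetitive selection among a category's
# response variants.

# evaluate expr with a private RNG stream, leaving the caller's RNG state
# untouched
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# deterministic per-call seed derived from a base seed and a draw counter
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + counter * 16807) %% 2147483647)
}

#' Render a single response template against a profile
#'
#' Substitutes `<get>` slot references with profile values, resolves
#' `<condition>` presence switches, and follows `<srai>` redirection (when a
#' knowledge base is supplied) up to a recursion depth of 10. Returns `NULL`
#' ("skip") when a referenced slot is absent and no condition guards it —
#' customized templates are never rendered with placeholder residue.
#'
#' @param template An `rt_template`.
#' @param profile An `rt_profile`.
#' @param kb Optional `rt_kb`, required only for `<srai>`.
#' @param context_id Context used for `<srai>` re-matching.
#' @param depth Internal srai recursion depth.
#' @param session Optional `rt_session`, threaded through `<srai>` so
#'   redirected responses share the session's RNG stream and
#'   non-repetition memory.
#' @return Rendered text, or `NULL` when the template must be skipped.
#' @export
render_template <- function(template, profile, kb = NULL,
                            context_id = NA_character_, depth = 0L,
                            session = NULL) {
  stopifnot(inherits(template, "rt_template"))
  if (depth > 10L) return(NULL)
  out <- render_parts(template$parts, profile, kb, context_id, depth, session)
  if (is.null(out)) return(NULL)
  out <- trimws(squeeze_ws(out))
  if (!nzchar(out)) NULL else out
}

render_parts <- function(parts, profile, kb, context_id, depth,
                         session = NULL) {
  pieces <- character(length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    piece <- switch(
      p$type,
      text = p$text,
      get = {
        v <- get_slot(profile, p$slot)
        if (is.na(v)) return(NULL)
        v
      },
      condition = {
        v <- get_slot(profile, p$slot)
        branch <- if (!is.na(v)) p$present else p$absent
        if (is.null(branch)) return(NULL)
        sub <- render_parts(branch, profile, kb, context_id, depth, session)
        if (is.null(sub)) return(NULL)
        sub
      },
      srai = {
        if (is.null(kb) || depth >= 10L) return(NULL)
        m <- kb_match(kb, normalize_utterance(p$text), context_id)
        if (is.null(m)) return(NULL)
        sub <- render_category(kb, m$category, profile, session = session,
                               seed = derive_seed(depth + 1L, i),
                               depth = depth + 1L)
        if (is.null(sub)) return(NULL)
        sub
      })
    pieces[i] <- piece
  }
  paste(pieces, collapse = "")
}

#' Select and render a response from a category
#'
#' A category may define several response variants (its `<random>` list).
#' Selection is uniform over the variants that (a) render completely for
#' this profile (no missing slot) and (b) are not among the most recent
#' responses remembered for the category's context — so with more variants
#' than the memory size `k` (default 3), no response repeats within any
#' window of `k + 1` consecutive renders. The draw is seeded: identical
#' (profile, session history, seed) give identical output.
#'
#' @param kb An `rt_kb` (used for `<srai>`; may be `NULL`).
#' @param category An `rt_category`.
#' @param profile An `rt_profile`.
#' @param session Optional `rt_session`; supplies and records the
#'   per-context non-repetition memory and the RNG stream.
#' @param seed Seed for the selection draw when no session is given.
#' @param depth Internal srai recursion depth.
#' @return Rendered response text, or `NULL` when every variant skips.
#' @export
render_category <- function(kb, category, profile, session = NULL,
                            seed = 0L, depth = 0L) {
  stopifnot(inherits(category, "rt_category"))
  rendered <- lapply(category$templates, render_template, profile = profile,
                     kb = kb, context_id = category$context_id, depth = depth,
                     session = session)
  ok <- !vapply(rendered, is.null, TRUE)
  if (!any(ok)) return(NULL)
  texts <- unlist(rendered[ok])

  recent <- character(0)
  ctx <- category$context_id
  if (!is.null(session) && !is.na(ctx)) {
    recent <- session$recent[[ctx]] %||% character(0)
  }
  k <- if (!is.null(session)) session$memory_k else 3L
  # exclude at most n-1 recent responses so a choice always remains
  n_avail <- length(texts)
  block <- recent[seq_len(min(length(recent), min(k, n_avail - 1L)))]
  pool <- setdiff(texts, block)
  if (!length(pool)) pool <- texts

  if (!is.null(session)) {
    session$rng_counter <- session$rng_counter + 1L
    seed <- derive_seed(session$seed, session$rng_counter)
  }
  choice <- with_local_seed(seed, pool[sample.int(length(pool), 1L)])

  if (!is.null(session) && !is.na(ctx)) {
    session$recent[[ctx]] <- utils::head(c(choice, setdiff(recent, choice)),
                                         session$memory_k)
  }
  choice
}
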
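# Shared fixtures and independent oracles for the test suite.

# the shipped KB and schema are immutable; load them once
shipped_kb <- local({
  kb <- NULL
  function() {
    if (is.null(kb)) kb <<- load_kb()
    kb
  }
})

shipped_schema <- local({
  sch <- NULL
  function() {
    if (is.null(sch)) sch <<- load_schema()
    sch
  }
})

fixed_clock <- function() {
  i <- 0L
  function() {
    i <<- i + 1L
    sprintf("T%04d", i)
  }
}

# profile matching the published personalization example
patricia_profile <- function() {
  st <- profile_store(withr::local_tempdir(.local_envir = parent.frame()))
  create_profile(st, shipped_schema(),
                 answers = list(patient_name = "María"),
                 family = list(family_member(1, "Patricia", "hija")),
                 patient_id = "maria",
                 created_at = "2021-01-01T00:00:00Z")
}

# Brute-force recursive unit-cost edit distance (independent of the DP
# implementation under test).
bf_edit_distance <- function(a, b) {
  if (!length(a)) return(length(b))
  if (!length(b)) return(length(a))
  min(bf_edit_distance(a[-1], b[-1]) + (a[1] != b[1]),
      bf_edit_distance(a[-1], b) + 1L,
      bf_edit_distance(a, b[-1]) + 1L)
}

# all token sequences of length 0..maxlen over the given alphabet
all_sequences <- function(alphabet, maxlen) {
  out <- list(character(0))
  for (len in seq_len(maxlen)) {
    grid <- do.call(expand.grid,
                    c(rep(list(alphabet), len),
                      list(stringsAsFactors = FALSE)))
    out <- c(out, lapply(seq_len(nrow(grid)), function(i) {
      unlist(grid[i, ], use.names = FALSE)
    }))
  }
  out
}

# Independent graphmaster oracle: a real trie searched depth-first with
# edge order "_", exact token, "*" (wildcards consume one or more tokens,
# shortest continuation first). Returns the order id of the winning
# pattern, or NA.
trie_match_oracle <- function(patterns, tokens) {
  new_node <- function() new.env(parent = emptyenv())
  root <- new_node()
  for (i in seq_along(patterns)) {
    node <- root
    for (tok in patterns[[i]]) {
      kids <- if (is.null(node$kids)) list() else node$kids
      if (is.null(kids[[tok]])) {
        kids[[tok]] <- new_node()
        node$kids <- kids
      }
      node <- node$kids[[tok]]
    }
    if (is.null(node$terminal) || node$terminal > i) node$terminal <- i
  }
  n <- length(tokens)
  dfs <- function(node, i) {
    if (i > n) {
      return(if (is.null(node$terminal)) NA_integer_ else node$terminal)
    }
    kids <- if (is.null(node$kids)) list() else node$kids
    if (!is.null(kids[["_"]])) {
      for (j in i:n) {
        r <- dfs(kids[["_"]], j + 1L)
        if (!is.na(r)) return(r)
      }
    }
    if (!is.null(kids[[tokens[i]]])) {
      r <- dfs(kids[[tokens[i]]], i + 1L)
      if (!is.na(r)) return(r)
    }
    if (!is.null(kids[["*"]])) {
      for (j in i:n) {
        r <- dfs(kids[["*"]], j + 1L)
        if (!is.na(r)) return(r)
      }
    }
    NA_integer_
  }
  dfs(root, 1L)
}

# wrap raw pattern token vectors as categories for the internal matcher
as_categories <- function(patterns) {
  lapply(seq_along(patterns), function(i) {
    structure(list(context_id = "test", pattern = patterns[[i]],
                   templates = list(), kind = "generic", slots = NULL,
                   trigger = FALSE, entry = FALSE, fallback = FALSE,
                   order = i),
              class = "rt_category")
  })
}

# minimal in-memory session for render-level tests
fake_session <- function(seed = 42L, memory_k = 3L) {
  s <- new.env(parent = emptyenv())
  s$recent <- list()
  s$memory_k <- memory_k
  s$rng_counter <- 0L
  s$seed <- as.integer(seed)
  class(s) <- "rt_session"
  s
}

# tiny KB from inline XML
kb_from_xml <- function(xml, schema = shipped_schema()) {
  path <- withr::local_tempfile(fileext = ".xml",
                                .local_envir = parent.frame())
  writeLines(xml, path, useBytes = TRUE)
  load_kb(path, schema)
}

# S/I/D counts for pre-tokenized sequences, straight on the alignment core
# (bypasses utterance normalization, which would collapse repeated tokens)
.sid_counts_of <- function(ref, hyp) {
  recuerda:::.sid_counts(as.character(ref), as.character(hyp))
}

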
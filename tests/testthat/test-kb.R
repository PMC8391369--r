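test_that("shipped KB loads with the 20 canonical contexts", {
  kb <- shipped_kb()
  expect_length(kb$contexts, 20L)
  expect_setequal(names(kb$contexts), dialogue_context_catalog()$context_id)
  expect_true(all(vapply(kb$contexts,
                         function(ctx) length(ctx$categories) >= 1L, TRUE)))
  # generic vs customized classification follows slot references
  fam_entry <- Filter(function(cat) isTRUE(cat$entry),
                      kb$contexts$family$categories)[[1]]
  expect_identical(fam_entry$kind, "customized")
  glob <- kb$globals[[1]]
  expect_identical(glob$kind, "generic")
})

test_that("malformed XML and unknown slots are rejected", {
  expect_error(
    kb_from_xml('<aiml><bogus/></aiml>'),
    class = "rt_kb_syntax_error")
  expect_error(
    kb_from_xml(paste0(
      '<aiml><topic name="t"><category><pattern>hola</pattern>',
      '<template><get name="xyz"/>?</template></category></topic></aiml>')),
    class = "rt_kb_slot_error")
  expect_error(
    kb_from_xml(paste0(
      '<aiml><topic name="t"><category><pattern>hola</pattern>',
      '<template><shout>x</shout></template></category></topic></aiml>')),
    class = "rt_kb_syntax_error")
})

test_that("matching picks the most specific pattern and binds wildcards", {
  kb <- kb_from_xml(paste0(
    '<aiml><topic name="t">',
    '<category><pattern>me gusta *</pattern><template>¿Sí?</template></category>',
    '<category><pattern>*</pattern><template>¿Ah?</template></category>',
    '<category><pattern>hola</pattern><template>¿Qué tal?</template></category>',
    '</topic></aiml>'))
  m <- kb_match(kb, normalize_utterance("me gusta el fútbol"), "t")
  expect_identical(paste(m$category$pattern, collapse = " "), "me gusta *")
  expect_identical(m$bindings[[1]], c("el", "fútbol"))
  m2 <- kb_match(kb, normalize_utterance("hola"), "t")
  expect_identical(paste(m2$category$pattern, collapse = " "), "hola")
  expect_null(kb_match(kb, normalize_utterance(""), "t"))
})

test_that("match priority agrees with an independent graphmaster trie", {
  set.seed(2024)
  alphabet <- c("a", "b", "c")
  rand_pattern <- function() {
    n <- sample(1:4, 1)
    vapply(seq_len(n), function(i) {
      sample(c(alphabet, "*", "_"), 1, prob = c(2, 2, 2, 1, 1) / 8)
    }, "")
  }
  for (rep in 1:80) {
    patterns <- unique(lapply(1:6, function(i) rand_pattern()))
    cats <- as_categories(patterns)
    tokens <- sample(alphabet, sample(1:5, 1), replace = TRUE)
    got <- recuerda:::best_category(cats, tokens)
    want <- trie_match_oracle(patterns, tokens)
    if (is.na(want)) {
      expect_null(got)
    } else {
      expect_identical(got$category$order, want)
    }
  }
})

test_that("rendering substitutes family slots into the published example", {
  kb <- shipped_kb()
  p <- patricia_profile()
  entry <- Filter(function(cat) isTRUE(cat$entry),
                  kb$contexts$family$categories)[[1]]
  expected <- c("¿Es verdad que Patricia es tu hija?",
                "¿Te gustaría platicar de tu hija Patricia?")
  seen <- vapply(1:6, function(i) {
    render_category(kb, entry, p, seed = i)
  }, "")
  expect_true(all(seen %in% expected))
  expect_setequal(unique(seen), expected)
  # no placeholder residue; requested values appear verbatim
  expect_false(any(grepl("<|>|\\{", seen)))
  expect_true(all(grepl("Patricia", seen)))
})

test_that("templates with missing slots skip instead of leaking placeholders", {
  kb <- shipped_kb()
  st <- profile_store(withr::local_tempdir())
  no_family <- create_profile(st, shipped_schema(),
                              answers = list(patient_name = "María"))
  entry <- Filter(function(cat) isTRUE(cat$entry),
                  kb$contexts$family$categories)[[1]]
  expect_null(render_category(kb, entry, no_family, seed = 1))
})

test_that("seeded selection never repeats within the memory window", {
  lis <- paste0("<li>¿Opción ", 1:5, "?</li>")
  kb <- kb_from_xml(paste0(
    '<aiml><topic name="t"><category><pattern>x</pattern>',
    '<template><random>', paste(lis, collapse = ""), '</random></template>',
    '</category></topic></aiml>'))
  cat5 <- kb$contexts$t$categories[[1]]
  p <- patricia_profile()
  s <- fake_session(seed = 9, memory_k = 3L)
  outs <- vapply(1:24, function(i) render_category(kb, cat5, p, session = s),
                 "")
  # windows of memory_k + 1 consecutive renders hold no duplicate
  for (i in seq_len(length(outs) - 3L)) {
    expect_length(unique(outs[i:(i + 3L)]), 4L)
  }
  # same seed reproduces the same sequence
  s2 <- fake_session(seed = 9, memory_k = 3L)
  outs2 <- vapply(1:24, function(i) render_category(kb, cat5, p, session = s2),
                  "")
  expect_identical(outs, outs2)
})

test_that("lint flags non-questions, repetition risk and long sentences", {
  kb <- shipped_kb()
  expect_identical(nrow(lint_kb(kb)), 0L)

  bad <- kb_from_xml(paste0(
    '<aiml><topic name="hobbies"><category><pattern>x</pattern>',
    '<template>Qué bien.</template></category></topic></aiml>'))
  f <- lint_kb(bad)
  expect_true("non_question" %in% f$kind)
  expect_true("single_template" %in% f$kind)
  expect_true(all(dialogue_context_catalog()$context_id[-8] %in%
                    f$context_id[f$kind == "missing_context"]))

  long <- kb_from_xml(paste0(
    '<aiml><topic name="t"><category><pattern>x</pattern>',
    '<template><random><li>¿', paste(rep("palabra", 25), collapse = " "),
    '?</li><li>¿Corta?</li></random></template></category></topic></aiml>'))
  expect_true("long_sentence" %in% lint_kb(long)$kind)
})
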
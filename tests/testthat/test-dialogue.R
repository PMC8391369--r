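test_that("a session opens with a personalized greeting in the opening context", {
  kb <- shipped_kb()
  p <- patricia_profile()
  s <- start_session(kb, p, seed = 3, clock = fixed_clock())
  expect_identical(s$active_context, "beginning_conversation")
  expect_true(grepl("María", s$last_response))
  expect_identical(s$transcript[[1]]$speaker, "system")

  # absent patient_name falls back to the generic greeting branch
  st <- profile_store(withr::local_tempdir())
  anon <- create_profile(st, shipped_schema())
  s2 <- start_session(kb, anon, seed = 3, clock = fixed_clock())
  expect_false(grepl("<|\\{", s2$last_response))
  expect_true(nzchar(s2$last_response))

  # determinism: same profile and seed give the same opening
  s3 <- start_session(kb, p, seed = 3, clock = fixed_clock())
  expect_identical(s3$last_response, s$last_response)
})

test_that("stepping follows the normalize-match-render pipeline", {
  kb <- shipped_kb()
  p <- patricia_profile()
  s <- start_session(kb, p, seed = 5, clock = fixed_clock())
  step_session(s, "quiero hablar de la familia")
  expect_identical(s$active_context, "family")
  r <- step_session(s, "sí")
  expect_true(grepl("\\?$", r))
  expect_true(grepl("Patricia", r))

  # unmatchable gibberish yields the fallback, context unchanged
  r2 <- step_session(s, "xyzzy frobnicar")
  expect_true(nzchar(r2))
  expect_identical(s$active_context, "family")

  # farewell trigger closes the session
  r3 <- step_session(s, "adiós")
  expect_true(s$closed)
  expect_error(step_session(s, "hola"), class = "rt_session_closed_error")
})

test_that("two consecutive stalls make the manager propose a new topic", {
  kb <- shipped_kb()
  p <- patricia_profile()
  s <- start_session(kb, p, seed = 8, clock = fixed_clock())
  step_session(s, "gmorfl bzzt")
  before <- s$active_context
  expect_identical(before, "beginning_conversation")
  step_session(s, "gmorfl bzzt")
  expect_false(identical(s$active_context, before))
  expect_true(s$active_context %in% names(kb$contexts))
})

test_that("sessions reproduce byte-identical transcripts under a fixed seed", {
  kb <- shipped_kb()
  p <- patricia_profile()
  script <- c("hola", "estoy muy bien gracias", "sí",
              "quiero hablar de comida", "sí", "adiós")
  run <- function() {
    s <- start_session(kb, p, seed = 11, clock = fixed_clock())
    for (u in script) step_session(s, u)
    export_transcript(s)
  }
  expect_identical(run(), run())
})

test_that("system responses outside the farewell always invite continuation", {
  kb <- shipped_kb()
  p <- patricia_profile()
  s <- start_session(kb, p, seed = 2, clock = fixed_clock())
  for (u in c("hola", "sí", "quiero hablar de música", "sí",
              "no", "quiero hablar de fiestas", "sí claro")) {
    step_session(s, u)
  }
  for (t in s$transcript) {
    if (t$speaker == "system" && t$context_id != "leave_conversation") {
      expect_true(grepl("\\?$", t$raw_text), label = t$raw_text)
    }
    expect_true(t$speaker %in% c("user", "system"))
  }
  # turns alternate after the opening greeting
  speakers <- vapply(s$transcript, function(t) t$speaker, "")
  expect_true(all(speakers[-1][c(TRUE, FALSE)] == "user"))
  expect_true(all(speakers[-1][c(FALSE, TRUE)] == "system"))
})

test_that("ending a session reports turns and visited contexts once", {
  kb <- shipped_kb()
  p <- patricia_profile()
  s <- start_session(kb, p, seed = 4, clock = fixed_clock())
  for (u in c("hola", "sí", "quiero hablar de deportes", "sí")) {
    step_session(s, u)
  }
  summary <- end_session(s)
  expect_identical(summary$turns, 4L)
  expect_true("beginning_conversation" %in% summary$contexts_visited)
  expect_true("sports" %in% summary$contexts_visited)
  expect_error(end_session(s), class = "rt_session_closed_error")
})

test_that("transcripts round-trip through JSONL and stay profile-free", {
  kb <- shipped_kb()
  p <- patricia_profile()
  s <- start_session(kb, p, seed = 6, clock = fixed_clock())
  step_session(s, "quiero hablar de la familia")
  path <- withr::local_tempfile(fileext = ".jsonl")
  export_transcript(s, path)
  back <- import_transcript(path)
  expect_identical(length(back), length(s$transcript))
  expect_identical(back[[2]]$normalized_text,
                   s$transcript[[2]]$normalized_text)
  expect_identical(export_transcript(s), readLines(path, encoding = "UTF-8"))
  # opened-but-unstepped session exports exactly the opening line
  s0 <- start_session(kb, p, seed = 6, clock = fixed_clock())
  expect_length(export_transcript(s0), 1L)
  # the transcript never embeds the patient id or unspoken profile fields
  lines <- export_transcript(s)
  expect_false(any(grepl(p$patient_id, lines, fixed = TRUE)))
})

test_that("speech adapters honor the text-mode and slow-speech contracts", {
  asr <- text_mode_asr()
  expect_identical(asr$transcribe("hola"), "hola")
  expect_identical(asr$transcribe(""), "")
  expect_identical(normalize_utterance(asr$transcribe("¿Cómo estás?"))$tokens,
                   normalize_utterance("¿Cómo estás?")$tokens)
  tts <- null_tts()
  expect_identical(tts$synthesize("hola")$rate, 0.8)
  expect_identical(tts$synthesize("hola", 1.0)$rate, 1.0)
  expect_error(tts$synthesize("hola", 0), class = "rt_range_error")
  expect_error(null_tts(-1), class = "rt_range_error")
})
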
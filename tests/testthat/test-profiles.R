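test_that("shipped questionnaire has the 11/4/17 topic structure", {
  sch <- shipped_schema()
  counts <- vapply(sch$topics, function(b) nrow(b$questions), 0L)
  expect_identical(counts, c(11L, 4L, 17L))
  expect_length(sch$slots, 32L)
  expect_false(anyDuplicated(sch$slots) > 0)
  expect_true("patient_name" %in% sch$slots)
})

test_that("schema validation rejects wrong counts and duplicate slots", {
  doc <- jsonlite::fromJSON(system.file("extdata", "schema",
                                        "questionnaire_es.json",
                                        package = "recuerda"),
                            simplifyDataFrame = FALSE)
  # a 12th personal question breaks the 11/4/17 invariant
  bad <- doc
  bad$topics[[1]]$questions <- c(bad$topics[[1]]$questions,
                                 list(list(slot_name = "extra",
                                           prompt_text = "x",
                                           value_kind = "free_text")))
  p1 <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(bad, auto_unbox = TRUE), p1)
  expect_error(load_schema(p1), class = "rt_schema_error")

  # duplicate slot name across blocks
  dup <- doc
  dup$topics[[3]]$questions[[1]]$slot_name <- "patient_name"
  p2 <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(dup, auto_unbox = TRUE), p2)
  expect_error(load_schema(p2), class = "rt_schema_error")
})

test_that("profiles persist, expose derived family slots, and round-trip", {
  st <- profile_store(withr::local_tempdir())
  p <- create_profile(st, shipped_schema(),
                      answers = list(patient_name = "María"),
                      family = list(family_member(1, "Patricia", "hija")))
  expect_identical(get_slot(p, "patient_name"), "María")
  expect_identical(get_slot(p, "fam1_name"), "Patricia")
  expect_identical(get_slot(p, "parentesco_fam1"), "hija")
  # unknown / out-of-range slots are absent, never an error
  expect_identical(get_slot(p, "fam9_name"), NA_character_)
  expect_identical(get_slot(p, "no_such_slot"), NA_character_)

  reloaded <- get_profile(st, p$patient_id)
  expect_identical(reloaded$answers, p$answers)
  expect_equal(reloaded$family, p$family)

  # empty profile is valid, all slots absent
  p0 <- create_profile(st, shipped_schema())
  expect_identical(get_slot(p0, "patient_name"), NA_character_)

  # keys outside the schema are rejected; empty strings are dropped
  expect_error(create_profile(st, shipped_schema(),
                              answers = list(not_a_slot = "x")),
               class = "rt_unknown_slot_error")
  p2 <- create_profile(st, shipped_schema(),
                       answers = list(apodo = "  "))
  expect_identical(get_slot(p2, "apodo"), NA_character_)
})

test_that("deleting a profile removes every trace, leaving others intact", {
  st <- profile_store(withr::local_tempdir())
  a <- create_profile(st, shipped_schema(),
                      answers = list(patient_name = "Rosa"))
  b <- create_profile(st, shipped_schema(),
                      answers = list(patient_name = "José"))
  # a session log referencing patient a
  s <- start_session(shipped_kb(), a, seed = 1, store = st,
                     clock = fixed_clock())
  step_session(s, "adiós")
  expect_true(s$closed)

  rep <- delete_profile(st, a$patient_id)
  expect_true(length(rep$removed) >= 2)  # profile + session log
  # full-store scan finds zero occurrences of the id
  files <- list.files(st$dir, recursive = TRUE, full.names = TRUE)
  hits <- vapply(files, function(f) {
    any(grepl(a$patient_id, readLines(f, warn = FALSE), fixed = TRUE))
  }, TRUE)
  expect_false(any(hits))
  # double delete errors; the other profile is intact
  expect_error(delete_profile(st, a$patient_id), class = "rt_not_found_error")
  expect_error(get_profile(st, a$patient_id), class = "rt_not_found_error")
  expect_identical(get_profile(st, b$patient_id)$answers$patient_name,
                   "José")
})
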
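test_that("synthetic profiles are deterministic, distinct and schema-valid", {
  a <- generate_profile(1)
  b <- generate_profile(1)
  expect_identical(a$answers, b$answers)
  expect_equal(a$family, b$family)
  c_ <- generate_profile(2)
  expect_false(identical(a$answers, c_$answers))
  # all 32 slots populated, at least one family member
  expect_length(a$answers, 32L)
  expect_gte(length(a$family), 1L)
  st <- profile_store(withr::local_tempdir())
  stored <- create_profile(st, shipped_schema(), answers = a$answers,
                           family = a$family)
  expect_identical(stored$answers, a$answers)
})

test_that("the simulated user sustains the requested turns per context", {
  kb <- shipped_kb()
  p <- generate_profile(3)
  for (cid in c("family", "sports", "agent_profile",
                "beginning_conversation", "leave_conversation")) {
    u1 <- simulated_user(kb, cid, p, seed = 1)
    u2 <- simulated_user(kb, cid, p, seed = 1)
    expect_identical(u1, u2)
    expect_gte(1L + 2L * length(u1), 6L)
  }
  # customized contexts echo the profile's topical slot value
  utts <- simulated_user(kb, "food_dishes", p, seed = 1)
  expect_true(any(grepl(get_slot(p, "comida_favorita"), utts, fixed = TRUE)))
  expect_error(simulated_user(kb, "no_such_context", p),
               class = "rt_not_found_error")
})

test_that("the default design point yields 40 four-candidate dialogues", {
  kb <- shipped_kb()
  p <- generate_profile(1)
  set <- generate_evaluation_set(kb, p, fixture_config(seed = 1))
  expect_length(set, 40L)
  expect_identical(
    unname(table(vapply(set, function(d) d$context_id, ""))[1]), 2L)
  for (d in set) {
    expect_length(d$candidates, 4L)
    expect_gte(length(d$turns), 4L)
    # true response never equals a distractor
    expect_false(d$candidates[1] %in% d$candidates[2:4])
    expect_length(unique(d$candidates), 4L)
    speakers <- vapply(d$turns, function(t) t$speaker, "")
    expect_true(all(speakers[-1] != speakers[-length(speakers)]))
  }
  # determinism and scalable design
  set2 <- generate_evaluation_set(kb, p, fixture_config(seed = 1))
  expect_identical(set, set2)
  small <- generate_evaluation_set(
    kb, p, fixture_config(seed = 1, n_dialogues_per_context = 1L))
  expect_length(small, 20L)
})

test_that("evaluation sets and votes round-trip through JSON and CSV", {
  kb <- shipped_kb()
  p <- generate_profile(4)
  set <- generate_evaluation_set(
    kb, p, fixture_config(seed = 4, n_dialogues_per_context = 1L))
  json <- withr::local_tempfile(fileext = ".json")
  write_evaluation_set(set, json)
  expect_identical(read_evaluation_set(json), set)

  votes <- generate_synthetic_votes(set, n_evaluators = 11, seed = 4)
  expect_identical(nrow(votes), 20L * 11L)
  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(votes, csv, row.names = FALSE)
  expect_identical(read_votes_csv(csv), votes)

  scaffold <- withr::local_tempfile(fileext = ".csv")
  write_votes_scaffold(set, scaffold)
  expect_identical(nrow(read_votes_csv(scaffold)), 0L)
})

test_that("corruption rates drive measured word errors monotonically", {
  zero <- generate_transcript_pairs(5, 6, list(sub = 0, ins = 0, del = 0))
  expect_true(all(wer_table(zero)$wer == 0))

  gone <- generate_transcript_pairs(5, 6, list(sub = 0, ins = 0, del = 1))
  expect_true(all(wer_table(gone)$wer == 1))

  rates <- c(0.05, 0.2, 0.5)
  means <- vapply(rates, function(r) {
    attr(wer_table(generate_transcript_pairs(
      11, 30, list(sub = r, ins = 0, del = 0))), "average")
  }, 0)
  expect_true(all(diff(means) > 0))

  expect_error(generate_transcript_pairs(1, 2, list(sub = 2, ins = 0,
                                                    del = 0)),
               class = "rt_range_error")
  expect_identical(generate_transcript_pairs(9, 4),
                   generate_transcript_pairs(9, 4))
})
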
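---
title: "A personalized reminiscence-therapy dialogue engine: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A personalized reminiscence-therapy dialogue engine: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recuerda)
```

## The problem

Reminiscence therapy (RT) is a non-pharmacological intervention for people
with Alzheimer's disease (PwAD): guided conversation that evokes
autobiographical memories, which in the early stage of the disease remain
far better preserved than recent memory. Delivering RT regularly is
labor-intensive for caregivers. `recuerda` implements a text-mode
conversational engine that conducts RT-style dialogue in Spanish,
personalized from a structured patient profile, plus the quantitative
machinery needed to evaluate such a system without live patients.

## The dialogue model

The engine is a pattern-matching dialogue system in the AIML tradition,
deliberately so: rule-based dialogue is auditable, deterministic under a
seed, and safe for a vulnerable user population (the system can only ever
say what a clinician-reviewed knowledge base contains — no generative
model, no surprises).

**Knowledge base.** Twenty topic-scoped *dialogue contexts* (greetings,
farewell, agent profile, patient profile, family, habits, skills, hobbies,
household chores, visited places, movies, TV shows, actors, music, singers,
sports, sport teams, food, beverages, festivities) hold pattern→template
rules. Templates are *generic* (profile-independent) or *customized*
(parameterized by profile slots). A category may be a context-switch
*trigger*, the context's *entry* prompt, or its *fallback*.

**Normalization.** User text is NFC-normalized, stripped of everything that
is not a Unicode letter or digit (Spanish diacritics are letters and are
preserved), lowercased, tokenized on whitespace, and runs of identical
consecutive tokens are collapsed to one — the typical false-start artifact
of spontaneous-speech recognition ("este este", "um um"). The collapse
applies to single tokens only; multi-token repeats ("no sé no sé") carry
meaning and are kept. Patterns pass through the same pipeline, so rules and
input live in one alphabet. The order of operations (strip, lowercase,
tokenize, collapse) is fixed; collapsing after punctuation stripping means
"sí, sí" also collapses, which we consider the intended reading of the
false-start rule.

**Matching.** Wildcards `_` and `*` each match one or more tokens. Priority
follows the classic graphmaster convention — at each input position an `_`
edge beats an exact token, which beats `*`, and stretching an open wildcard
over a further token ranks below taking any edge — resolved left to right,
ties broken by authoring order. This de-facto standard is adopted because it
keeps independently authored AIML-style knowledge bases portable. The test
suite checks the matcher against an independent trie-search oracle on random
pattern sets.

**Search order.** The active context is searched first, then the trigger
categories of other contexts (a match switches context), then global
categories. Because every topical context also defines a fallback, a
context's own rules always win over a topic switch — the conversation is
sticky by design, as RT favors staying with an evoked memory.

**Rendering.** `<get>` references substitute profile slots; `<condition>`
branches on slot presence; `<srai>` redirects (depth-capped at 10). A
template referencing an unanswered slot is *skipped* — never rendered with
placeholder residue. If every variant of a matched category skips, the
dialogue manager falls back: customized template → generic template in the
same category → the context's authored fallback prompt. Among eligible
variants, selection is uniform and seeded, excluding the `k = 3` most
recent responses in that context, so with more than `k` variants no
response repeats within any window of `k + 1` turns. `k = 3` is our choice:
the smallest memory that makes 4-variant categories visibly non-repetitive
without starving 2-variant ones.

**Dialogue management.** A session opens in `beginning_conversation` (and
never returns there — a re-greeting mid-session would be disorienting).
After `n_stall = 2` consecutive fallbacks, the manager proposes a new
context whose entry template renders for this profile, i.e. a topic the
profile actually populates; candidates are tried in the canonical context
order, deterministically. Matching the farewell context renders the goodbye
and closes the session. Timestamps come from an injectable clock, so
identical (profile, seed, script) reproduce byte-identical transcripts.

**Communication strategy.** The shipped knowledge base follows
dementia-communication recommendations: short simple sentences, positive
reinforcement, personalization, and every response outside the farewell
context ends with a question that invites the patient to continue.
`lint_kb()` enforces all three rules mechanically (non-question templates,
single-template contexts, sentences over a 20-word ceiling — the ceiling is
configurable; 20 is generous for Spanish and flags only genuinely long
sentences).

## The patient profile

Personalization draws on a 32-question caregiver questionnaire in three
blocks: 11 personal-information, 4 family-relationship and 17
life-history/lifestyle questions. The published design fixes these counts
and a handful of slot names (`patient_name`, `fam1_name`,
`parentesco_fam1`); the remaining slot names and question texts are our
reconstruction, each life-history slot mapped to the dialogue context it
personalizes (e.g. `comida_favorita` → food). Family members are stored as
an ordered list; position *i* exposes derived slots `fam<i>_name` and
`parentesco_fam<i>`.

Storage is one JSON document per profile in a directory store. A database
server would add nothing at desk scale, and the flat layout makes the
withdrawal contract auditable: `delete_profile()` removes the profile
document and every session log referencing the patient id, and the tests
verify by full-store scan that no trace remains. Missing answers are stored
as *absent* (never empty strings); customized templates needing a missing
slot are skipped at render time.

## Speech adapters

The engine is text-mode. Cloud speech recognition and synthesis are
representable as injected adapters mirroring the call shape of commercial
services (`transcribe(audio) -> text`, `synthesize(text, rate)`); the
default ASR adapter is the identity on strings and the default TTS adapter
records text at a speaking rate of 0.8 relative to normal speed — the slow,
clear delivery recommended for listeners with cognitive impairment. The
engine itself never imports a network client.

## Evaluation machinery

**Word error rate.** For a reference of `N` tokens,
`WER = (S + I + D) / N` from a unit-cost Levenshtein alignment
(substitutions, insertions, deletions). Both transcripts pass through the
engine's own normalizer, making the metric case- and
punctuation-insensitive — standard ASR-scoring practice. The alignment core
is compiled (Rcpp); `S + I + D` always equals the edit distance, and the
backtrace canonicalizes ties by preferring substitution over deletion over
insertion, so the reported split is deterministic even where the optimal
alignment is not unique. Tests verify the total against base R's
`utils::adist` on the exhaustive grid of token sequences up to length 6
over a 3-symbol alphabet, and against a brute-force recursive oracle
exhaustively at shorter lengths plus a random sample of the full grid —
the recursion is exponential, so running it on all 1.2 million grid pairs
would be wasteful when a second independent oracle covers them.

**Voted Appropriateness.** In the static-context (bystander) scheme,
evaluators read fixed dialogues of at least 4 turns and vote for the most
appropriate of 4 candidate responses, one of which (position 0, hidden) is
the engine's actual response. `Rvoted` is a candidate's vote count, `Rmax`
the per-dialogue maximum. Agreement percentages are *tie-inclusive*: a
position counts as agreeing whenever its count equals `Rmax`, so the
percentages can sum above 100 — the convention under which the published
per-position figures (62.5 + 42.5 + 2.5 + 0) exceed 100. Pearson's *r*
between system votes and `Rmax` uses the exact *t* transform with `n − 2`
degrees of freedom (via `stats::cor.test`); at `n = 40`-scale inputs a
permutation test would add nothing. Star ratings (1–5) are summarized by
their mean, reported half-up at 2 decimals as such scores are conventionally
printed; WER tables print half-up at 3 decimals.

## Synthetic fixtures: what they emulate and what they do not

All inputs are generated in code, seeded, with no downloads.

* `generate_profile()` fills all 32 slots with plausible Mexican-Spanish
  values and 1–3 family members. Values are chosen so templates read
  naturally (nouns carry their article: "el mole poblano").
* `simulated_user()` is rule-based: it steers into a context with a
  keyword phrase, affirms, echoes the profile's topical slot value, and
  keeps answering. Determinism and zero dependencies are the point; it
  emulates a cooperative patient, not disfluent, tangential or silent
  speech.
* `generate_evaluation_set()` reproduces the published evaluation design
  point: 2 dialogues × 20 contexts = 40 dialogues, ≥ 4 alternating turns,
  4 candidates. Distractors are rendered (fully slot-substituted) entry
  templates of *other* contexts — fluent but contextually wrong, which is
  what makes the bystander task meaningful; how the original distractors
  were authored is not documented, so this rule is our stand-in.
* `generate_transcript_pairs()` corrupts sampled Spanish sentences with
  independent per-token substitutions, insertions and deletions at
  configured rates, avoiding corruptions that would create consecutive
  duplicate tokens (the normalizer would collapse them and shift the
  measured rates). It is a parametric stand-in for recognizer output: it
  reproduces error *rates*, not the acoustic or phonetic structure of real
  recognizer confusions on elderly speech.

Consequently, passing tests show the machinery is correct and the design
point is reproduced; they do not show how real patients converse, nor real
recognizer error patterns.

## Numerical and degenerate-input choices

* WER with an empty-normalizing reference is an error (`N = 0` divides);
  an empty hypothesis is fine (all deletions, WER 1).
* WER may exceed 1 when insertions outnumber reference tokens.
* An evaluator voting twice on a dialogue, or a vote outside candidates
  0–3, is a data error; an empty vote table is valid (all counts 0) and
  correlation on it reports NA rather than failing.
* Pearson correlation requires n ≥ 3 and non-constant vectors.
* Random draws everywhere use a derived-seed scheme (multiplicative hash
  of the base seed and a call counter, kept below 2^31) against a private
  RNG state, so package code never disturbs the caller's `.Random.seed`.
* Profile ids are sequential (`p000001`, ...) unless supplied; fixture
  profiles use `sim<seed>`.

## Problem sizes

The shipped test suite exercises the full 40-dialogue design point, the
complete exhaustive alignment grid (lengths ≤ 6, 3 symbols; ~1.2 million
ordered pairs through the compiled core), 200-pair corruption-recovery
runs, and 80-case randomized matcher/oracle comparisons; the whole suite
runs in well under a minute on a single CPU.

## Known limitations

* The engine implements context/topic scoping but not response-conditioned
  matching (AIML `<that>`); a category cannot condition on what the system
  just said. Context stickiness compensates in practice.
* The shipped knowledge base is Spanish; the engine is language-agnostic
  but the normalizer's case-folding table targets the Spanish alphabet.
* Per-vote reproduction of the published panel results is out of reach by
  construction — the human votes live in an external repository — so
  vote-level claims are covered by property checks (tie-inclusive
  arithmetic, correlation bounds) rather than value reproduction.
* The simulated user cannot measure therapeutic benefit; it measures only
  that the engine holds coherent, personalized, non-repetitive dialogue.
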
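# recuerda

A text-mode conversational engine for delivering **reminiscence therapy**
(RT) to people with early-stage Alzheimer's disease, together with the
quantitative machinery to evaluate it. RT evokes autobiographical memories
through guided conversation; `recuerda` personalizes that conversation from
a 32-question patient profile (11 personal-information, 4
family-relationship, 17 life-history questions) and drives it with an
AIML-subset knowledge base of 20 Spanish dialogue contexts — greetings,
family, habits, hobbies, food, music, festivities and so on — authored to
dementia-communication guidelines: short sentences, positive reinforcement,
and every response ending in a question that invites the patient to
continue.

Who it is for: researchers and developers of assistive conversational
systems who need a deterministic, auditable RT dialogue engine and a
reproducible evaluation pipeline that runs entirely on synthetic and
in-paper data — no cloud services, no patient recordings.

## What is inside

* **Dialogue engine** — graphmaster pattern matching (`_` > exact > `*`,
  left to right), topic-scoped contexts with pattern-triggered switching,
  profile slot substitution (`fam1_name`, `parentesco_fam1`, ...), seeded
  non-repetitive response selection, stall handling, JSONL transcripts.
* **Profile store** — schema-validated 32-slot profiles, one JSON document
  each, with a complete-deletion contract for patient withdrawal.
* **Evaluation** — word error rate
  `WER = (S + I + D) / N`
  from a unit-cost Levenshtein alignment with a canonical
  substitution/insertion/deletion decomposition (compiled core); Voted
  Appropriateness `Rvoted = V(u_t, context_t)` with per-dialogue `Rmax`,
  tie-inclusive agreement percentages, Pearson correlation (exact *t*
  p-values), and star-rating summaries.
* **Fixtures** — seeded generators for profiles, simulated users,
  static-context evaluation sets (2 dialogues × 20 contexts = 40
  dialogues, ≥ 4 turns, 4 candidate responses each) and
  error-rate-controlled transcript pairs.
* **CLI** — `inst/cli/recuerda` with subcommands `chat`, `eval-wer`,
  `eval-votes`, `gen-fixtures`, `validate-kb`.

## Worked example

```r
library(recuerda)

kb      <- load_kb()                      # shipped 20-context Spanish KB
store   <- profile_store(tempfile("store"))
profile <- create_profile(store, load_schema(),
  answers = list(patient_name = "María", comida_favorita = "el mole poblano"),
  family  = list(family_member(1, "Patricia", "hija")))

s <- start_session(kb, profile, seed = 1)
s$last_response
for (u in c("quiero hablar de la familia", "sí",
            "quiero hablar de comida", "sí", "adiós")) {
  cat("USER:  ", u, "\nSYSTEM:", step_session(s, u), "\n")
}
```

```
SYSTEM: ¡Hola María! Qué gusto saludarte. ¿Cómo estás hoy?
USER:   quiero hablar de la familia
SYSTEM: ¿Es verdad que Patricia es tu hija?
USER:   sí
SYSTEM: ¡Muy bien! ¿Tienes un recuerdo bonito con Patricia?
USER:   quiero hablar de comida
SYSTEM: ¿Cuál es tu platillo favorito?
USER:   sí
SYSTEM: ¡Qué rico! ¿Quién preparaba el mole poblano en tu casa?
USER:   adiós
SYSTEM: Adiós. Cuídate mucho y que tengas un bonito día.
```

The greeting and the family question are *customized* templates filled
from the profile (the `fam1_name`/`parentesco_fam1` example above renders
exactly the published personalization); mentioning a topic keyword
switches context; the farewell closes the session.

Evaluation primitives:

```r
word_error_rate("hola buenos días señora", "hola buenas días")
#> WER = 0.500  (S=1 I=0 D=1 over N=4 reference words)

aggregate_wer(c(0.39, 0.27, 0.43, 0.34, 0.50, 0.37, 0.41, 0.45))
#> [1] 0.395

star_rating_summary(c(rep(4, 7), rep(5, 3), 3))
#> star rating: mean 4.18 over 11 ratings
```

`word_error_rate` normalizes both transcripts with the engine's own
pipeline (punctuation stripped, lowercased, false-start repeats collapsed),
then aligns: here "buenos"→"buenas" is a substitution and "señora" a
deletion over a 4-word reference, so WER = 2/4. The second call averages a
per-file WER column; the third summarizes an 11-member rating panel.

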
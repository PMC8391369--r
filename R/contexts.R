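#' Catalog of the twenty dialogue contexts
#'
#' The reminiscence knowledge base is organized into 20 topic-scoped
#' dialogue contexts spanning the three questionnaire areas (personal
#' information, family relationships, life history and lifestyle). The
#' catalog also records, per context: the single-token Spanish keyword its
#' context-switch triggers listen for, the phrase the simulated user says
#' to steer the conversation there, and the profile slot that personalizes
#' its templates (`NA` for purely generic contexts).
#'
#' @return data.frame with columns `context_id`, `description`, `keyword`,
#'   `trigger_phrase`, `slot`.
#' @export
dialogue_context_catalog <- function() {
  tab <- rbind(
    c("beginning_conversation", "opening greetings for the patient",
      "hola", "hola", NA),
    c("leave_conversation", "farewell phrases closing the session",
      "adiós", "adiós", NA),
    c("agent_profile", "who and what the conversational agent is",
      "quién", "dime quién eres", NA),
    c("pwad_profile", "the patient's own personal information",
      "vida", "quiero hablar de mi vida", "apodo"),
    c("family", "family members that matter to the patient",
      "familia", "quiero hablar de la familia", "fam1_name"),
    c("habits", "daily habits the patient used to keep",
      "costumbres", "quiero hablar de mis costumbres", "habito_diario"),
    c("skills", "things the patient was especially good at",
      "habilidades", "quiero hablar de mis habilidades", "habilidad"),
    c("hobbies", "the patient's preferred pastimes",
      "pasatiempos", "quiero hablar de mis pasatiempos", "hobby"),
    c("household_chores", "home activities the patient enjoyed helping with",
      "hogar", "quiero hablar del hogar", "labor_hogar"),
    c("visited_places", "places that were meaningful in the patient's life",
      "lugares", "quiero hablar de lugares", "lugar_visitado"),
    c("movies", "the patient's favorite films",
      "películas", "quiero hablar de películas", "pelicula_favorita"),
    c("tv_shows", "favorite television programs",
      "televisión", "quiero hablar de la televisión", "programa_tv"),
    c("actors", "actors and characters the patient likes",
      "actores", "quiero hablar de actores", "actor_favorito"),
    c("music", "music the patient prefers",
      "música", "quiero hablar de música", "musica_favorita"),
    c("singers", "singers and bands the patient prefers",
      "cantantes", "quiero hablar de cantantes", "cantante_favorito"),
    c("sports", "sports the patient enjoys",
      "deportes", "quiero hablar de deportes", "deporte_favorito"),
    c("sport_teams", "teams and athletes the patient follows",
      "equipos", "quiero hablar de equipos", "equipo_favorito"),
    c("food_dishes", "the patient's favorite dishes",
      "comida", "quiero hablar de comida", "comida_favorita"),
    c("beverages", "the patient's favorite drinks",
      "bebidas", "quiero hablar de bebidas", "bebida_favorita"),
    c("festivities", "festivities the patient enjoys",
      "fiestas", "quiero hablar de fiestas", "festividad_favorita"))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("context_id", "description", "keyword", "trigger_phrase",
                  "slot")
  out
}

#' Lint a knowledge base for therapy-communication rules
#'
#' Checks the authored templates against the communication strategy the
#' engine enforces for dementia-friendly dialogue:
#'
#' * `non_question` — outside `leave_conversation`, every response must end
#'   with a question so the patient is always invited to continue.
#' * `single_template` — a context offering fewer than two response
#'   variants will repeat itself; flagged as repetition risk.
#' * `long_sentence` — sentences longer than `max_words` words violate the
#'   short-and-simple rule.
#' * `missing_context` — a canonical dialogue context absent from the KB.
#'
#' @param kb An `rt_kb`.
#' @param max_words Sentence-length ceiling in words (default 20).
#' @return data.frame of findings with columns `kind`, `context_id`,
#'   `detail`; zero rows when the KB is clean.
#' @export
lint_kb <- function(kb, max_words = 20L) {
  stopifnot(inherits(kb, "rt_kb"))
  findings <- list()
  add <- function(kind, ctx, detail) {
    findings[[length(findings) + 1L]] <<- data.frame(
      kind = kind, context_id = ctx, detail = detail,
      stringsAsFactors = FALSE)
  }
  dummy <- lint_dummy_profile()
  for (cat in kb$categories) {
    ctx <- cat$context_id
    for (tpl in cat$templates) {
      txt <- render_template(tpl, dummy, kb = kb, context_id = ctx)
      if (is.null(txt)) next
      if (!identical(ctx, "leave_conversation") &&
          !grepl("\\?$", txt)) {
        add("non_question", if (is.na(ctx)) "(global)" else ctx, txt)
      }
      sentences <- strsplit(txt, "[.?!]")[[1]]
      for (sent in sentences) {
        nw <- length(tokenize(sent))
        if (nw > max_words) {
          add("long_sentence", if (is.na(ctx)) "(global)" else ctx,
              sprintf("%d words: %s", nw, trimws(sent)))
        }
      }
    }
  }
  for (ctx in kb$contexts) {
    n_templates <- sum(vapply(ctx$categories, function(cat) {
      if (isTRUE(cat$fallback)) 0L else length(cat$templates)
    }, 0L))
    if (n_templates < 2L) {
      add("single_template", ctx$context_id,
          sprintf("%d response template(s)", n_templates))
    }
  }
  for (cid in setdiff(dialogue_context_catalog()$context_id,
                      names(kb$contexts))) {
    add("missing_context", cid, "canonical dialogue context absent")
  }
  if (!length(findings)) {
    return(data.frame(kind = character(0), context_id = character(0),
                      detail = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, findings)
}

# fully-populated stand-in profile so every customized template renders
# during linting
lint_dummy_profile <- function() {
  schema <- load_schema()
  answers <- stats::setNames(as.list(rep("tal", length(schema$slots))),
                             schema$slots)
  structure(list(patient_id = "lint", answers = answers,
                 family = list(family_member(1, "Fulana", "hija"),
                               family_member(2, "Mengano", "nieto")),
                 created_at = "1970-01-01T00:00:00Z",
                 schema_id = schema$schema_id),
            class = "rt_profile")
}
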
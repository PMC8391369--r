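# Seeded synthetic fixtures: patient profiles, simulated users, evaluation
# dialogue sets, and corrupted transcript pairs. Everything is generated in
# code — no downloads, no stored corpora — and every generator is a pure
# function of its seed.

#' Fixture configuration
#'
#' Defaults reproduce the evaluation design the engine is built for: two
#' dialogues per dialogue context over the 20-context knowledge base (40
#' dialogues), each of at least 4 alternating turns, with 4 candidate
#' responses per dialogue.
#'
#' @param seed Master seed.
#' @param n_dialogues_per_context Dialogues generated per context.
#' @param min_turns Minimum alternating turns shown per dialogue.
#' @param n_candidates Candidate responses per dialogue (fixed at 4).
#' @param locale Fixture language (only "es" is shipped).
#' @return A list of class `rt_fixture_config`.
#' @export
fixture_config <- function(seed = 0L, n_dialogues_per_context = 2L,
                           min_turns = 4L, n_candidates = 4L,
                           locale = "es") {
  stopifnot(n_candidates == 4L, identical(locale, "es"))
  structure(list(seed = as.integer(seed),
                 n_dialogues_per_context = as.integer(n_dialogues_per_context),
                 min_turns = as.integer(min_turns),
                 n_candidates = 4L, locale = locale),
            class = "rt_fixture_config")
}

profile_value_pools <- function() {
  list(
    patient_name = c("María", "José", "Carmen", "Antonio", "Guadalupe",
                     "Dolores", "Francisco", "Rosa"),
    apodo = c("Mari", "Pepe", "Carmelita", "Toño", "Lupita", "Lola",
              "Paco", "Rosita"),
    lugar_nacimiento = c("Puebla", "Oaxaca", "Guadalajara", "Mérida",
                         "Morelia", "Veracruz"),
    edad = as.character(70:88),
    genero = c("femenino", "masculino"),
    estado_civil = c("viuda/o", "casada/o", "soltera/o"),
    profesion = c("maestra", "carpintero", "costurera", "comerciante",
                  "enfermera", "agricultor"),
    religion = c("católica", "ninguna"),
    color_favorito = c("azul", "verde", "rojo", "amarillo", "morado"),
    descripcion_lugar_nacimiento = c("su plaza principal",
                                     "sus calles tranquilas",
                                     "el mercado de los domingos"),
    nombre_conyuge = c("Manuel", "Josefina", "Raúl", "Esperanza"),
    numero_hijos = c("dos", "tres", "cuatro", "cinco"),
    familiar_mas_cercano = c("mi hija mayor", "mi nieto", "mi hermana"),
    recuerdo_familiar = c("las comidas de los domingos",
                          "las posadas en casa de mi madre",
                          "los paseos al campo con mis hijos"),
    habito_diario = c("tomar café por la mañana", "regar las plantas",
                      "caminar por el parque", "leer el periódico"),
    rutina_diaria = c("levantarme temprano y desayunar pan dulce",
                      "oír la radio mientras hago el quehacer"),
    habilidad = c("tejer", "bordar", "cantar", "dibujar", "la carpintería"),
    hobby = c("la jardinería", "jugar lotería", "coser", "bailar danzón"),
    labor_hogar = c("cocinar", "barrer el patio", "lavar los trastes",
                    "planchar"),
    lugar_visitado = c("Veracruz", "Acapulco", "la Basílica", "Chapultepec"),
    recuerdo_infancia = c("jugar canicas en la calle",
                          "las ferias del pueblo"),
    pelicula_favorita = c("Nosotros los pobres",
                          "Allá en el Rancho Grande", "El rey del barrio"),
    programa_tv = c("las telenovelas", "el programa de Chespirito",
                    "las noticias"),
    actor_favorito = c("Pedro Infante", "Cantinflas", "María Félix",
                       "Jorge Negrete"),
    musica_favorita = c("la música ranchera", "los boleros", "el danzón"),
    cantante_favorito = c("Pedro Infante", "Javier Solís", "Lola Beltrán",
                          "José Alfredo Jiménez"),
    deporte_favorito = c("el fútbol", "el béisbol", "la lucha libre"),
    equipo_favorito = c("el América", "las Chivas", "los Pumas"),
    comida_favorita = c("el mole poblano", "los tamales", "el pozole",
                        "los chiles en nogada"),
    bebida_favorita = c("el café de olla", "el atole",
                        "el agua de jamaica", "el chocolate caliente"),
    festividad_favorita = c("la Navidad", "el Día de Muertos",
                            "las posadas", "la fiesta del pueblo")
  )
}

#' Generate a fully populated synthetic patient profile
#'
#' Fills all 32 questionnaire slots with plausible Spanish values and
#' registers one to three family members. Deterministic per seed; the
#' result validates against the shipped schema via [create_profile()].
#'
#' @param seed Integer seed.
#' @param schema An `rt_schema`.
#' @return An `rt_profile` (not persisted; pass its `answers`/`family` to
#'   [create_profile()] to store it).
#' @examples
#' p <- generate_profile(seed = 7)
#' get_slot(p, "comida_favorita")
#' @export
generate_profile <- function(seed = 0L, schema = load_schema()) {
  pools <- profile_value_pools()
  with_local_seed(as.integer(seed) + 1L, {
    answers <- list()
    for (slot in schema$slots) {
      pool <- pools[[slot]]
      if (is.null(pool)) {
        # date slot: plausible birth date
        answers[[slot]] <- sprintf(
          "%d de %s de %d", sample(1:28, 1),
          sample(c("enero", "marzo", "mayo", "julio", "septiembre",
                   "noviembre"), 1),
          sample(1935:1952, 1))
      } else {
        answers[[slot]] <- sample(pool, 1)
      }
    }
    members <- list(c("Patricia", "hija"), c("Juan", "hijo"),
                    c("Lucía", "nieta"), c("Miguel", "nieto"),
                    c("Ana", "hija"), c("Carlos", "hermano"),
                    c("Elena", "hermana"), c("Jorge", "hijo"))
    picked <- sample(members, sample(1:3, 1))
    family <- lapply(seq_along(picked), function(i) {
      family_member(i, picked[[i]][1], picked[[i]][2])
    })
    structure(list(patient_id = sprintf("sim%06d", as.integer(seed) %% 1000000L),
                   answers = answers, family = family,
                   created_at = "1970-01-01T00:00:00Z",
                   schema_id = schema$schema_id),
              class = "rt_profile")
  })
}

#' Scripted utterances of a simulated patient
#'
#' A rule-based stand-in for the person in therapy: steers the conversation
#' into the requested context, affirms, echoes the profile value the
#' context personalizes on, and keeps answering long enough to sustain the
#' requested number of turns. Deterministic per (context, seed).
#'
#' @param kb An `rt_kb` (the context must exist in it).
#' @param context_id Target dialogue context.
#' @param profile An `rt_profile`; supplies the topical slot value echoed
#'   in customized contexts.
#' @param seed Integer seed.
#' @param min_turns Minimum alternating turns the stream must sustain
#'   (opening system turn plus two per utterance).
#' @return Character vector of user utterances.
#' @export
simulated_user <- function(kb, context_id, profile = generate_profile(),
                           seed = 0L, min_turns = 4L) {
  if (!context_id %in% names(kb$contexts)) {
    rt_not_found_error(sprintf("unknown context %s", context_id))
  }
  catalog <- dialogue_context_catalog()
  row <- catalog[catalog$context_id == context_id, ]
  if (context_id == "beginning_conversation") {
    utts <- c("hola", "estoy muy bien gracias", "sí")
  } else if (context_id == "leave_conversation") {
    utts <- c("hola", "estoy muy bien gracias", "adiós")
  } else {
    trigger <- if (nrow(row)) row$trigger_phrase else context_id
    slot <- if (nrow(row)) row$slot else NA
    val <- if (!is.na(slot)) get_slot(profile, slot) else NA
    echo <- if (!is.na(val)) paste("sí me encanta", val) else "sí claro que sí"
    utts <- c(trigger, "sí", echo)
  }
  # 1 opening turn + 2 turns per utterance must reach min_turns + 2 so that
  # at least min_turns turns remain once the final response is split off as
  # the candidate
  extra <- c("sí claro", "no", "sí")
  i <- 0L
  while (1L + 2L * length(utts) < min_turns + 2L) {
    i <- i + 1L
    utts <- append(utts, extra[(i - 1L) %% length(extra) + 1L],
                   after = length(utts) - 1L)
  }
  utts
}

make_fixed_clock <- function() {
  i <- 0L
  function() {
    i <<- i + 1L
    sprintf("T%04d", i)
  }
}

#' Generate a static-context evaluation dialogue set
#'
#' Builds, for every dialogue context, `n_dialogues_per_context` scripted
#' conversations between the engine and the simulated user, and attaches to
#' each a set of 4 candidate responses: position 0 is the engine's actual
#' next response; the other three are distractors rendered (with full slot
#' substitution) from the entry templates of other contexts — fluent but
#' contextually wrong, which is what makes the bystander voting task
#' meaningful. Distractors are never string-equal to the true response.
#'
#' @param kb An `rt_kb`.
#' @param profile An `rt_profile` (fully populated works best).
#' @param config An `rt_fixture_config`.
#' @return List of `rt_dialogue` objects (`dialogue_id`, `context_id`,
#'   `turns`, `candidates`; candidates[1] is the system response).
#' @examples
#' \donttest{
#' kb <- load_kb()
#' set <- generate_evaluation_set(kb, generate_profile(1), fixture_config(1))
#' length(set)
#' }
#' @export
generate_evaluation_set <- function(kb, profile,
                                    config = fixture_config()) {
  stopifnot(inherits(kb, "rt_kb"), inherits(profile, "rt_profile"),
            inherits(config, "rt_fixture_config"))
  catalog <- dialogue_context_catalog()
  contexts <- intersect(catalog$context_id, names(kb$contexts))
  dialogues <- list()
  idx <- 0L
  for (cid in contexts) {
    for (k in seq_len(config$n_dialogues_per_context)) {
      idx <- idx + 1L
      seed_i <- derive_seed(config$seed, idx)
      s <- start_session(kb, profile, seed = seed_i,
                         clock = make_fixed_clock())
      utts <- simulated_user(kb, cid, profile, seed = seed_i,
                             min_turns = config$min_turns)
      for (u in utts[-length(utts)]) step_session(s, u)
      truth <- step_session(s, utts[length(utts)])
      turns <- s$transcript[-length(s$transcript)]
      if (length(turns) < config$min_turns) {
        rt_insufficient_kb_error(sprintf(
          "context %s sustained only %d turns (need %d)", cid,
          length(turns), config$min_turns))
      }
      distractors <- sample_distractors(kb, profile, cid, truth,
                                        seed = derive_seed(seed_i, 7L))
      if (length(distractors) < 3L) {
        rt_insufficient_kb_error(sprintf(
          "context %s: could not draw 3 distinct distractors", cid))
      }
      dialogues[[idx]] <- structure(
        list(dialogue_id = sprintf("d%02d", idx),
             context_id = cid,
             turns = lapply(turns, function(t) {
               list(speaker = t$speaker, text = t$raw_text)
             }),
             candidates = c(truth, distractors)),
        class = "rt_dialogue")
    }
  }
  dialogues
}

sample_distractors <- function(kb, profile, context_id, truth, seed) {
  others <- setdiff(names(kb$contexts),
                    c(context_id, "leave_conversation"))
  order_ <- with_local_seed(seed, sample(others))
  out <- character(0)
  for (cid in order_) {
    ctx <- kb$contexts[[cid]]
    entry <- Filter(function(cat) isTRUE(cat$entry), ctx$categories)
    if (!length(entry)) next
    txt <- render_category(kb, entry[[1]], profile,
                           seed = derive_seed(seed, length(out) + 1L))
    if (is.null(txt) || identical(txt, truth) || txt %in% out) next
    out <- c(out, txt)
    if (length(out) == 3L) break
  }
  out
}

#' Simulate bystander evaluator votes over a dialogue set
#'
#' Synthetic stand-in for a human voting panel: each evaluator casts one
#' vote per dialogue, drawn over the candidate positions with the given
#' weights (defaults favor the system's actual response).
#'
#' @param dialogues List of `rt_dialogue`.
#' @param n_evaluators Panel size (11 in the study design).
#' @param seed Integer seed.
#' @param weights Length-4 sampling weights over candidate positions 0-3.
#' @return data.frame with columns `dialogue_id`, `evaluator_id`,
#'   `chosen_candidate`.
#' @export
generate_synthetic_votes <- function(dialogues, n_evaluators = 11L,
                                     seed = 0L,
                                     weights = c(0.55, 0.25, 0.15, 0.05)) {
  stopifnot(length(weights) == 4L, all(weights >= 0), sum(weights) > 0)
  with_local_seed(as.integer(seed) + 11L, {
    rows <- lapply(dialogues, function(d) {
      data.frame(
        dialogue_id = d$dialogue_id,
        evaluator_id = sprintf("e%02d", seq_len(n_evaluators)),
        chosen_candidate = sample(0:3, n_evaluators, replace = TRUE,
                                  prob = weights),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Write / read an evaluation dialogue set as JSON
#'
#' @param dialogues List of `rt_dialogue`.
#' @param path Output JSON path.
#' @return `write_evaluation_set` returns `path` invisibly;
#'   `read_evaluation_set` returns the list of `rt_dialogue`.
#' @export
write_evaluation_set <- function(dialogues, path) {
  doc <- lapply(dialogues, unclass)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE),
             path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_evaluation_set
#' @export
read_evaluation_set <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(doc, function(d) {
    structure(list(dialogue_id = d$dialogue_id, context_id = d$context_id,
                   turns = lapply(d$turns, function(t) {
                     list(speaker = t$speaker, text = t$text)
                   }),
                   candidates = unlist(d$candidates)),
              class = "rt_dialogue")
  })
}

#' Write an empty votes CSV scaffold for a dialogue set
#'
#' @param dialogues List of `rt_dialogue`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_votes_scaffold <- function(dialogues, path) {
  utils::write.csv(
    data.frame(dialogue_id = character(0), evaluator_id = character(0),
               chosen_candidate = integer(0)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate reference/hypothesis transcript pairs with controlled errors
#'
#' References are sampled Spanish sentences; hypotheses corrupt them with
#' independent per-token substitutions, insertions and deletions at the
#' configured rates — a parametric stand-in for recognizer output whose
#' measured S/I/D rates can be compared against the configured ones.
#' Corruptions never create consecutive duplicate tokens, which the
#' normalizer would collapse.
#'
#' @param seed Integer seed.
#' @param n_pairs Number of pairs.
#' @param error_rates List with elements `sub`, `ins`, `del`, each in
#'   `[0, 1]`.
#' @return data.frame with columns `reference`, `hypothesis`.
#' @examples
#' generate_transcript_pairs(1, 2, list(sub = 0.2, ins = 0, del = 0))
#' @export
generate_transcript_pairs <- function(seed = 0L, n_pairs = 8L,
                                      error_rates = list(sub = 0.1,
                                                         ins = 0.05,
                                                         del = 0.05)) {
  for (r in c("sub", "ins", "del")) {
    v <- error_rates[[r]]
    if (is.null(v) || !is.numeric(v) || v < 0 || v > 1) {
      rt_range_error(sprintf("error rate %s must be in [0, 1]", r))
    }
  }
  vocab <- c("casa", "perro", "calle", "mercado", "domingo", "familia",
             "canción", "recuerdo", "pueblo", "iglesia", "campo", "flor",
             "comida", "fiesta", "niños", "escuela", "tren", "plaza",
             "abuela", "jardín", "tarde", "mañana", "lluvia", "sol",
             "pan", "café", "radio", "baile", "viaje", "mar", "montaña",
             "amigo", "vecina", "parque", "feria", "cocina", "patio",
             "nieto", "historia", "vida")
  pick_diff <- function(avoid) {
    repeat {
      w <- vocab[sample.int(length(vocab), 1L)]
      if (!w %in% avoid) return(w)
    }
  }
  with_local_seed(as.integer(seed) + 97L, {
    refs <- character(n_pairs)
    hyps <- character(n_pairs)
    for (i in seq_len(n_pairs)) {
      n <- sample(6:12, 1L)
      ref <- character(n)
      for (j in seq_len(n)) {
        ref[j] <- pick_diff(if (j > 1L) ref[j - 1L] else character(0))
      }
      hyp <- character(0)
      for (j in seq_len(n)) {
        tok <- ref[j]
        if (stats::runif(1) < error_rates$del) {
          # deletion: skip, unless the gap would fuse identical neighbors
          fuses <- length(hyp) && j < n &&
            identical(ref[j + 1L], hyp[length(hyp)])
          if (!fuses) next
        }
        if (stats::runif(1) < error_rates$sub) {
          avoid <- c(tok, if (length(hyp)) hyp[length(hyp)],
                     if (j < n) ref[j + 1L])
          tok <- pick_diff(avoid)
        }
        hyp <- c(hyp, tok)
        if (stats::runif(1) < error_rates$ins) {
          hyp <- c(hyp, pick_diff(c(tok, if (j < n) ref[j + 1L])))
        }
      }
      refs[i] <- paste(ref, collapse = " ")
      hyps[i] <- paste(hyp, collapse = " ")
    }
    data.frame(reference = refs, hypothesis = hyps,
               stringsAsFactors = FALSE)
  })
}
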
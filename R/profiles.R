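#' Open (or create) a patient-profile store
#'
#' Profiles are kept one JSON document per patient in a plain directory —
#' `<dir>/profiles/<patient_id>.json` — with session transcripts under
#' `<dir>/sessions/`. The layout keeps every record greppable and makes the
#' deletion contract auditable: removing a patient removes files, nothing
#' else retains the id.
#'
#' @param dir Directory for the store; created if missing.
#' @return An object of class `rt_profile_store`.
#' @export
profile_store <- function(dir) {
  dir.create(file.path(dir, "profiles"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "sessions"), recursive = TRUE,
             showWarnings = FALSE)
  structure(list(dir = normalizePath(dir)), class = "rt_profile_store")
}

#' Construct a family-member record
#'
#' @param index 1-based position in the patient's family list; position `i`
#'   exposes the derived slots `fam<i>_name` and `parentesco_fam<i>`.
#' @param name Given name.
#' @param relationship Spanish kinship term (e.g. "hija", "nieto").
#' @return A named list of class `rt_family_member`.
#' @export
family_member <- function(index, name, relationship) {
  stopifnot(is.numeric(index), index >= 1, nzchar(name),
            nzchar(relationship))
  structure(list(index = as.integer(index), name = name,
                 relationship = relationship),
            class = "rt_family_member")
}

#' Create and persist a patient profile
#'
#' Answers are validated against the schema: every key must be a schema slot
#' and values must be non-empty after trimming (missing answers are simply
#' omitted, never stored as empty strings). Family members must occupy
#' contiguous 1-based positions. The caregiver-provided answers drive the
#' customized dialogue templates at render time.
#'
#' @param store An `rt_profile_store`.
#' @param schema An `rt_schema` (default: the shipped questionnaire).
#' @param answers Named list/character vector of slot values.
#' @param family List of [family_member()] records (may be empty).
#' @param patient_id Optional explicit id; autogenerated when `NULL`.
#' @param created_at ISO-8601 timestamp; injectable for deterministic tests.
#' @return The persisted profile, class `rt_profile`.
#' @examples
#' st <- profile_store(tempfile("store"))
#' p <- create_profile(st, answers = list(patient_name = "María"),
#'                     family = list(family_member(1, "Patricia", "hija")))
#' get_slot(p, "fam1_name")
#' @export
create_profile <- function(store, schema = load_schema(), answers = list(),
                           family = list(), patient_id = NULL,
                           created_at = format(Sys.time(),
                                               "%Y-%m-%dT%H:%M:%S%z")) {
  stopifnot(inherits(store, "rt_profile_store"),
            inherits(schema, "rt_schema"))
  answers <- as.list(answers)
  unknown <- setdiff(names(answers), schema$slots)
  if (length(unknown)) {
    rt_unknown_slot_error(sprintf("answer key(s) outside the schema: %s",
                                  paste(unknown, collapse = ", ")))
  }
  answers <- lapply(answers, function(v) trimws(as.character(v)))
  answers <- answers[vapply(answers, nzchar, TRUE)]

  family <- lapply(family, function(f) {
    if (!inherits(f, "rt_family_member")) {
      f <- family_member(f$index, f$name, f$relationship)
    }
    f
  })
  idx <- vapply(family, function(f) f$index, 0L)
  if (length(idx) && !identical(sort(idx), seq_along(idx))) {
    rt_schema_error("family member indices must be contiguous from 1")
  }
  family <- family[order(idx)]

  if (is.null(patient_id)) {
    existing <- list_profiles(store)
    n <- length(existing)
    repeat {
      n <- n + 1L
      patient_id <- sprintf("p%06d", n)
      if (!patient_id %in% existing) break
    }
  }
  profile <- structure(
    list(patient_id = patient_id, answers = answers, family = family,
         created_at = created_at, schema_id = schema$schema_id),
    class = "rt_profile")
  write_profile(store, profile)
  profile
}

write_profile <- function(store, profile) {
  doc <- list(
    patient_id = profile$patient_id,
    answers = profile$answers,
    family = lapply(profile$family, function(f) {
      list(index = f$index, name = f$name, relationship = f$relationship)
    }),
    created_at = profile$created_at,
    schema_id = profile$schema_id
  )
  path <- file.path(store$dir, "profiles",
                    paste0(profile$patient_id, ".json"))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE),
             path, useBytes = TRUE)
  invisible(path)
}

#' Retrieve a stored profile
#'
#' @param store An `rt_profile_store`.
#' @param patient_id Profile identifier.
#' @return The `rt_profile`.
#' @export
get_profile <- function(store, patient_id) {
  path <- file.path(store$dir, "profiles", paste0(patient_id, ".json"))
  if (!file.exists(path)) {
    rt_not_found_error(sprintf("no profile with id %s", patient_id))
  }
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  structure(
    list(patient_id = doc$patient_id,
         answers = lapply(doc$answers, as.character),
         family = lapply(doc$family, function(f) {
           family_member(f$index, f$name, f$relationship)
         }),
         created_at = doc$created_at,
         schema_id = doc$schema_id),
    class = "rt_profile")
}

#' List stored profile ids
#' @param store An `rt_profile_store`.
#' @return Character vector of patient ids.
#' @export
list_profiles <- function(store) {
  sort(tools::file_path_sans_ext(dir(file.path(store$dir, "profiles"),
                                     pattern = "\\.json$")))
}

#' Look up a profile slot, including derived family slots
#'
#' Family members registered at position `i` expose two derived slots:
#' `fam<i>_name` (given name) and `parentesco_fam<i>` (kinship term). Unknown
#' or unanswered slots yield `NA_character_` — never an error — so template
#' rendering can skip customized templates for incomplete profiles.
#'
#' @param profile An `rt_profile`.
#' @param slot_name Slot identifier.
#' @return The stored string, or `NA_character_` when absent.
#' @export
get_slot <- function(profile, slot_name) {
  stopifnot(inherits(profile, "rt_profile"), is.character(slot_name),
            length(slot_name) == 1L)
  m <- regmatches(slot_name,
                  regexec("^fam([0-9]+)_name$", slot_name))[[1]]
  if (length(m) == 2L) {
    i <- as.integer(m[2])
    if (i >= 1L && i <= length(profile$family)) {
      return(profile$family[[i]]$name)
    }
    return(NA_character_)
  }
  m <- regmatches(slot_name,
                  regexec("^parentesco_fam([0-9]+)$", slot_name))[[1]]
  if (length(m) == 2L) {
    i <- as.integer(m[2])
    if (i >= 1L && i <= length(profile$family)) {
      return(profile$family[[i]]$relationship)
    }
    return(NA_character_)
  }
  v <- profile$answers[[slot_name]]
  if (is.null(v) || !nzchar(v)) NA_character_ else v
}

#' Delete a patient's records completely
#'
#' Honors the withdrawal contract: the profile document and every session
#' log referencing the patient id are removed, and the report enumerates the
#' files deleted. After this call a full-store scan finds no occurrence of
#' the id.
#'
#' @param store An `rt_profile_store`.
#' @param patient_id Profile identifier.
#' @return Invisibly, a list with `patient_id` and `removed` (paths).
#' @export
delete_profile <- function(store, patient_id) {
  path <- file.path(store$dir, "profiles", paste0(patient_id, ".json"))
  if (!file.exists(path)) {
    rt_not_found_error(sprintf("no profile with id %s", patient_id))
  }
  removed <- path
  sess_dir <- file.path(store$dir, "sessions")
  for (f in dir(sess_dir, full.names = TRUE)) {
    if (any(grepl(patient_id, readLines(f, warn = FALSE), fixed = TRUE))) {
      removed <- c(removed, f)
    }
  }
  unlink(removed)
  invisible(list(patient_id = patient_id, removed = removed))
}

#' @export
print.rt_profile <- function(x, ...) {
  cat("<patient profile> ", x$patient_id, "\n", sep = "")
  cat("  answered slots: ", length(x$answers),
      "; family members: ", length(x$family), "\n", sep = "")
  invisible(x)
}
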
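#' Load an AIML-subset knowledge base
#'
#' Parses one or more knowledge-base XML files into an in-memory index of
#' dialogue contexts. The dialect is the subset needed for profile-driven
#' reminiscence dialogue (see `vignette("reminiscence-engine")` and
#' `inst/extdata/kb/DIALECT.md`):
#'
#' * `<aiml>` root; `<topic name="..." description="...">` scopes categories
#'   to a dialogue context; topic-less categories are global.
#' * `<category>` holds one `<pattern>` and one `<template>`. Attributes:
#'   `trigger="true"` (matching it from another context switches context),
#'   `entry="true"` (rendered when the system itself opens the context),
#'   `fallback="true"` (the context's prompt when nothing matches; its
#'   pattern is the reserved token `FALLBACK`).
#' * Patterns are token sequences with wildcards `*` and `_`, each matching
#'   one or more tokens; literal tokens are normalized with the same
#'   pipeline as user utterances.
#' * Templates mix literal text, `<get name="slot"/>` profile references,
#'   `<random><li>...</li></random>` choice lists, `<condition
#'   name="slot"><li value="present">..</li><li>..</li></condition>`
#'   presence switches, and `<srai>...</srai>` redirection (depth-capped).
#'
#' Every `<get>`/`<condition>` slot must exist in the profile schema or be a
#' derived family slot (`fam<i>_name`, `parentesco_fam<i>`).
#'
#' @param paths Character vector of KB XML files, or a directory containing
#'   them. Defaults to the Spanish KB shipped with the package (20 dialogue
#'   contexts).
#' @param schema An `rt_schema` used to validate slot references.
#' @return An object of class `rt_kb`: list with `contexts` (named list),
#'   `globals` (topic-less categories), `categories` (flat list) and
#'   `validation` (files read, category count).
#' @export
load_kb <- function(paths = system.file("extdata", "kb", package = "recuerda"),
                    schema = load_schema()) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- sort(dir(paths, pattern = "\\.xml$", full.names = TRUE))
  }
  if (!length(paths)) rt_kb_syntax_error("no knowledge-base files given")
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    rt_kb_syntax_error(paste("knowledge-base file(s) not found:",
                             paste(missing, collapse = ", ")))
  }
  contexts <- list()
  globals <- list()
  categories <- list()
  for (path in paths) {
    doc <- tryCatch(xml2::read_xml(path), error = function(e) {
      rt_kb_syntax_error(sprintf("%s: malformed XML (%s)", basename(path),
                                 conditionMessage(e)))
    })
    if (xml2::xml_name(doc) != "aiml") {
      rt_kb_syntax_error(sprintf("%s: root element must be <aiml>",
                                 basename(path)))
    }
    for (node in xml2::xml_children(doc)) {
      nm <- xml2::xml_name(node)
      if (nm == "topic") {
        cid <- xml2::xml_attr(node, "name")
        if (is.na(cid) || !nzchar(cid)) {
          rt_kb_syntax_error(sprintf("%s: <topic> without name", basename(path)))
        }
        if (is.null(contexts[[cid]])) {
          contexts[[cid]] <- list(
            context_id = cid,
            description = xml2::xml_attr(node, "description"),
            categories = list())
        }
        for (catnode in xml2::xml_children(node)) {
          if (xml2::xml_name(catnode) != "category") {
            rt_kb_syntax_error(sprintf("%s: unexpected tag <%s> inside <topic>",
                                       basename(path), xml2::xml_name(catnode)))
          }
          cat <- parse_category(catnode, cid, schema, basename(path),
                                length(categories) + 1L)
          contexts[[cid]]$categories <- c(contexts[[cid]]$categories, list(cat))
          categories <- c(categories, list(cat))
        }
      } else if (nm == "category") {
        cat <- parse_category(node, NA_character_, schema, basename(path),
                              length(categories) + 1L)
        globals <- c(globals, list(cat))
        categories <- c(categories, list(cat))
      } else {
        rt_kb_syntax_error(sprintf("%s: unexpected tag <%s> under <aiml>",
                                   basename(path), nm))
      }
    }
  }
  structure(list(contexts = contexts, globals = globals,
                 categories = categories,
                 validation = list(files = paths,
                                   n_contexts = length(contexts),
                                   n_categories = length(categories))),
            class = "rt_kb")
}

parse_category <- function(node, context_id, schema, file, ord) {
  kids <- xml2::xml_children(node)
  names_ <- vapply(kids, xml2::xml_name, "")
  bad <- setdiff(names_, c("pattern", "template"))
  if (length(bad)) {
    rt_kb_syntax_error(sprintf("%s: unknown tag <%s> inside <category>",
                               file, bad[1]))
  }
  pat_node <- kids[names_ == "pattern"]
  tpl_node <- kids[names_ == "template"]
  if (length(pat_node) != 1L || length(tpl_node) != 1L) {
    rt_kb_syntax_error(sprintf(
      "%s: <category> needs exactly one <pattern> and one <template>", file))
  }
  pattern <- parse_pattern(xml2::xml_text(pat_node[[1]]), file)
  templates <- parse_template(tpl_node[[1]], schema, file)
  slots <- unique(unlist(lapply(templates, template_slots)))
  structure(list(
    context_id = context_id,
    pattern = pattern,
    templates = templates,
    kind = if (length(slots)) "customized" else "generic",
    slots = slots,
    trigger = identical(xml2::xml_attr(node, "trigger"), "true"),
    entry = identical(xml2::xml_attr(node, "entry"), "true"),
    fallback = identical(xml2::xml_attr(node, "fallback"), "true"),
    order = ord
  ), class = "rt_category")
}

# Pattern tokens: wildcards pass through; literals go through the utterance
# normalizer so patterns and inputs share one alphabet.
parse_pattern <- function(text, file) {
  toks <- tokenize(text)
  if (!length(toks)) {
    rt_kb_syntax_error(sprintf("%s: empty <pattern>", file))
  }
  vapply(toks, function(tk) {
    if (tk %in% c("*", "_")) return(tk)
    norm <- normalize_utterance(tk)$tokens
    if (length(norm) != 1L) {
      rt_kb_syntax_error(sprintf(
        "%s: pattern token %s does not normalize to one token", file, tk))
    }
    norm
  }, "", USE.NAMES = FALSE)
}

# A <template> yields a list of rt_template variants: one per <random> <li>,
# or a single variant when there is no <random>. Each variant is a parts
# tree of text / get / condition / srai segments.
parse_template <- function(node, schema, file) {
  kids <- xml2::xml_children(node)
  if (length(kids) == 1L && xml2::xml_name(kids[[1]]) == "random") {
    lis <- xml2::xml_children(kids[[1]])
    if (!length(lis) || any(vapply(lis, xml2::xml_name, "") != "li")) {
      rt_kb_syntax_error(sprintf("%s: <random> must contain only <li>", file))
    }
    return(lapply(lis, function(li) new_template(parse_parts(li, schema, file))))
  }
  list(new_template(parse_parts(node, schema, file)))
}

new_template <- function(parts) {
  txt <- flatten_literal(parts)
  structure(list(parts = parts,
                 follow_up = grepl("\\?\\s*$", txt)),
            class = "rt_template")
}

# literal text of a parts tree with slot refs elided (for the follow-up flag)
flatten_literal <- function(parts) {
  paste(vapply(parts, function(p) {
    switch(p$type,
           text = p$text,
           get = "",
           srai = "",
           condition = flatten_literal(p$present))
  }, ""), collapse = "")
}

parse_parts <- function(node, schema, file) {
  parts <- list()
  push_text <- function(txt) {
    if (nzchar(txt)) parts[[length(parts) + 1L]] <<- list(type = "text",
                                                          text = txt)
  }
  for (child in xml2::xml_contents(node)) {
    nm <- xml2::xml_name(child)
    if (nm == "text") {
      push_text(squeeze_ws(xml2::xml_text(child)))
    } else if (nm == "get") {
      slot <- xml2::xml_attr(child, "name")
      check_slot(slot, schema, file)
      parts[[length(parts) + 1L]] <- list(type = "get", slot = slot)
    } else if (nm == "srai") {
      parts[[length(parts) + 1L]] <- list(type = "srai",
                                          text = xml2::xml_text(child))
    } else if (nm == "condition") {
      slot <- xml2::xml_attr(child, "name")
      check_slot(slot, schema, file)
      lis <- xml2::xml_children(child)
      if (any(vapply(lis, xml2::xml_name, "") != "li")) {
        rt_kb_syntax_error(sprintf("%s: <condition> must contain only <li>",
                                   file))
      }
      vals <- vapply(lis, function(li) xml2::xml_attr(li, "value"), "")
      present <- which(vals == "present")
      absent <- which(is.na(vals))
      if (length(present) != 1L || length(absent) > 1L) {
        rt_kb_syntax_error(sprintf(
          "%s: <condition> needs one value=\"present\" <li> and at most one default <li>",
          file))
      }
      parts[[length(parts) + 1L]] <- list(
        type = "condition", slot = slot,
        present = parse_parts(lis[[present]], schema, file),
        absent = if (length(absent)) parse_parts(lis[[absent]], schema, file))
    } else {
      rt_kb_syntax_error(sprintf("%s: unknown template tag <%s>", file, nm))
    }
  }
  parts
}

squeeze_ws <- function(x) gsub("[[:space:]]+", " ", x)

check_slot <- function(slot, schema, file) {
  if (is.na(slot) || !nzchar(slot)) {
    rt_kb_syntax_error(sprintf("%s: slot reference without name", file))
  }
  derived <- grepl("^fam[0-9]+_name$", slot) ||
    grepl("^parentesco_fam[0-9]+$", slot)
  if (!derived && !slot %in% schema$slots) {
    rt_kb_slot_error(sprintf(
      "%s: template references slot \"%s\" absent from the schema",
      file, slot))
  }
  invisible(TRUE)
}

template_slots <- function(template) {
  walk <- function(parts) {
    unlist(lapply(parts, function(p) {
      switch(p$type,
             get = p$slot,
             condition = c(p$slot, walk(p$present),
                           if (!is.null(p$absent)) walk(p$absent)),
             NULL)
    }))
  }
  unique(walk(template$parts))
}

#' @export
print.rt_kb <- function(x, ...) {
  cat("<knowledge base> ", length(x$contexts), " contexts, ",
      length(x$categories), " categories\n", sep = "")
  invisible(x)
}
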
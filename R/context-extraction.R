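# Biological context extraction: context elements are entities of type
# cell / drug / disease / organism found inside conditioning clauses --
# prepositional clauses or phrases and relative-adverb clauses. Clause
# spans are first-class input (annotated mode, from an upstream parser or
# fixture generator); a transparent token-level heuristic is the fallback
# when no parse is available.

CONTEXT_PREPOSITIONS <- c("in", "within", "under", "during", "among", "from")
RELATIVE_ADVERBS <- c("where", "when", "while")
COORD_CONJUNCTIONS <- c("and", "or", "but")

#' Detect conditioning clause spans in a sentence
#'
#' In `annotated` mode the sentence's own `clauses` spans are returned
#' verbatim. In `heuristic` mode, maximal spans are detected that start at a
#' conditioning preposition (in, within, under, during, among, from) or a
#' relative adverb (where, when, while) and run to the next clause boundary:
#' a comma, semicolon, sentence-final period, or a coordinating conjunction
#' (and/or/but). Nested triggers inside an open span do not start new spans.
#'
#' @param sentence an [annotated_sentence()].
#' @param mode `"annotated"` or `"heuristic"`.
#' @return data.frame with columns `start`, `end` (0-based half-open) and
#'   `kind`.
#' @export
detect_context_spans <- function(sentence,
                                 mode = c("annotated", "heuristic")) {
  mode <- match.arg(mode)
  if (mode == "annotated") return(sentence$clauses)
  heuristic_clause_spans(sentence$text)
}

heuristic_clause_spans <- function(text) {
  m <- gregexpr("\\S+", text)[[1]]
  if (m[1] == -1) return(empty_clauses())
  starts <- as.integer(m) - 1L              # 0-based token starts
  lens <- attr(m, "match.length")
  tokens <- regmatches(text, gregexpr("\\S+", text))[[1]]
  words <- tolower(gsub("[[:punct:]]+$", "", tokens))
  spans <- empty_clauses()
  open <- FALSE
  span_start <- NA_integer_
  span_end <- NA_integer_
  span_kind <- NA_character_
  close_span <- function() {
    if (open && span_end > span_start)
      spans <<- rbind(spans, data.frame(start = span_start, end = span_end,
                                        kind = span_kind,
                                        stringsAsFactors = FALSE))
    open <<- FALSE
  }
  for (i in seq_along(tokens)) {
    tok <- tokens[i]
    w <- words[i]
    if (!open) {
      kind <- if (w %in% CONTEXT_PREPOSITIONS) "prepositional"
              else if (w %in% RELATIVE_ADVERBS) "relative_adverb"
              else NA_character_
      if (!is.na(kind)) {
        open <- TRUE
        span_start <- starts[i]
        span_end <- starts[i] + nchar(w)
        span_kind <- kind
      }
      if (open && grepl("[,.;]$", tok)) close_span()
      next
    }
    if (w %in% COORD_CONJUNCTIONS) {          # boundary before conjunction
      close_span()
      next
    }
    span_end <- starts[i] + nchar(w)          # token minus trailing punct
    if (grepl("[,.;]$", tok)) close_span()    # boundary after this token
  }
  close_span()
  spans
}

#' Extract the biological context of a sentence
#'
#' Every entity of type cell, drug, disease or organism whose character span
#' intersects a detected clause span contributes its normalized term to the
#' matching context slot; slots with no hit are `NoData`. Context entities
#' outside every clause span are never extracted. The term is the entity's
#' official symbol when present, otherwise the lowercased,
#' whitespace-stripped surface form.
#'
#' @param sentence an [annotated_sentence()].
#' @param mode clause-span source, as in [detect_context_spans()].
#' @return a [context_tuple()].
#' @export
extract_context <- function(sentence, mode = c("annotated", "heuristic")) {
  mode <- match.arg(mode)
  spans <- detect_context_spans(sentence, mode)
  ents <- sentence$entities
  ents <- ents[ents$type %in% CONTEXT_SLOTS, , drop = FALSE]
  slots <- stats::setNames(vector("list", length(CONTEXT_SLOTS)),
                           CONTEXT_SLOTS)
  if (nrow(ents) > 0 && nrow(spans) > 0) {
    for (i in seq_len(nrow(ents))) {
      hit <- any(ents$start[i] < spans$end & spans$start < ents$end[i])
      if (!hit) next
      term <- if (nzchar(ents$symbol[i])) ents$symbol[i] else ents$surface[i]
      slots[[ents$type[i]]] <- c(slots[[ents$type[i]]], normalize_term(term))
    }
  }
  context_tuple(cell = slots$cell, drug = slots$drug,
                disease = slots$disease, organism = slots$organism)
}

#' Extract context-annotated co-occurrence relations from sentences
#'
#' Runs [extract_cooccurrence_pairs()] and [extract_context()] on each
#' sentence and stamps the sentence's context tuple onto all relations
#' extracted from it, producing a relation table ready for the ABC models.
#'
#' @param sentences list of [annotated_sentence()] objects.
#' @param mode clause-span source, as in [detect_context_spans()].
#' @return a `relation_table`.
#' @export
extract_relations <- function(sentences,
                              mode = c("annotated", "heuristic")) {
  mode <- match.arg(mode)
  tables <- lapply(sentences, function(s) {
    rel <- extract_cooccurrence_pairs(s)
    if (nrow(rel) == 0) return(rel)
    ctx <- extract_context(s, mode)
    for (slot in CONTEXT_SLOTS)
      rel[[slot]] <- if (is.null(ctx[[slot]])) NA_character_
                     else context_slot_to_cell(ctx[[slot]])
    rel
  })
  if (length(tables) == 0) return(relation_table())
  as_relation_table(do.call(rbind, c(tables, list(make.row.names = FALSE))))
}
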
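# Annotated sentences: the unit of extraction. Each sentence carries typed
# entity annotations (gene / cell / drug / disease / organism, with 0-based
# half-open character spans and official symbols) and optional clause spans
# marking prepositional or relative-adverb clauses, which stand in for a
# full constituency parse.

ENTITY_TYPES <- c("gene", "cell", "drug", "disease", "organism")
CLAUSE_KINDS <- c("prepositional", "relative_adverb")

#' Construct an annotated sentence
#'
#' @param pmid document identifier.
#' @param sentence_id integer sentence number within the abstract (>= 1).
#' @param text the sentence string.
#' @param entities data.frame with columns `start`, `end` (0-based,
#'   half-open character span), `type` (one of gene, cell, drug, disease,
#'   organism), `surface`, `symbol` (official symbol; lowercased). May have
#'   zero rows.
#' @param clauses data.frame with columns `start`, `end`, `kind`
#'   (`"prepositional"` or `"relative_adverb"`); may have zero rows.
#' @return an object of class `annotated_sentence`.
#' @export
annotated_sentence <- function(pmid, sentence_id, text,
                               entities = empty_entities(),
                               clauses = empty_clauses()) {
  entities <- as.data.frame(entities, stringsAsFactors = FALSE)
  clauses <- as.data.frame(clauses, stringsAsFactors = FALSE)
  if (nrow(entities) == 0) entities <- empty_entities()
  if (nrow(clauses) == 0) clauses <- empty_clauses()
  stopifnot(all(c("start", "end", "type", "surface", "symbol") %in%
                  names(entities)),
            all(c("start", "end", "kind") %in% names(clauses)))
  entities$start <- as.integer(entities$start)
  entities$end <- as.integer(entities$end)
  entities$symbol <- tolower(entities$symbol)
  clauses$start <- as.integer(clauses$start)
  clauses$end <- as.integer(clauses$end)
  nc <- nchar(text)
  if (nrow(entities) > 0) {
    if (any(!entities$type %in% ENTITY_TYPES))
      stop("unknown entity type(s): ",
           paste(setdiff(entities$type, ENTITY_TYPES), collapse = ", "),
           call. = FALSE)
    if (any(entities$start < 0 | entities$end > nc |
              entities$start >= entities$end))
      stop("entity span outside sentence bounds (pmid ", pmid,
           ", sentence ", sentence_id, ")", call. = FALSE)
  }
  if (nrow(clauses) > 0) {
    if (any(!clauses$kind %in% CLAUSE_KINDS))
      stop("unknown clause kind(s): ",
           paste(setdiff(clauses$kind, CLAUSE_KINDS), collapse = ", "),
           call. = FALSE)
    if (any(clauses$start < 0 | clauses$end > nc |
              clauses$start >= clauses$end))
      stop("clause span outside sentence bounds (pmid ", pmid,
           ", sentence ", sentence_id, ")", call. = FALSE)
  }
  structure(
    list(pmid = as.character(pmid), sentence_id = as.integer(sentence_id),
         text = text, entities = entities, clauses = clauses),
    class = "annotated_sentence"
  )
}

empty_entities <- function() {
  data.frame(start = integer(), end = integer(), type = character(),
             surface = character(), symbol = character(),
             stringsAsFactors = FALSE)
}

empty_clauses <- function() {
  data.frame(start = integer(), end = integer(), kind = character(),
             stringsAsFactors = FALSE)
}

#' @export
print.annotated_sentence <- function(x, ...) {
  cat(sprintf("<sentence pmid=%s id=%d: %d entities, %d clause spans>\n",
              x$pmid, x$sentence_id, nrow(x$entities), nrow(x$clauses)))
  cat(" ", x$text, "\n")
  invisible(x)
}

# annotate surface occurrences by locating them in the text; convenience
# used by fixtures and the corpus generator so spans never drift.
locate_entity <- function(text, surface, type, symbol,
                          occurrence = 1L) {
  hits <- gregexpr(surface, text, fixed = TRUE)[[1]]
  if (hits[1] == -1 || length(hits) < occurrence)
    stop("surface '", surface, "' not found in sentence", call. = FALSE)
  start <- hits[occurrence] - 1L  # to 0-based
  data.frame(start = start, end = start + nchar(surface), type = type,
             surface = surface, symbol = tolower(symbol),
             stringsAsFactors = FALSE)
}

#' Read an annotated-sentence file
#'
#' Tab-separated dialect with header `PMID`, `Sentence_ID`, `Text`,
#' `Entities`, `Clauses`. The `Entities` cell packs annotations as
#' `start:end:type:surface:symbol` entries joined by `|` (spans 0-based,
#' half-open); `Clauses` packs `start:end:kind` entries the same way.
#' Either cell may be empty.
#'
#' @param path file path.
#' @return list of [annotated_sentence()] objects, in file order.
#' @export
read_annotated_sentences <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL,
                           fileEncoding = "UTF-8")
  need <- c("PMID", "Sentence_ID", "Text", "Entities", "Clauses")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0)
    stop("annotated-sentence file missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  lapply(seq_len(nrow(raw)), function(i) {
    annotated_sentence(
      pmid = raw$PMID[i],
      sentence_id = as.integer(raw$Sentence_ID[i]),
      text = raw$Text[i],
      entities = unpack_entities(raw$Entities[i]),
      clauses = unpack_clauses(raw$Clauses[i])
    )
  })
}

#' Write an annotated-sentence file
#'
#' @param sentences list of [annotated_sentence()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotated_sentences <- function(sentences, path) {
  rows <- lapply(sentences, function(s) {
    data.frame(
      PMID = s$pmid, Sentence_ID = s$sentence_id, Text = s$text,
      Entities = pack_entities(s$entities),
      Clauses = pack_clauses(s$clauses),
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows) == 0)
    data.frame(PMID = character(), Sentence_ID = integer(),
               Text = character(), Entities = character(),
               Clauses = character())
  else do.call(rbind, c(rows, list(make.row.names = FALSE)))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

pack_entities <- function(entities) {
  if (nrow(entities) == 0) return("")
  paste(sprintf("%d:%d:%s:%s:%s", entities$start, entities$end,
                entities$type, entities$surface, entities$symbol),
        collapse = "|")
}

unpack_entities <- function(cell) {
  if (is.na(cell) || !nzchar(cell)) return(empty_entities())
  parts <- strsplit(strsplit(cell, "|", fixed = TRUE)[[1]], ":", fixed = TRUE)
  bad <- which(lengths(parts) != 5L)
  if (length(bad) > 0)
    stop("malformed entity annotation: '",
         paste(parts[[bad[1]]], collapse = ":"), "'", call. = FALSE)
  do.call(rbind, lapply(parts, function(p) {
    data.frame(start = as.integer(p[1]), end = as.integer(p[2]),
               type = p[3], surface = p[4], symbol = p[5],
               stringsAsFactors = FALSE)
  }))
}

pack_clauses <- function(clauses) {
  if (nrow(clauses) == 0) return("")
  paste(sprintf("%d:%d:%s", clauses$start, clauses$end, clauses$kind),
        collapse = "|")
}

unpack_clauses <- function(cell) {
  if (is.na(cell) || !nzchar(cell)) return(empty_clauses())
  parts <- strsplit(strsplit(cell, "|", fixed = TRUE)[[1]], ":", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad) > 0)
    stop("malformed clause annotation: '",
         paste(parts[[bad[1]]], collapse = ":"), "'", call. = FALSE)
  do.call(rbind, lapply(parts, function(p) {
    data.frame(start = as.integer(p[1]), end = as.integer(p[2]), kind = p[3],
               stringsAsFactors = FALSE)
  }))
}
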
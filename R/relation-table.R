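# Relation tables: one row per extracted entity relation, with provenance,
# verb metadata and the four biological context columns. The on-disk dialect
# is tab-separated UTF-8 with the fixed 14-column header (plus an optional
# Origin column distinguishing verb-based / co-occurrence / assigned rows).

RELATION_HEADER <- c(
  "PMID", "Sentence_ID", "Entity1", "Entity1OfficialSymbol",
  "Entity2", "Entity2OfficialSymbol", "Negation", "Voice", "Verb",
  "Re_Type", "CELL", "DRUG", "DISEASE", "ORGANISM"
)
ORIGIN_COLUMN <- "Origin"

RELATION_COLUMNS <- c(
  "pmid", "sentence_id", "entity1", "entity1_symbol",
  "entity2", "entity2_symbol", "negation", "voice", "verb",
  "re_type", "cell", "drug", "disease", "organism", "origin"
)

ORIGIN_LEVELS <- c("verb_based", "cooccurrence", "assigned")

#' Construct a relation table
#'
#' The canonical in-memory container for extracted entity relations: a
#' data.frame of class `relation_table` with one row per relation. Context
#' columns hold semicolon-joined normalized term sets, `NA` meaning
#' `NoData`.
#'
#' @param pmid document identifiers (coerced to character).
#' @param sentence_id integer sentence numbers (>= 1).
#' @param entity1,entity2 surface forms as they appeared in the sentence.
#' @param entity1_symbol,entity2_symbol official symbols (lowercased); the
#'   two symbols of a row must differ.
#' @param negation `"POSITIVE"` or `"NEGATIVE"`.
#' @param voice `"ACTIVE"` or `"PASSIVE"`.
#' @param verb main verb connecting the entities (may be empty for
#'   co-occurrence rows).
#' @param re_type relation type label (e.g. `"AFFECTS"`, `"COOCCUR"`).
#' @param cell,drug,disease,organism context columns: `NA` for `NoData` or
#'   semicolon-joined term sets.
#' @param origin `"verb_based"`, `"cooccurrence"` or `"assigned"`.
#' @return a `relation_table` data.frame.
#' @export
relation_table <- function(pmid = character(), sentence_id = integer(),
                           entity1 = character(), entity1_symbol = character(),
                           entity2 = character(), entity2_symbol = character(),
                           negation = "POSITIVE", voice = "ACTIVE",
                           verb = "", re_type = "",
                           cell = NA_character_, drug = NA_character_,
                           disease = NA_character_, organism = NA_character_,
                           origin = "verb_based") {
  n <- length(pmid)
  df <- data.frame(
    pmid = as.character(pmid),
    sentence_id = as.integer(sentence_id),
    entity1 = as.character(entity1),
    entity1_symbol = tolower(as.character(entity1_symbol)),
    entity2 = as.character(entity2),
    entity2_symbol = tolower(as.character(entity2_symbol)),
    negation = rep_len(as.character(negation), n),
    voice = rep_len(as.character(voice), n),
    verb = rep_len(as.character(verb), n),
    re_type = rep_len(as.character(re_type), n),
    cell = rep_len(as.character(cell), n),
    drug = rep_len(as.character(drug), n),
    disease = rep_len(as.character(disease), n),
    organism = rep_len(as.character(organism), n),
    origin = rep_len(as.character(origin), n),
    stringsAsFactors = FALSE
  )
  validate_relation_table(as_relation_table(df))
}

as_relation_table <- function(df) {
  class(df) <- unique(c("relation_table", class(df)))
  df
}

validate_relation_table <- function(df) {
  stopifnot(is.data.frame(df), all(RELATION_COLUMNS %in% names(df)))
  if (nrow(df) > 0) {
    if (any(!df$negation %in% c("POSITIVE", "NEGATIVE")))
      stop("negation must be POSITIVE or NEGATIVE", call. = FALSE)
    if (any(!df$voice %in% c("ACTIVE", "PASSIVE")))
      stop("voice must be ACTIVE or PASSIVE", call. = FALSE)
    if (any(!df$origin %in% ORIGIN_LEVELS))
      stop("origin must be one of ", paste(ORIGIN_LEVELS, collapse = ", "),
           call. = FALSE)
    if (any(df$entity1_symbol == df$entity2_symbol))
      stop("entity1 and entity2 official symbols must differ", call. = FALSE)
    # re-normalize context cells: no empty strings, sets deduplicated
    for (s in CONTEXT_SLOTS) {
      df[[s]] <- vapply(df[[s]], function(cell)
        context_slot_to_cell(context_cell_to_slot(cell)), character(1),
        USE.NAMES = FALSE)
      df[[s]][df[[s]] == NODATA] <- NA_character_
    }
  }
  df
}

#' Extract the context tuple of one relation row
#'
#' @param relations a `relation_table`.
#' @param i row index.
#' @return a [context_tuple()].
#' @export
relation_context <- function(relations, i) {
  row <- relations[i, , drop = FALSE]
  context_tuple(
    cell = context_cell_to_slot(row$cell),
    drug = context_cell_to_slot(row$drug),
    disease = context_cell_to_slot(row$disease),
    organism = context_cell_to_slot(row$organism)
  )
}

#' Read a relation table file
#'
#' Reads the tab-separated relation-table dialect: the 14-column header
#' (`PMID`, `Sentence_ID`, entity surfaces and official symbols, `Negation`,
#' `Voice`, `Verb`, `Re_Type` and the four context columns), with the
#' literal cell `NoData` marking absent context elements and semicolons
#' separating multi-valued context sets. An optional trailing `Origin`
#' column is honoured; absent, rows are treated as verb-based.
#'
#' @param path file path.
#' @param strict if `TRUE`, a non-integer `Sentence_ID` is a parse error
#'   naming the offending row; if `FALSE` it becomes `NA` with a warning.
#' @return a `relation_table`; row order follows the file.
#' @export
read_relation_table <- function(path, strict = TRUE) {
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL,
                           fileEncoding = "UTF-8")
  missing <- setdiff(RELATION_HEADER, names(raw))
  if (length(missing) > 0)
    stop("relation table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  sid <- suppressWarnings(as.integer(raw$Sentence_ID))
  bad <- which(is.na(sid) & nzchar(raw$Sentence_ID))
  if (length(bad) > 0) {
    if (strict)
      stop("non-integer Sentence_ID at data row ", bad[1], ": '",
           raw$Sentence_ID[bad[1]], "'", call. = FALSE)
    warning("non-integer Sentence_ID coerced to NA at row(s) ",
            paste(bad, collapse = ", "), call. = FALSE)
  }
  origin <- if (ORIGIN_COLUMN %in% names(raw)) raw[[ORIGIN_COLUMN]]
            else rep("verb_based", nrow(raw))
  ctx <- lapply(c("CELL", "DRUG", "DISEASE", "ORGANISM"), function(col) {
    x <- raw[[col]]
    x[x == NODATA | !nzchar(x)] <- NA_character_
    x
  })
  relation_table(
    pmid = raw$PMID, sentence_id = sid,
    entity1 = raw$Entity1, entity1_symbol = raw$Entity1OfficialSymbol,
    entity2 = raw$Entity2, entity2_symbol = raw$Entity2OfficialSymbol,
    negation = raw$Negation, voice = raw$Voice,
    verb = raw$Verb, re_type = raw$Re_Type,
    cell = ctx[[1]], drug = ctx[[2]], disease = ctx[[3]], organism = ctx[[4]],
    origin = origin
  )
}

#' Write a relation table file
#'
#' Inverse of [read_relation_table()]: emits the same tab-separated dialect
#' with a stable column order, writing `NoData` literally for absent context
#' elements and appending the `Origin` column.
#'
#' @param relations a `relation_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_relation_table <- function(relations, path) {
  relations <- validate_relation_table(relations)
  out <- data.frame(
    relations$pmid, relations$sentence_id,
    relations$entity1, relations$entity1_symbol,
    relations$entity2, relations$entity2_symbol,
    relations$negation, relations$voice, relations$verb, relations$re_type,
    stringsAsFactors = FALSE
  )
  for (s in CONTEXT_SLOTS) {
    col <- relations[[s]]
    col[is.na(col)] <- NODATA
    out[[s]] <- col
  }
  out[[ORIGIN_COLUMN]] <- relations$origin
  names(out) <- c(RELATION_HEADER, ORIGIN_COLUMN)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map an entity surface form to its official symbol
#'
#' Official symbols fold the many aliases of a gene or context entity onto
#' one dictionary key. A dictionary hit returns the mapped symbol; a miss
#' falls back to the lowercased, whitespace-trimmed surface (so matching is
#' case-insensitive even without a dictionary).
#'
#' @param surface entity surface form (non-empty).
#' @param dictionary named character vector mapping lowercase surfaces to
#'   official symbols; may be empty.
#' @return the normalized official symbol.
#' @examples
#' normalize_symbol("hsf-1", c("hsf-1" = "nr5a1"))
#' normalize_symbol("WT1", character())
#' @export
normalize_symbol <- function(surface, dictionary = character()) {
  if (length(surface) != 1L || is.na(surface) || !nzchar(trimws(surface)))
    stop("surface must be a single non-empty string", call. = FALSE)
  key <- tolower(trimws(surface))
  hit <- dictionary[key]
  if (length(hit) == 1L && !is.na(hit)) unname(tolower(hit)) else key
}

#' Read a surface-to-symbol dictionary
#'
#' Two tab-separated columns, no header: surface form, official symbol.
#'
#' @param path file path.
#' @return named character vector (lowercase surface -> lowercase symbol).
#' @export
read_symbol_dictionary <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           fileEncoding = "UTF-8")
  if (ncol(raw) < 2) stop("dictionary needs two columns", call. = FALSE)
  stats::setNames(tolower(raw[[2]]), tolower(trimws(raw[[1]])))
}
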
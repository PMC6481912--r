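# A-B-C path construction (closed discovery). Given a fixed entity A and
# entity C, every relation containing A with partner B is joined to every
# relation containing B with partner C (undirected matching on official
# symbols). The co-occurrence model joins unconditionally; the context
# models join only when the context similarity of the two relations reaches
# the threshold. Paths are per relation-instance pair, so the same A-B-C
# triple appears once per supporting relation pair; deduplication happens
# at the B-entity level.

ABC_MODELS <- c("cooccurrence", "context", "context_assignment")

PATH_HEADER <- c("EntityA", "EntityB", "EntityC", "Similarity",
                 "AB_PMID", "AB_Sentence_ID",
                 "AB_CELL", "AB_DRUG", "AB_DISEASE", "AB_ORGANISM",
                 "BC_PMID", "BC_Sentence_ID",
                 "BC_CELL", "BC_DRUG", "BC_DISEASE", "BC_ORGANISM")

#' Build A-B-C paths between a fixed A and C
#'
#' @param relations a `relation_table`.
#' @param a,c official symbols of the fixed endpoints (case-insensitive);
#'   `a == c` is an error.
#' @param model `"cooccurrence"`, `"context"` or `"context_assignment"`.
#'   The context model first drops relations with no context element; the
#'   context-assignment model first applies [assign_contexts()] (idempotent,
#'   so pre-assigned input is fine).
#' @param threshold minimum context similarity for joining two relations
#'   (inclusive: a score equal to the threshold connects, so threshold 1
#'   means exact context matching). Ignored by the co-occurrence model.
#' @param vocabs named list of [hierarchy_vocab()] objects for the context
#'   models.
#' @param normalization passed to [context_similarity()].
#' @return an `abc_paths` data.frame, one row per supporting relation pair,
#'   ordered by (B symbol, A-B PMID, B-C PMID), with both context tuples
#'   and, for the context models, the similarity score.
#' @export
build_paths <- function(relations, a, c,
                        model = c("cooccurrence", "context",
                                  "context_assignment"),
                        threshold = 1, vocabs = list(),
                        normalization = "all") {
  model <- match.arg(model)
  relations <- validate_relation_table(relations)
  a <- tolower(a); c <- tolower(c)
  if (identical(a, c)) stop("A and C must differ", call. = FALSE)
  stopifnot(threshold >= 0, threshold <= 1)

  if (model == "context_assignment")
    relations <- assign_contexts(relations)
  if (model %in% c("context", "context_assignment")) {
    counts <- vapply(seq_len(nrow(relations)), function(i)
      element_count(relation_context(relations, i)), integer(1))
    if (model == "context")
      relations <- relations[counts > 0, , drop = FALSE]
  }

  partner_rows <- function(sym) {
    hit1 <- relations$entity1_symbol == sym
    hit2 <- relations$entity2_symbol == sym
    idx <- which(hit1 | hit2)
    partner <- ifelse(hit1[idx], relations$entity2_symbol[idx],
                      relations$entity1_symbol[idx])
    data.frame(row = idx, partner = partner, stringsAsFactors = FALSE)
  }
  ab <- partner_rows(a)
  ab <- ab[ab$partner != c, , drop = FALSE]
  bc <- partner_rows(c)
  bc <- bc[bc$partner != a, , drop = FALSE]

  out <- list()
  for (b in intersect(unique(ab$partner), unique(bc$partner))) {
    ab_rows <- ab$row[ab$partner == b]
    bc_rows <- bc$row[bc$partner == b]
    for (i in ab_rows) {
      ctx_ab <- relation_context(relations, i)
      for (j in bc_rows) {
        if (model == "cooccurrence") {
          sim <- NA_real_
        } else {
          sim <- context_similarity(ctx_ab, relation_context(relations, j),
                                    vocabs, normalization)
          if (sim < threshold) next
        }
        out[[length(out) + 1L]] <- data.frame(
          a = a, b = b, c = c, similarity = sim,
          ab_pmid = relations$pmid[i],
          ab_sentence_id = relations$sentence_id[i],
          ab_cell = relations$cell[i], ab_drug = relations$drug[i],
          ab_disease = relations$disease[i],
          ab_organism = relations$organism[i],
          bc_pmid = relations$pmid[j],
          bc_sentence_id = relations$sentence_id[j],
          bc_cell = relations$cell[j], bc_drug = relations$drug[j],
          bc_disease = relations$disease[j],
          bc_organism = relations$organism[j],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  paths <- if (length(out) == 0) empty_paths()
           else do.call(rbind, c(out, list(make.row.names = FALSE)))
  paths <- paths[order(paths$b, paths$ab_pmid, paths$bc_pmid), , drop = FALSE]
  rownames(paths) <- NULL
  class(paths) <- unique(c("abc_paths", class(paths)))
  paths
}

empty_paths <- function() {
  data.frame(a = character(), b = character(), c = character(),
             similarity = numeric(),
             ab_pmid = character(), ab_sentence_id = integer(),
             ab_cell = character(), ab_drug = character(),
             ab_disease = character(), ab_organism = character(),
             bc_pmid = character(), bc_sentence_id = integer(),
             bc_cell = character(), bc_drug = character(),
             bc_disease = character(), bc_organism = character(),
             stringsAsFactors = FALSE)
}

#' Deduplicate the B entities of a path set
#'
#' @param paths an `abc_paths` data.frame (or anything with a `b` column).
#' @return unique B symbols in first-appearance order.
#' @export
dedup_b_entities <- function(paths) {
  unique(as.character(paths$b))
}

#' Write an A-B-C path table
#'
#' Tab-separated mirror of the in-memory path set: path triple, similarity
#' (empty for the co-occurrence model) and both context tuples with
#' `NoData` written literally.
#'
#' @param paths an `abc_paths` data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_path_table <- function(paths, path) {
  out <- paths[, c("a", "b", "c", "similarity",
                   "ab_pmid", "ab_sentence_id",
                   "ab_cell", "ab_drug", "ab_disease", "ab_organism",
                   "bc_pmid", "bc_sentence_id",
                   "bc_cell", "bc_drug", "bc_disease", "bc_organism")]
  for (col in grep("_(cell|drug|disease|organism)$", names(out), value = TRUE))
    out[[col]][is.na(out[[col]])] <- NODATA
  out$similarity <- ifelse(is.na(out$similarity), "",
                           format(out$similarity, digits = 15))
  names(out) <- PATH_HEADER
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an A-B-C path table
#'
#' @param path file path written by [write_path_table()] (or hand-built in
#'   the same dialect).
#' @return an `abc_paths` data.frame.
#' @export
read_path_table <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL,
                           fileEncoding = "UTF-8")
  missing <- setdiff(PATH_HEADER, names(raw))
  if (length(missing) > 0)
    stop("path table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- data.frame(
    a = tolower(raw$EntityA), b = tolower(raw$EntityB),
    c = tolower(raw$EntityC),
    similarity = suppressWarnings(as.numeric(raw$Similarity)),
    ab_pmid = raw$AB_PMID,
    ab_sentence_id = as.integer(raw$AB_Sentence_ID),
    ab_cell = raw$AB_CELL, ab_drug = raw$AB_DRUG,
    ab_disease = raw$AB_DISEASE, ab_organism = raw$AB_ORGANISM,
    bc_pmid = raw$BC_PMID,
    bc_sentence_id = as.integer(raw$BC_Sentence_ID),
    bc_cell = raw$BC_CELL, bc_drug = raw$BC_DRUG,
    bc_disease = raw$BC_DISEASE, bc_organism = raw$BC_ORGANISM,
    stringsAsFactors = FALSE
  )
  for (col in grep("_(cell|drug|disease|organism)$", names(out), value = TRUE)) {
    x <- out[[col]]
    x[x == NODATA | !nzchar(x)] <- NA_character_
    out[[col]] <- normalize_context_cells(x)
  }
  class(out) <- unique(c("abc_paths", class(out)))
  out
}

normalize_context_cells <- function(x) {
  vapply(x, function(cell) {
    slot <- context_cell_to_slot(cell)
    if (is.null(slot)) NA_character_ else paste(slot, collapse = ";")
  }, character(1), USE.NAMES = FALSE)
}
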
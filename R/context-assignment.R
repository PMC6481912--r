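# Abstract-level context assignment: all entity relations extracted from
# the same abstract are taken to share the abstract's combined biological
# context -- the per-slot union of every context element extracted anywhere
# in that abstract. Relations that already carried contexts also receive
# the combined tuple, so that no single sentence's context dominates.

#' Assign the combined abstract context to every relation
#'
#' For each PMID, builds the combined context tuple as the per-slot union of
#' all non-`NoData` values across that PMID's rows, then stamps it onto all
#' of them. Rows that previously had no context at all switch their origin
#' to `"assigned"`. Abstracts with no extracted context anywhere are
#' returned unchanged. The operation is idempotent and never removes a
#' context value (per slot, output is a superset of input).
#'
#' @param relations a `relation_table`.
#' @return a `relation_table` with the same rows in the same order.
#' @export
assign_contexts <- function(relations) {
  relations <- validate_relation_table(relations)
  if (nrow(relations) == 0) return(relations)
  for (pmid in unique(relations$pmid)) {
    rows <- which(relations$pmid == pmid)
    combined <- lapply(CONTEXT_SLOTS, function(slot) {
      vals <- unlist(lapply(relations[[slot]][rows], context_cell_to_slot))
      if (length(vals) == 0) NULL else sort(unique(vals))
    })
    names(combined) <- CONTEXT_SLOTS
    if (all(vapply(combined, is.null, logical(1)))) next
    had_context <- vapply(rows, function(i)
      element_count(relation_context(relations, i)) > 0, logical(1))
    for (slot in CONTEXT_SLOTS)
      relations[[slot]][rows] <- context_slot_to_cell_na(combined[[slot]])
    relations$origin[rows[!had_context]] <- "assigned"
  }
  relations
}

context_slot_to_cell_na <- function(values) {
  if (is.null(values)) NA_character_ else paste(values, collapse = ";")
}
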
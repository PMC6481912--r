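# Biological context: the four-slot tuple (cell, drug, disease, organism).
# Internally a slot is NULL ("NoData") or a non-empty character vector of
# normalized hierarchy terms; in the tabular dialect sets are semicolon-joined
# and NoData is written literally.

CONTEXT_SLOTS <- c("cell", "drug", "disease", "organism")
NODATA <- "NoData"

#' Construct a biological context tuple
#'
#' A biological context is the set of conditions under which an entity
#' relation was observed, split into four independent element types:
#' cell, drug, disease and organism. Slots with no extracted element are
#' `NULL` (the `NoData` sentinel in the tabular dialect); populated slots
#' hold one or more normalized hierarchy terms.
#'
#' @param cell,drug,disease,organism `NULL` or a character vector of terms.
#'   Terms are normalized with [normalize_term()]; empty strings are dropped
#'   and a slot that ends up empty becomes `NULL`.
#' @return An object of class `context_tuple`: a named list with the four
#'   slots.
#' @examples
#' context_tuple(disease = "amyloidosis", organism = "transgenic mouse")
#' @export
context_tuple <- function(cell = NULL, drug = NULL, disease = NULL,
                          organism = NULL) {
  slots <- list(cell = cell, drug = drug, disease = disease,
                organism = organism)
  slots <- lapply(slots, function(x) {
    if (is.null(x) || length(x) == 0L) return(NULL)
    x <- normalize_term(as.character(x))
    x <- unique(x[nzchar(x) & x != tolower(NODATA)])
    if (length(x) == 0L) NULL else x
  })
  structure(slots, class = "context_tuple")
}

#' Normalize a context term for hierarchy lookup
#'
#' Lowercases and removes all whitespace, so that surface variants such as
#' `"transgenic mouse"` and `"Transgenic  Mouse"` map to the single key
#' `"transgenicmouse"` used in vocabulary files.
#'
#' @param x character vector of terms.
#' @return character vector of normalized terms.
#' @export
normalize_term <- function(x) {
  gsub("[[:space:]]+", "", tolower(x))
}

#' Number of populated context elements
#'
#' @param ctx a [context_tuple()].
#' @return integer in 0..4: the count of non-`NoData` slots.
#' @export
element_count <- function(ctx) {
  stopifnot(inherits(ctx, "context_tuple"))
  sum(!vapply(ctx, is.null, logical(1)))
}

#' @export
format.context_tuple <- function(x, ...) {
  vals <- vapply(CONTEXT_SLOTS, function(s) {
    if (is.null(x[[s]])) NODATA else paste(x[[s]], collapse = ";")
  }, character(1))
  paste0("<context ", paste(CONTEXT_SLOTS, vals, sep = "=", collapse = " "),
         ">")
}

#' @export
print.context_tuple <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# serialize one slot for the tabular dialect
context_slot_to_cell <- function(values) {
  if (is.null(values)) NODATA else paste(values, collapse = ";")
}

# parse one tabular cell into a slot (NULL for NoData / empties)
context_cell_to_slot <- function(cell) {
  if (is.na(cell) || !nzchar(cell) || cell == NODATA) return(NULL)
  vals <- strsplit(cell, ";", fixed = TRUE)[[1]]
  vals <- normalize_term(vals)
  vals <- unique(vals[nzchar(vals)])
  if (length(vals) == 0L) NULL else vals
}
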
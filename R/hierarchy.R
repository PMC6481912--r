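# Hierarchy vocabularies and context similarity.
#
# Each context element type has a vocabulary mapping terms to one or more
# dotted tree positions (MeSH tree-number style, e.g. C10.228.140.380;
# drugs follow DrugBank's taxonomy, organisms KEGG's). Distance between two
# terms is the edge-path length through the deepest common dotted prefix;
# terms whose positions share no top-level category are unrelated. Distance
# normalizes to a similarity through a per-type maximum distance, and the
# four per-element similarities aggregate into a cosine-style context
# similarity between two context tuples.

# per-type maximum hierarchy distances used to normalize Eq-style distances
MAX_DISTANCES <- c(cell = 30, drug = 14, disease = 26, organism = 12)

#' The unrelated-terms distance sentinel
#'
#' [tree_distance()] returns `UNRELATED` (`Inf`) when two terms share no
#' top-level hierarchy category; [element_similarity()] maps it to 0.
#' @export
UNRELATED <- Inf

#' Construct a hierarchy vocabulary
#'
#' @param positions named list mapping normalized terms to character vectors
#'   of dotted tree positions (a term may occupy several positions in a
#'   poly-hierarchy).
#' @param element_type one of `"cell"`, `"drug"`, `"disease"`,
#'   `"organism"`.
#' @param max_distance normalizing constant for [element_similarity()];
#'   defaults per element type to cell 30, drug 14, disease 26, organism 12.
#' @return an object of class `hierarchy_vocab`.
#' @export
hierarchy_vocab <- function(positions, element_type, max_distance = NULL) {
  element_type <- match.arg(element_type, CONTEXT_SLOTS)
  if (is.null(max_distance)) max_distance <- MAX_DISTANCES[[element_type]]
  stopifnot(max_distance > 0)
  if (length(positions) > 0) {
    names(positions) <- normalize_term(names(positions))
    bad <- !vapply(positions, function(p)
      length(p) >= 1 && all(valid_position(p)), logical(1))
    if (any(bad))
      stop("invalid tree position(s) for term(s): ",
           paste(names(positions)[bad], collapse = ", "), call. = FALSE)
  }
  structure(list(element_type = element_type,
                 positions = positions,
                 max_distance = max_distance),
            class = "hierarchy_vocab")
}

valid_position <- function(p) {
  grepl("^[A-Za-z0-9]+(\\.[A-Za-z0-9]+)*$", p)
}

#' @export
print.hierarchy_vocab <- function(x, ...) {
  cat(sprintf("<hierarchy_vocab %s: %d terms, max_distance %d>\n",
              x$element_type, length(x$positions),
              as.integer(x$max_distance)))
  invisible(x)
}

#' Load a hierarchy vocabulary from a flat file
#'
#' Two tab-separated columns, no header: term, dotted tree position; one
#' row per term-position pair (repeat the term for poly-hierarchy
#' positions). Terms are normalized with [normalize_term()].
#'
#' @param path file path.
#' @param element_type one of the four context element types.
#' @param max_distance optional override of the per-type default.
#' @return a [hierarchy_vocab()].
#' @export
load_hierarchy <- function(path, element_type, max_distance = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  positions <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !nzchar(trimws(parts[1])))
      stop("malformed hierarchy row at line ", i, ": '", lines[i], "'",
           call. = FALSE)
    pos <- trimws(parts[2])
    if (!valid_position(pos))
      stop("malformed tree position at line ", i, ": '", pos, "'",
           call. = FALSE)
    term <- normalize_term(parts[1])
    positions[[term]] <- c(positions[[term]], pos)
  }
  hierarchy_vocab(positions, element_type, max_distance)
}

#' Write a hierarchy vocabulary to a flat file
#'
#' @param vocab a [hierarchy_vocab()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hierarchy <- function(vocab, path) {
  terms <- names(vocab$positions)
  rows <- unlist(lapply(terms, function(tm)
    paste(tm, vocab$positions[[tm]], sep = "\t")))
  writeLines(rows %||% character(), path, useBytes = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

lookup_positions <- function(term, vocab) {
  p <- vocab$positions[[normalize_term(term)]]
  if (is.null(p))
    stop("term '", term, "' not found in ", vocab$element_type,
         " vocabulary", call. = FALSE)
  p
}

# edge-path length between two dotted positions through their deepest
# common prefix; Inf when the top-level categories differ
position_distance <- function(p1, p2) {
  s1 <- strsplit(p1, ".", fixed = TRUE)[[1]]
  s2 <- strsplit(p2, ".", fixed = TRUE)[[1]]
  n <- min(length(s1), length(s2))
  lcp <- 0L
  while (lcp < n && s1[lcp + 1L] == s2[lcp + 1L]) lcp <- lcp + 1L
  if (lcp == 0L) return(UNRELATED)
  (length(s1) - lcp) + (length(s2) - lcp)
}

#' Tree distance between two vocabulary terms
#'
#' The minimum, over all position pairs of the two terms, of the edge-path
#' length through the deepest common dotted prefix (tree segments as unit
#' steps). Identical positions give 0; positions in different top-level
#' categories give [UNRELATED] (`Inf`).
#'
#' @param term1,term2 terms present in `vocab`.
#' @param vocab a [hierarchy_vocab()].
#' @return non-negative integer distance, or `UNRELATED`.
#' @export
tree_distance <- function(term1, term2, vocab) {
  p1 <- lookup_positions(term1, vocab)
  p2 <- lookup_positions(term2, vocab)
  min(outer(p1, p2, Vectorize(position_distance)))
}

#' Per-element hierarchy similarity
#'
#' `1 - distance / max_distance`, clamped to `[0, 1]`; unrelated terms and
#' distances at or beyond the maximum score 0. Set-valued inputs score as
#' the maximum over all cross pairs, the most favorable reading of a
#' multi-valued slot.
#'
#' @param terms1,terms2 character vectors of terms (each treated as a set).
#' @param vocab a [hierarchy_vocab()].
#' @return similarity in `[0, 1]`.
#' @export
element_similarity <- function(terms1, terms2, vocab) {
  sims <- outer(terms1, terms2, Vectorize(function(a, b) {
    d <- tree_distance(a, b, vocab)
    if (!is.finite(d)) 0 else max(0, 1 - d / vocab$max_distance)
  }))
  max(sims)
}

#' Context similarity between two biological context tuples
#'
#' A cosine-style aggregate of the per-element similarities. The numerator
#' sums [element_similarity()] over the four slots where *both* tuples have
#' data; slots that are `NoData` on either side contribute nothing. The
#' denominator is `sqrt(n1 * n2)` where `n_i` is the number of populated
#' slots of tuple i (`normalization = "all"`, the default). With
#' `normalization = "shared"` only slots populated on both sides count
#' toward `n_i` — an alternative reading of excluding `NoData` elements
#' from the calculation; both readings agree on single-slot tuples. If
#' either tuple is empty the similarity is 0.
#'
#' @param ctx1,ctx2 [context_tuple()] objects.
#' @param vocabs named list of [hierarchy_vocab()] objects, keyed by element
#'   type; a vocabulary is required only for slots populated on both sides.
#' @param normalization `"all"` (default) or `"shared"`.
#' @return similarity in `[0, 1]`.
#' @examples
#' v <- hierarchy_vocab(list("alzheimer disease" = "C10.228.140.380.100"),
#'                      "disease")
#' ctx <- context_tuple(disease = "alzheimer disease")
#' context_similarity(ctx, ctx, list(disease = v))  # 1
#' @export
context_similarity <- function(ctx1, ctx2, vocabs,
                               normalization = c("all", "shared")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(ctx1, "context_tuple"), inherits(ctx2, "context_tuple"))
  shared <- CONTEXT_SLOTS[!vapply(CONTEXT_SLOTS, function(s)
    is.null(ctx1[[s]]) || is.null(ctx2[[s]]), logical(1))]
  if (normalization == "all") {
    n1 <- element_count(ctx1)
    n2 <- element_count(ctx2)
  } else {
    n1 <- n2 <- length(shared)
  }
  if (n1 == 0 || n2 == 0) return(0)
  num <- 0
  for (s in shared) {
    vocab <- vocabs[[s]]
    if (is.null(vocab))
      stop("no ", s, " vocabulary supplied but both contexts carry ", s,
           " elements", call. = FALSE)
    num <- num + element_similarity(ctx1[[s]], ctx2[[s]], vocab)
  }
  num / sqrt(n1 * n2)
}
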
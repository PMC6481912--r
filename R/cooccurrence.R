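# Co-occurrence relation extraction: the baseline assumption that two gene
# entities mentioned in one sentence stand in some relation. Context-type
# entities (cell/drug/disease/organism) never form relation endpoints.

#' Extract co-occurrence gene pairs from one sentence
#'
#' Emits one relation per unordered pair of distinct gene symbols mentioned
#' in the sentence. Duplicate mentions of the same symbol collapse before
#' pairing, so a sentence with k distinct gene symbols yields exactly
#' k*(k-1)/2 relations. Entity 1 of each pair is the earlier mention in the
#' sentence. Co-occurrence rows carry no verb (`verb = ""`,
#' `re_type = "COOCCUR"`), default `POSITIVE`/`ACTIVE` metadata, an
#' all-`NoData` context and `origin = "cooccurrence"`.
#'
#' @param sentence an [annotated_sentence()] with normalized entity symbols.
#' @return a `relation_table` (possibly with zero rows).
#' @examples
#' s <- annotated_sentence("1", 1, "aa and bb",
#'   entities = data.frame(start = c(0L, 7L), end = c(2L, 9L),
#'                         type = "gene", surface = c("aa", "bb"),
#'                         symbol = c("aa", "bb")))
#' extract_cooccurrence_pairs(s)
#' @export
extract_cooccurrence_pairs <- function(sentence) {
  stopifnot(inherits(sentence, "annotated_sentence"))
  genes <- sentence$entities[sentence$entities$type == "gene", , drop = FALSE]
  if (nrow(genes) > 0) {
    genes <- genes[order(genes$start), , drop = FALSE]
    genes <- genes[!duplicated(genes$symbol), , drop = FALSE]
  }
  k <- nrow(genes)
  if (k < 2) return(relation_table())
  idx <- utils::combn(k, 2)
  relation_table(
    pmid = rep(sentence$pmid, ncol(idx)),
    sentence_id = rep(sentence$sentence_id, ncol(idx)),
    entity1 = genes$surface[idx[1, ]],
    entity1_symbol = genes$symbol[idx[1, ]],
    entity2 = genes$surface[idx[2, ]],
    entity2_symbol = genes$symbol[idx[2, ]],
    negation = "POSITIVE", voice = "ACTIVE",
    verb = "", re_type = "COOCCUR",
    origin = "cooccurrence"
  )
}
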
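# Evaluation of extracted B entities against expert relevance labels, and
# threshold sweeps over the context-similarity gate.

#' Construct gold relevance labels
#'
#' @param relevant symbols judged relevant B entities.
#' @param universe the assumed-complete relevant set used as the recall
#'   denominator (e.g. all B entities validated under a reference model);
#'   defaults to `relevant`. `relevant` must be a subset of `universe`.
#' @return an object of class `gold_labels`.
#' @export
gold_labels <- function(relevant, universe = relevant) {
  relevant <- unique(tolower(relevant))
  universe <- unique(tolower(universe))
  if (!all(relevant %in% universe))
    stop("relevant symbols must be a subset of the universe", call. = FALSE)
  structure(list(relevant = relevant, universe = universe),
            class = "gold_labels")
}

#' Read gold relevance labels from file
#'
#' Two tab-separated columns, no header: symbol, `O` (relevant) or `X`
#' (irrelevant). The universe defaults to the relevant symbols; pass
#' `universe_path` (one symbol per line) to widen the recall denominator.
#'
#' @param path label file path.
#' @param universe_path optional universe file path.
#' @return a [gold_labels()] object.
#' @export
read_gold_labels <- function(path, universe_path = NULL) {
  raw <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           fileEncoding = "UTF-8")
  if (ncol(raw) < 2) stop("gold file needs two columns", call. = FALSE)
  marks <- trimws(raw[[2]])
  if (any(!marks %in% c("O", "X")))
    stop("gold labels must be O or X", call. = FALSE)
  relevant <- tolower(trimws(raw[[1]][marks == "O"]))
  universe <- if (is.null(universe_path)) relevant
              else tolower(trimws(readLines(universe_path)))
  universe <- universe[nzchar(universe)]
  gold_labels(relevant, unique(c(relevant, universe)))
}

#' Precision, recall and F-measure of extracted B entities
#'
#' Precision is the fraction of predicted symbols that are labelled
#' relevant (`NA` when nothing was predicted — an empty prediction has no
#' precision rather than a zero one). Recall divides by the size of the
#' gold universe. F is the harmonic mean, 0 when either component is 0 and
#' `NA` when either is `NA`.
#'
#' @param predicted ordered character vector of predicted B symbols
#'   (deduplicated internally).
#' @param gold a [gold_labels()] object.
#' @return list with `n_predicted`, `n_hit`, `precision`, `recall`,
#'   `f_measure`.
#' @export
evaluate_b_entities <- function(predicted, gold) {
  stopifnot(inherits(gold, "gold_labels"))
  predicted <- unique(tolower(predicted))
  n_hit <- length(intersect(predicted, gold$relevant))
  precision <- if (length(predicted) == 0) NA_real_
               else n_hit / length(predicted)
  recall <- if (length(gold$universe) == 0) NA_real_
            else n_hit / length(gold$universe)
  f <- if (is.na(precision) || is.na(recall)) NA_real_
       else if (precision + recall == 0) 0
       else 2 * precision * recall / (precision + recall)
  list(n_predicted = length(predicted), n_hit = n_hit,
       precision = precision, recall = recall, f_measure = f)
}

#' Sweep the context-similarity threshold
#'
#' Runs [build_paths()], [dedup_b_entities()] and [evaluate_b_entities()]
#' at each threshold. Path and B-entity counts are non-increasing in the
#' threshold (the similarity gate only ever removes connections).
#'
#' @param relations a `relation_table`.
#' @param a,c fixed endpoint symbols.
#' @param model ABC model name, as in [build_paths()].
#' @param thresholds numeric vector, sorted ascending.
#' @param vocabs named list of [hierarchy_vocab()] objects.
#' @param gold optional [gold_labels()]; without it the precision, recall
#'   and F columns are `NA`.
#' @param normalization passed to [context_similarity()].
#' @return data.frame with one row per threshold: `threshold`, `n_paths`,
#'   `n_b`, `precision`, `recall`, `f_measure`.
#' @export
threshold_sweep <- function(relations, a, c, model, thresholds,
                            vocabs = list(), gold = NULL,
                            normalization = "all") {
  stopifnot(!is.unsorted(thresholds))
  rows <- lapply(thresholds, function(th) {
    paths <- build_paths(relations, a, c, model, threshold = th,
                         vocabs = vocabs, normalization = normalization)
    b <- dedup_b_entities(paths)
    scores <- if (is.null(gold))
      list(precision = NA_real_, recall = NA_real_, f_measure = NA_real_)
    else evaluate_b_entities(b, gold)
    data.frame(threshold = th, n_paths = nrow(paths), n_b = length(b),
               precision = scores$precision, recall = scores$recall,
               f_measure = scores$f_measure)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
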
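# Synthetic fixtures with known ground truth: random hierarchy
# vocabularies and template-based annotated corpora with planted A-B-C
# chains of controllable context agreement. Everything is deterministic
# under a seed, so the full pipeline can be tested offline against the
# generator's own bookkeeping.

#' Generate a random hierarchy vocabulary
#'
#' Grows a random tree of dotted positions under one or more top-level
#' roots: starting from the roots, nodes are attached one at a time to a
#' uniformly chosen parent that still has spare child slots, until
#' `n_terms` terms exist. Every position's parent is also a term, the
#' maximum observed depth never exceeds `depth` (root = depth 0) and no
#' node has more than `branching` children. Terms are named
#' `<type>term001`, `<type>term002`, ... in creation order.
#'
#' @param element_type one of the four context element types.
#' @param n_terms number of terms (including the roots).
#' @param branching maximum children per node (>= 2).
#' @param depth maximum tree depth below a root (>= 2).
#' @param roots character vector of top-level category codes; terms under
#'   different roots are unrelated.
#' @param seed optional integer seed; the same seed yields an identical
#'   vocabulary.
#' @param max_distance optional override of the per-type default.
#' @return a [hierarchy_vocab()].
#' @export
simulate_hierarchy <- function(element_type, n_terms, branching = 3,
                               depth = 4, roots = "X", seed = NULL,
                               max_distance = NULL) {
  stopifnot(branching >= 2, depth >= 2, length(roots) >= 1,
            n_terms >= length(roots))
  capacity <- length(roots) * sum(branching^(0:depth))
  if (n_terms > capacity)
    stop("n_terms (", n_terms, ") exceeds tree capacity (", capacity, ")",
         call. = FALSE)
  build <- function() {
    pos <- roots
    node_depth <- rep(0L, length(roots))
    n_children <- rep(0L, length(roots))
    while (length(pos) < n_terms) {
      eligible <- which(node_depth < depth & n_children < branching)
      parent <- if (length(eligible) == 1L) eligible
                else eligible[sample.int(length(eligible), 1L)]
      n_children[parent] <- n_children[parent] + 1L
      pos <- c(pos, paste(pos[parent], n_children[parent], sep = "."))
      node_depth <- c(node_depth, node_depth[parent] + 1L)
      n_children <- c(n_children, 0L)
    }
    terms <- sprintf("%sterm%03d", gsub("[^a-z]", "", tolower(element_type)),
                     seq_along(pos))
    hierarchy_vocab(stats::setNames(as.list(pos), terms), element_type,
                    max_distance)
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Generate a synthetic annotated corpus with planted A-B-C chains
#'
#' Each planted chain `(a, b, c, matched)` yields an A-B sentence and a B-C
#' sentence, each in its own abstract. Matched chains place one identical
#' disease term inside a generated prepositional clause of both sentences,
#' so their relations agree perfectly in context; mismatched chains draw
#' their two terms from unrelated top-level hierarchy categories, so their
#' context similarity is 0. A `context_rate` fraction of the non-planted
#' filler sentences carry decoy disease contexts; decoy gene symbols are
#' disjoint from all chain endpoints, so fillers never create A-B-C paths.
#' Optionally, a `contaminate` fraction of the matched chains get a
#' drug-context decoy sentence planted into their A-B abstract: per-sentence
#' extraction is unaffected, but abstract-level context assignment widens
#' the A-B tuple and disconnects the chain — the known failure mode of the
#' context-assignment model.
#'
#' @param chains data.frame with columns `a`, `b`, `c` (symbols) and
#'   `matched` (logical).
#' @param n_abstracts total number of abstracts; must exceed twice the
#'   number of chains so fillers exist.
#' @param context_rate fraction of filler sentences carrying a decoy
#'   context, in `[0, 1]`.
#' @param contaminate fraction of matched chains whose A-B abstract gets a
#'   drug-context decoy sentence, in `[0, 1]`.
#' @param n_genes size of the decoy gene pool.
#' @param seed optional integer seed.
#' @return list with elements `sentences` (annotated sentences), `vocabs`
#'   (named list with `disease` and `drug` vocabularies), `chains` (the
#'   input plus planted term and abstract bookkeeping), `truth` (the B
#'   entities surviving each model at threshold 1) and `gold`
#'   ([gold_labels()]: matched B entities over all planted B entities).
#' @export
simulate_corpus <- function(chains, n_abstracts = 200, context_rate = 0.3,
                            contaminate = 0, n_genes = 40, seed = NULL) {
  chains <- as.data.frame(chains, stringsAsFactors = FALSE)
  stopifnot(all(c("a", "b", "c", "matched") %in% names(chains)),
            context_rate >= 0, context_rate <= 1,
            contaminate >= 0, contaminate <= 1)
  chains$a <- tolower(chains$a)
  chains$b <- tolower(chains$b)
  chains$c <- tolower(chains$c)
  n_chains <- nrow(chains)
  if (n_abstracts <= 2 * n_chains)
    stop("n_abstracts must exceed twice the number of chains", call. = FALSE)
  build <- function() {
    disease_vocab <- simulate_hierarchy("disease", n_terms = 30,
                                        branching = 3, depth = 3,
                                        roots = c("C10", "C18"))
    drug_vocab <- simulate_hierarchy("drug", n_terms = 10, branching = 3,
                                     depth = 3, roots = "D02")
    dpos <- unlist(lapply(names(disease_vocab$positions), function(tm)
      disease_vocab$positions[[tm]][1]))
    root1 <- names(disease_vocab$positions)[startsWith(dpos, "C10")]
    root2 <- names(disease_vocab$positions)[startsWith(dpos, "C18")]
    drug_terms <- names(drug_vocab$positions)

    chains$ab_term <- sample(root1, n_chains, replace = TRUE)
    chains$bc_term <- ifelse(chains$matched, chains$ab_term,
                             sample(root2, n_chains, replace = TRUE))
    chains$ab_abstract <- sprintf("SYN%05d", seq_len(n_chains))
    chains$bc_abstract <- sprintf("SYN%05d", n_chains + seq_len(n_chains))
    contaminated <- chains$matched &
      (stats::runif(n_chains) < contaminate)
    chains$contaminated <- contaminated

    sentences <- list()
    add <- function(s) sentences[[length(sentences) + 1L]] <<- s
    for (k in seq_len(n_chains)) {
      add(planted_sentence(chains$ab_abstract[k], 1L,
                           chains$a[k], chains$b[k],
                           term = chains$ab_term[k], term_type = "disease"))
      add(planted_sentence(chains$bc_abstract[k], 1L,
                           chains$b[k], chains$c[k],
                           term = chains$bc_term[k], term_type = "disease"))
    }
    decoy_genes <- setdiff(sprintf("gene%03d", seq_len(n_genes)),
                           unlist(chains[c("a", "b", "c")]))
    for (k in which(contaminated)) {
      pair <- sample(decoy_genes, 2L)
      add(planted_sentence(chains$ab_abstract[k], 2L, pair[1], pair[2],
                           term = sample(drug_terms, 1L),
                           term_type = "drug"))
    }
    filler_ids <- sprintf("SYN%05d", (2 * n_chains + 1):n_abstracts)
    for (id in filler_ids) {
      for (sid in seq_len(sample(1:3, 1L))) {
        pair <- sample(decoy_genes, 2L)
        term <- if (stats::runif(1) < context_rate)
          sample(c(root1, root2), 1L) else NULL
        add(planted_sentence(id, sid, pair[1], pair[2],
                             term = term, term_type = "disease"))
      }
    }

    b_all <- unique(chains$b)
    b_context <- unique(chains$b[chains$matched])
    b_assign <- unique(chains$b[chains$matched & !chains$contaminated])
    list(
      sentences = sentences,
      vocabs = list(disease = disease_vocab, drug = drug_vocab),
      chains = chains,
      truth = list(cooccurrence = b_all, context = b_context,
                   context_assignment = b_assign),
      gold = gold_labels(relevant = b_context, universe = b_all)
    )
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

# one template sentence: "<G1> modulates <G2>[ in <term>]." with the
# context term (if any) inside a recorded prepositional clause span
planted_sentence <- function(pmid, sentence_id, g1, g2, term = NULL,
                             term_type = "disease") {
  s1 <- toupper(g1)
  s2 <- toupper(g2)
  head_txt <- paste0(s1, " modulates ", s2)
  ents <- rbind(
    data.frame(start = 0L, end = nchar(s1), type = "gene", surface = s1,
               symbol = g1, stringsAsFactors = FALSE),
    data.frame(start = nchar(s1) + 11L, end = nchar(head_txt), type = "gene",
               surface = s2, symbol = g2, stringsAsFactors = FALSE)
  )
  if (is.null(term)) {
    return(annotated_sentence(pmid, sentence_id, paste0(head_txt, "."),
                              entities = ents))
  }
  text <- paste0(head_txt, " in ", term, ".")
  term_start <- nchar(head_txt) + 4L
  ents <- rbind(ents, data.frame(
    start = term_start, end = term_start + nchar(term), type = term_type,
    surface = term, symbol = term, stringsAsFactors = FALSE))
  clauses <- data.frame(start = nchar(head_txt) + 1L,
                        end = nchar(text) - 1L,
                        kind = "prepositional", stringsAsFactors = FALSE)
  annotated_sentence(pmid, sentence_id, text, entities = ents,
                     clauses = clauses)
}
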
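# Independent oracles and fixture builders used across the suite. The
# oracles deliberately re-derive results by brute force (graph BFS, plain
# loops, exhaustive enumeration) so they share no code path with the
# implementation they check.

# --- brute-force tree distances: BFS over the explicit position graph ----

bf_position_graph <- function(vocab) {
  all_pos <- unique(unlist(vocab$positions))
  nodes <- unique(unlist(lapply(all_pos, function(p) {
    segs <- strsplit(p, ".", fixed = TRUE)[[1]]
    vapply(seq_along(segs), function(k)
      paste(segs[1:k], collapse = "."), character(1))
  })))
  parent_of <- function(p) sub("\\.[^.]+$", "", p)
  parents <- vapply(nodes, parent_of, character(1))
  adj <- lapply(nodes, function(p) {
    nb <- character()
    if (grepl(".", p, fixed = TRUE)) nb <- parent_of(p)
    unique(c(nb, nodes[grepl(".", nodes, fixed = TRUE) & parents == p]))
  })
  names(adj) <- nodes
  adj
}

bf_bfs <- function(adj, src) {
  nodes <- names(adj)
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  dist[src] <- 0
  queue <- src
  while (length(queue) > 0) {
    cur <- queue[1]; queue <- queue[-1]
    for (nb in adj[[cur]]) {
      if (dist[nb] > dist[cur] + 1) {
        dist[nb] <- dist[cur] + 1
        queue <- c(queue, nb)
      }
    }
  }
  dist
}

bf_tree_distance <- function(term1, term2, vocab) {
  adj <- bf_position_graph(vocab)
  p1 <- vocab$positions[[abcontext::normalize_term(term1)]]
  p2 <- vocab$positions[[abcontext::normalize_term(term2)]]
  min(unlist(lapply(p1, function(x) bf_bfs(adj, x)[p2])))
}

# all pairwise term distances of a vocabulary, BFS once per position
bf_distance_table <- function(vocab) {
  adj <- bf_position_graph(vocab)
  terms <- names(vocab$positions)
  pos_dist <- lapply(unique(unlist(vocab$positions)),
                     function(p) bf_bfs(adj, p))
  names(pos_dist) <- unique(unlist(vocab$positions))
  m <- matrix(Inf, length(terms), length(terms),
              dimnames = list(terms, terms))
  for (t1 in terms) for (t2 in terms) {
    m[t1, t2] <- min(unlist(lapply(vocab$positions[[t1]], function(p)
      pos_dist[[p]][vocab$positions[[t2]]])))
  }
  m
}

# --- brute-force context similarity over precomputed distance tables -----

bf_context_similarity <- function(ctx1, ctx2, vocabs, tables) {
  slots <- c("cell", "drug", "disease", "organism")
  n1 <- sum(!sapply(ctx1[slots], is.null))
  n2 <- sum(!sapply(ctx2[slots], is.null))
  if (n1 == 0 || n2 == 0) return(0)
  total <- 0
  for (s in slots) {
    if (is.null(ctx1[[s]]) || is.null(ctx2[[s]])) next
    best <- 0
    for (a in ctx1[[s]]) for (b in ctx2[[s]]) {
      d <- tables[[s]][a, b]
      sim <- if (is.infinite(d)) 0
             else max(0, 1 - d / vocabs[[s]]$max_distance)
      best <- max(best, sim)
    }
    total <- total + best
  }
  total / sqrt(n1 * n2)
}

# --- toy vocabularies -------------------------------------------------------

fig_disease_vocab <- function() {
  load_hierarchy(abc_example("mesh_disease_toy.tsv"), "disease")
}

toy_vocabs <- function() {
  list(
    cell = load_hierarchy(abc_example("mesh_cell_toy.tsv"), "cell"),
    drug = load_hierarchy(abc_example("drugbank_drug_toy.tsv"), "drug"),
    disease = fig_disease_vocab(),
    organism = load_hierarchy(abc_example("kegg_organism_toy.tsv"), "organism")
  )
}

# all context tuples over: per slot NoData, one singleton, or one pair
enumerate_tuples <- function(vocabs) {
  opts <- lapply(vocabs, function(v) {
    terms <- names(v$positions)
    list(NULL, terms[1], terms[2:3])
  })
  grid <- expand.grid(i1 = 1:3, i2 = 1:3, i3 = 1:3, i4 = 1:3)
  lapply(seq_len(nrow(grid)), function(r) {
    context_tuple(cell = opts$cell[[grid$i1[r]]],
                  drug = opts$drug[[grid$i2[r]]],
                  disease = opts$disease[[grid$i3[r]]],
                  organism = opts$organism[[grid$i4[r]]])
  })
}

# --- randomized relation records for round-trip checks ----------------------

random_relations <- function(n, seed) {
  withr::with_seed(seed, {
    syms <- sprintf("g%02d", 1:20)
    e1 <- sample(syms, n, replace = TRUE)
    e2 <- vapply(e1, function(s) sample(setdiff(syms, s), 1), character(1))
    ctx_col <- function() sample(c(NA, "termx", "termx;termy"), n,
                                 replace = TRUE)
    relation_table(
      pmid = sample(sprintf("PM%03d", 1:8), n, replace = TRUE),
      sentence_id = sample(1:9, n, replace = TRUE),
      entity1 = toupper(e1), entity1_symbol = e1,
      entity2 = toupper(e2), entity2_symbol = e2,
      negation = sample(c("POSITIVE", "NEGATIVE"), n, replace = TRUE),
      voice = sample(c("ACTIVE", "PASSIVE"), n, replace = TRUE),
      verb = sample(c("affect", "inhibit", ""), n, replace = TRUE),
      re_type = "TEST",
      cell = ctx_col(), drug = ctx_col(), disease = ctx_col(),
      organism = ctx_col(),
      origin = sample(c("verb_based", "cooccurrence"), n, replace = TRUE)
    )
  })
}

# sentence with the given gene mentions, in order, symbols possibly repeated
gene_sentence <- function(symbols) {
  if (length(symbols) == 0)
    return(annotated_sentence("PMX", 1L, "No genes here."))
  surfaces <- toupper(symbols)
  text <- paste(surfaces, collapse = " and ")
  starts <- integer(length(surfaces))
  off <- 0L
  for (i in seq_along(surfaces)) {
    starts[i] <- off
    off <- off + nchar(surfaces[i]) + 5L
  }
  annotated_sentence("PMX", 1L, text, entities = data.frame(
    start = starts, end = starts + nchar(surfaces), type = "gene",
    surface = surfaces, symbol = symbols, stringsAsFactors = FALSE))
}
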
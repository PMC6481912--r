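test_that("generated hierarchies respect shape, capacity and determinism", {
  v <- simulate_hierarchy("disease", n_terms = 7, branching = 2, depth = 2,
                          seed = 1)
  pos <- unlist(v$positions)
  expect_equal(length(pos), 7)
  # all positions come from the enumerable branching-2 depth-2 universe
  universe <- c("X", "X.1", "X.2",
                paste0("X.1.", 1:2), paste0("X.2.", 1:2))
  expect_true(all(pos %in% universe))
  # parent of every position is also a term
  parents <- sub("\\.[^.]+$", "", pos[grepl(".", pos, fixed = TRUE)])
  expect_true(all(parents %in% pos))
  expect_error(simulate_hierarchy("disease", n_terms = 100, branching = 2,
                                  depth = 2), "capacity")
  # byte-identical output for one seed
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_hierarchy(simulate_hierarchy("drug", 9, seed = 77), f1)
  write_hierarchy(simulate_hierarchy("drug", 9, seed = 77), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(
    simulate_hierarchy("drug", 9, seed = 78)$positions,
    simulate_hierarchy("drug", 9, seed = 77)$positions))
})

test_that("pairwise distances in a generated tree stay within 2*depth", {
  depth <- 3
  v <- simulate_hierarchy("cell", n_terms = 20, branching = 3,
                          depth = depth, seed = 5)
  terms <- names(v$positions)
  for (t1 in terms) for (t2 in terms) {
    d <- tree_distance(t1, t2, v)
    expect_lte(d, 2 * depth)
    expect_equal(d, bf_tree_distance(t1, t2, v))
  }
})

test_that("matched chains carry one shared clause-embedded context term", {
  chains <- data.frame(a = "apoe", b = c("x1", "x2"), c = "mapt",
                       matched = c(TRUE, FALSE))
  sim <- simulate_corpus(chains, n_abstracts = 10, context_rate = 0,
                         seed = 3)
  ch <- sim$chains
  expect_equal(ch$ab_term[1], ch$bc_term[1])
  expect_false(ch$ab_term[2] == ch$bc_term[2])
  # mismatched terms sit in unrelated top-level categories
  expect_identical(tree_distance(ch$ab_term[2], ch$bc_term[2],
                                 sim$vocabs$disease), UNRELATED)
  # every planted context term is inside a recorded clause span
  for (s in sim$sentences) {
    ctx_ents <- s$entities[s$entities$type != "gene", , drop = FALSE]
    if (nrow(ctx_ents) == 0) next
    expect_true(all(vapply(seq_len(nrow(ctx_ents)), function(i)
      any(ctx_ents$start[i] >= s$clauses$start &
            ctx_ents$end[i] <= s$clauses$end), logical(1))))
  }
})

test_that("all-matched chains are fully recovered; all-mismatched give none", {
  base <- data.frame(a = "aa", b = sprintf("b%d", 1:6), c = "cc")
  for (flag in c(TRUE, FALSE)) {
    chains <- transform(base, matched = flag)
    sim <- simulate_corpus(chains, n_abstracts = 30, context_rate = 0.5,
                           seed = 13)
    rel <- extract_relations(sim$sentences)
    b_ctx <- dedup_b_entities(
      build_paths(rel, "aa", "cc", "context", 1, vocabs = sim$vocabs))
    b_co <- dedup_b_entities(
      build_paths(rel, "aa", "cc", "cooccurrence"))
    expect_setequal(b_co, chains$b)
    if (flag) expect_setequal(b_ctx, chains$b) else
      expect_equal(b_ctx, character())
  }
})

test_that("co-occurrence precision equals the planted relevant fraction", {
  chains <- data.frame(a = "aa", b = sprintf("b%02d", 1:10), c = "cc",
                       matched = rep(c(TRUE, FALSE), 5))
  sim <- simulate_corpus(chains, n_abstracts = 50, context_rate = 0.3,
                         seed = 29)
  rel <- extract_relations(sim$sentences)
  b <- dedup_b_entities(build_paths(rel, "aa", "cc", "cooccurrence"))
  res <- evaluate_b_entities(b, sim$gold)
  # analytic expectation: relevant fraction of planted B entities
  expect_equal(res$precision, mean(chains$matched))
  expect_equal(res$recall, length(unique(chains$b[chains$matched])) /
                 length(unique(chains$b)))
})

test_that("contamination disconnects assigned chains but not context ones", {
  chains <- data.frame(a = "aa", b = sprintf("b%d", 1:10), c = "cc",
                       matched = TRUE)
  sim <- simulate_corpus(chains, n_abstracts = 30, context_rate = 0,
                         contaminate = 0.6, seed = 37)
  expect_true(any(sim$chains$contaminated))
  rel <- extract_relations(sim$sentences)
  b_ctx <- dedup_b_entities(
    build_paths(rel, "aa", "cc", "context", 1, vocabs = sim$vocabs))
  b_asg <- dedup_b_entities(
    build_paths(rel, "aa", "cc", "context_assignment", 1,
                vocabs = sim$vocabs))
  expect_setequal(b_ctx, sim$truth$context)
  expect_setequal(b_asg, sim$truth$context_assignment)
  expect_lt(length(b_asg), length(b_ctx))
})

test_that("the whole generator is deterministic per seed", {
  chains <- data.frame(a = "aa", b = c("b1", "b2"), c = "cc",
                       matched = c(TRUE, FALSE))
  s1 <- simulate_corpus(chains, n_abstracts = 12, context_rate = 0.5,
                        contaminate = 0.5, seed = 101)
  s2 <- simulate_corpus(chains, n_abstracts = 12, context_rate = 0.5,
                        contaminate = 0.5, seed = 101)
  expect_identical(s1, s2)
})
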
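vocabs <- toy_vocabs()
disease <- vocabs$disease

test_that("hierarchy files load with per-type default maximum distances", {
  expect_equal(disease$max_distance, 26)
  expect_equal(vocabs$cell$max_distance, 30)
  expect_equal(vocabs$drug$max_distance, 14)
  expect_equal(vocabs$organism$max_distance, 12)
  expect_true("alzheimerdisease" %in% names(disease$positions))
  over <- load_hierarchy(abc_example("mesh_disease_toy.tsv"), "disease",
                         max_distance = 10)
  expect_equal(over$max_distance, 10)
})

test_that("malformed hierarchy rows report their line number", {
  path <- withr::local_tempfile()
  writeLines(c("ok\tC10.1", "bad row without tab", "also ok\tC10.2"), path)
  expect_error(load_hierarchy(path, "disease"), "line 2")
  writeLines(c("ok\tC10.1", "bad\tC10..5"), path)
  expect_error(load_hierarchy(path, "disease"), "line 2")
})

test_that("an empty vocabulary loads but any lookup errors", {
  path <- withr::local_tempfile()
  writeLines(character(), path)
  v <- load_hierarchy(path, "drug")
  expect_equal(length(v$positions), 0)
  expect_error(tree_distance("x", "x", v), "not found")
})

test_that("write/load round-trips a generated random hierarchy", {
  v <- simulate_hierarchy("organism", n_terms = 15, branching = 3,
                          depth = 4, seed = 3)
  path <- withr::local_tempfile()
  write_hierarchy(v, path)
  back <- load_hierarchy(path, "organism")
  expect_equal(back$positions[order(names(back$positions))],
               v$positions[order(names(v$positions))])
})

test_that("tree distances match the BFS oracle on the toy tree", {
  expect_equal(tree_distance("dementia", "dementia", disease), 0)
  # siblings through their parent
  expect_equal(tree_distance("alzheimer disease", "huntington disease",
                             disease), 2)
  expect_equal(bf_tree_distance("alzheimer disease", "huntington disease",
                                disease), 2)
  # parent-child
  expect_equal(tree_distance("dementia", "alzheimer disease", disease), 1)
  # across top-level categories: unrelated
  expect_identical(tree_distance("alzheimer disease", "amyloidosis",
                                 disease), UNRELATED)
  # all pairs agree with the oracle
  tab <- bf_distance_table(disease)
  for (t1 in names(disease$positions))
    for (t2 in names(disease$positions))
      expect_equal(tree_distance(t1, t2, disease), tab[t1, t2])
})

test_that("element similarity normalizes, clamps and maxes over sets", {
  expect_equal(element_similarity("dementia", "dementia", disease), 1)
  expect_equal(element_similarity("alzheimer disease", "huntington disease",
                                  disease), 1 - 2 / 26)
  expect_equal(element_similarity("alzheimer disease", "amyloidosis",
                                  disease), 0)
  # distance at or past max_distance clamps to zero, not negative
  tight <- load_hierarchy(abc_example("mesh_disease_toy.tsv"), "disease",
                          max_distance = 2)
  expect_equal(element_similarity("alzheimer disease", "huntington disease",
                                  tight), 0)
  expect_gte(element_similarity("parkinson disease", "dementia", tight), 0)
  # set-valued: the most favorable cross pair wins
  expect_equal(
    element_similarity(c("amyloidosis", "dementia"), "alzheimer disease",
                       disease), 1 - 1 / 26)
})

test_that("a multi-position term takes its minimum distance", {
  v <- hierarchy_vocab(
    list(poly = c("C10.1.1.1.1", "C10.9"), other = "C10.9.1"),
    "disease")
  expect_equal(tree_distance("poly", "other", v), 1)
  expect_equal(bf_tree_distance("poly", "other", v), 1)
})

test_that("context similarity reproduces hand-derived mixed-count cases", {
  ctx_d <- context_tuple(disease = "dementia")
  ctx_do <- context_tuple(disease = "dementia", organism = "mouse")
  expect_equal(context_similarity(ctx_d, ctx_do, vocabs), 1 / sqrt(2))
  # slot present on one side only: numerator unaffected, n_i counts it
  ctx_o <- context_tuple(organism = "mouse")
  expect_equal(context_similarity(ctx_d, ctx_o, vocabs), 0)
  # "shared" normalization drops one-sided slots from the counts too
  expect_equal(context_similarity(ctx_d, ctx_do, vocabs,
                                  normalization = "shared"), 1)
  # empty tuple on either side scores 0
  expect_equal(context_similarity(context_tuple(), ctx_d, vocabs), 0)
  # unknown term raises a lookup error naming the term
  expect_error(
    context_similarity(context_tuple(disease = "nosuch"), ctx_d, vocabs),
    "nosuch")
})

test_that("similarity is symmetric, bounded and exhaustively oracle-equal", {
  tuples <- enumerate_tuples(vocabs)
  tables <- lapply(vocabs, bf_distance_table)
  n <- length(tuples)
  expect_equal(n, 81)
  sims <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- context_similarity(tuples[[i]], tuples[[j]], vocabs)
    sims[i, j] <- s
    expect_gte(s, 0)
    expect_lte(s, 1)
    expect_equal(s, bf_context_similarity(tuples[[i]], tuples[[j]],
                                          vocabs, tables))
  }
  expect_equal(sims, t(sims))
  # score 1 iff equal element counts and every shared slot is perfect
  for (i in seq_len(n))
    expect_equal(sims[i, i], if (element_count(tuples[[i]]) > 0) 1 else 0)
})
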
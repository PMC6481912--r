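rel_am <- read_relation_table(abc_example("apoe_mapt_relations_synthetic.tsv"))
vocabs <- toy_vocabs()

test_that("the APOE-MAPT relation set gives 19 exact-match paths", {
  p <- build_paths(rel_am, "APOE", "MAPT", model = "context",
                   threshold = 1, vocabs = vocabs)
  expect_equal(nrow(p), 19)
  expect_true(all(p$similarity == 1))
  # each path's A-B and B-C contexts are identical
  for (s in c("cell", "drug", "disease", "organism"))
    expect_identical(p[[paste0("ab_", s)]], p[[paste0("bc_", s)]])
  expect_setequal(dedup_b_entities(p),
                  c("ins", "c9orf72", "snca", "phgdh", "bche", "src",
                    "mcidas"))
  # path multiplicities per B entity as printed
  expect_equal(as.vector(table(p$b)[c("ins", "c9orf72", "snca", "phgdh",
                                      "bche", "src", "mcidas")]),
               c(3, 3, 5, 2, 2, 3, 1))
  # ordered by (b, ab_pmid, bc_pmid)
  expect_false(is.unsorted(p$b))
})

test_that("threshold 0 equals co-occurrence on context-bearing relations", {
  p0 <- build_paths(rel_am, "apoe", "mapt", "context", threshold = 0,
                    vocabs = vocabs)
  pco <- build_paths(rel_am, "apoe", "mapt", "cooccurrence")
  # every relation here bears context, so the sets coincide
  key <- function(p) paste(p$b, p$ab_pmid, p$bc_pmid)
  expect_setequal(key(p0), key(pco))
  # and context-model paths are always a subset of co-occurrence paths
  p1 <- build_paths(rel_am, "apoe", "mapt", "context", threshold = 1,
                    vocabs = vocabs)
  expect_true(all(key(p1) %in% key(pco)))
})

test_that("the context model drops context-free relations first", {
  rel <- read_relation_table(abc_example("hsf1_relations.tsv"))
  # nr5a1 links nphs1 (with context) and wt1 (without): under the context
  # model only the context-bearing relation survives, leaving no chain
  p <- build_paths(rel, "nphs1", "wt1", "context", threshold = 0,
                   vocabs = vocabs)
  expect_equal(nrow(p), 0)
  # co-occurrence still chains nphs1 -nr5a1- wt1
  pco <- build_paths(rel, "nphs1", "wt1", "cooccurrence")
  expect_equal(pco$b, "nr5a1")
})

test_that("raising the threshold never adds paths or B entities", {
  sim <- simulate_corpus(
    data.frame(a = "aa", b = sprintf("b%d", 1:8), c = "cc",
               matched = rep(c(TRUE, FALSE), 4)),
    n_abstracts = 40, context_rate = 0.6, seed = 17)
  rel <- extract_relations(sim$sentences)
  sweep <- threshold_sweep(rel, "aa", "cc", "context",
                           thresholds = seq(0, 1, by = 0.1),
                           vocabs = sim$vocabs)
  expect_true(all(diff(sweep$n_paths) <= 0))
  expect_true(all(diff(sweep$n_b) <= 0))
  # monotone similarity: perturbing one context to agree cannot lose paths
  assigned <- build_paths(rel, "aa", "cc", "context_assignment",
                          threshold = 1, vocabs = sim$vocabs)
  ctx <- build_paths(rel, "aa", "cc", "context", threshold = 1,
                     vocabs = sim$vocabs)
  expect_true(all(assigned$similarity >= 1))
  expect_true(all(ctx$similarity >= 1))
})

test_that("identical contexts make threshold-1 context = co-occurrence", {
  rel <- random_relations(30, seed = 9)
  for (s in c("cell", "drug", "disease", "organism"))
    rel[[s]] <- NA_character_
  rel$disease <- "dementia"
  a <- rel$entity1_symbol[1]
  partners <- c(rel$entity2_symbol[rel$entity1_symbol == a],
                rel$entity1_symbol[rel$entity2_symbol == a])
  c_sym <- setdiff(unique(c(rel$entity1_symbol, rel$entity2_symbol)),
                   c(a, partners))[1]
  expect_false(is.na(c_sym))  # deterministic under the fixed seed
  p_ctx <- build_paths(rel, a, c_sym, "context", threshold = 1,
                       vocabs = vocabs)
  p_co <- build_paths(rel, a, c_sym, "cooccurrence")
  expect_equal(paste(p_ctx$b, p_ctx$ab_pmid, p_ctx$bc_pmid),
               paste(p_co$b, p_co$ab_pmid, p_co$bc_pmid))
})

test_that("dedup keeps first appearance, is idempotent and set-faithful", {
  p <- read_path_table(abc_example("apoe_mapt_paths.tsv"))
  b <- dedup_b_entities(p)
  expect_equal(b, c("ins", "c9orf72", "snca", "phgdh", "bche", "src",
                    "mcidas"))
  expect_equal(dedup_b_entities(data.frame(b = b)), b)
  withr::with_seed(23, {
    for (rep in 1:10) {
      x <- sample(letters[1:6], 30, replace = TRUE)
      d <- dedup_b_entities(data.frame(b = x))
      expect_setequal(d, unique(x))       # set oracle
      expect_equal(d, x[!duplicated(x)])  # order stability
    }
  })
})

test_that("degenerate inputs are rejected or empty", {
  expect_error(build_paths(rel_am, "apoe", "APOE", "cooccurrence"),
               "must differ")
  p <- build_paths(rel_am, "nphs1", "nphs2", "cooccurrence")
  expect_equal(nrow(p), 0)
  expect_equal(dedup_b_entities(p), character())
})

test_that("path tables round-trip through the file dialect", {
  p <- build_paths(rel_am, "apoe", "mapt", "context", threshold = 1,
                   vocabs = vocabs)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_path_table(p, path)
  back <- read_path_table(path)
  expect_equal(as.data.frame(back), as.data.frame(p))
})
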
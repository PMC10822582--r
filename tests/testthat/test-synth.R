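test_that("generation is deterministic in the seed", {
  cfg <- fg_synth_config(n_docs = 6)
  c1 <- generate_corpus(cfg, seed = 5)
  c2 <- generate_corpus(cfg, seed = 5)
  expect_identical(c1, c2)
  c3 <- generate_corpus(cfg, seed = 6)
  expect_false(identical(lapply(c1, `[[`, "text"), lapply(c3, `[[`, "text")))
})

test_that("generated documents validate and bookkeeping matches parsing", {
  cfg <- fg_synth_config(n_docs = 12)
  corpus <- generate_corpus(cfg, seed = 2)
  expect_length(corpus, 12)
  sch <- fg_schema()
  for (doc in corpus) {
    expect_s3_class(doc, "fg_document")
    m <- doc$mentions
    # offsets point at the surfaces, assertions lie in the right vocabulary
    expect_identical(m$surface, substring(doc$text, m$start + 1L, m$end))
    for (i in seq_len(nrow(m))) {
      expect_true(m$assertion[i] %in% sch$assertions[[m$category[i]]])
    }
  }
  book <- attr(corpus, "bookkeeping")
  expect_s3_class(book, "fg_corpus_stats")
  counted <- corpus_stats(corpus)
  expect_identical(unclass(counted), unclass(book))
})

test_that("the minimal configuration yields one four-mention group", {
  cfg <- fg_synth_config(n_docs = 1, experiments_per_doc = 1,
                         groups_per_experiment = 1, p_multisentence = 0,
                         p_distractor = 0, p_unlinked = 0)
  corpus <- generate_corpus(cfg, seed = 1)
  doc <- corpus[[1]]
  expect_identical(nrow(doc$mentions), 4L)
  expect_identical(nrow(doc$links), 1L)
  expect_setequal(doc$mentions$category, fg_schema()$categories)
  expect_identical(nrow(fg_gold_pairs(doc)), 6L)
  # single sentence: the baseline is perfect here
  expect_equal(evaluate_linking("baseline", corpus)[["f1"]], 1)
})

test_that("groups of one experiment share the perturbing-action mention", {
  cfg <- fg_synth_config(n_docs = 10, experiments_per_doc = 1,
                         groups_per_experiment = 3, p_distractor = 0,
                         p_unlinked = 0)
  corpus <- generate_corpus(cfg, seed = 4)
  for (doc in corpus) {
    expect_identical(nrow(doc$links), 3L)
    expect_length(unique(doc$links$PerturbingAction), 1L)
    # each group has its own effect/phenotype/context members
    expect_length(unique(doc$links$Phenotype), 3L)
  }
})

test_that("p_unlinked leaves some mentions outside every group", {
  cfg <- fg_synth_config(n_docs = 40, p_unlinked = 0.5)
  corpus <- generate_corpus(cfg, seed = 8)
  s <- corpus_stats(corpus)
  expect_lt(s$n_linked_mentions, s$n_mentions)
  # unlinked mentions come from framing prose without a perturbation, so
  # they are Phenotype/Context mentions
  for (doc in corpus) {
    linked <- unique(unlist(doc$links[fg_schema()$categories],
                            use.names = FALSE))
    un <- doc$mentions[!doc$mentions$id %in% linked, , drop = FALSE]
    expect_true(all(un$category %in% c("Phenotype", "Context")))
  }
  none <- generate_corpus(fg_synth_config(n_docs = 10, p_unlinked = 0),
                          seed = 8)
  sn <- corpus_stats(none)
  expect_identical(sn$n_linked_mentions, sn$n_mentions)
})

test_that("assertion_skew concentrates mass on early vocabulary entries", {
  skew <- generate_corpus(fg_synth_config(n_docs = 60, assertion_skew = 2),
                          seed = 10)
  flat <- generate_corpus(fg_synth_config(n_docs = 60, assertion_skew = 0),
                          seed = 10)
  ps <- corpus_stats(skew)$per_assertion$Phenotype
  pf <- corpus_stats(flat)$per_assertion$Phenotype
  # share of the five most frequent vocabulary entries
  top_share <- function(x) sum(sort(x, decreasing = TRUE)[1:5]) / sum(x)
  expect_gt(top_share(ps), top_share(pf) + 0.2)
})

test_that("p_multisentence = 0 keeps every group inside one sentence", {
  cfg <- fg_synth_config(n_docs = 15, p_multisentence = 0)
  corpus <- generate_corpus(cfg, seed = 12)
  expect_equal(corpus_summary(corpus)$cross_sentence_group_fraction, 0)
  cfg2 <- fg_synth_config(n_docs = 15, p_multisentence = 1,
                          groups_per_experiment = 2:4)
  corpus2 <- generate_corpus(cfg2, seed = 12)
  expect_gt(corpus_summary(corpus2)$cross_sentence_group_fraction, 0)
})

test_that("generated documents survive a standoff XML roundtrip", {
  corpus <- generate_corpus(fg_synth_config(n_docs = 3), seed = 14)
  for (doc in corpus) {
    path <- withr::local_tempfile(fileext = ".xml")
    write_standoff_xml(doc, path)
    back <- read_standoff_xml(path)
    expect_identical(back$text, doc$text)
    expect_identical(back$mentions, doc$mentions)
    expect_identical(back$links, doc$links)
  }
})

test_that("default configuration is the released-corpus scale", {
  cfg <- fg_synth_config()
  expect_identical(cfg$n_docs, 800L)
  expect_identical(cfg$experiments_per_doc, 1:2)
  expect_identical(cfg$groups_per_experiment, 1:4)
})
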
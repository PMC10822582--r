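tiny_link_corpus <- function(n = 5, seed = 31) {
  generate_corpus(fg_synth_config(n_docs = n, experiments_per_doc = 1,
                                  groups_per_experiment = 1:2,
                                  p_distractor = 0.2),
                  seed = seed)
}

tiny_link_cfg <- function(...) {
  args <- utils::modifyList(list(d_model = 32L, n_layers = 1L,
                                 n_heads = 2L, max_len = 160L),
                            list(...))
  do.call(fg_linking_config, args)
}

test_that("enumerate_pairs in mode 'all' covers the upper triangle", {
  doc <- worked_example()
  tok <- tiny_tokenizer(doc$text)
  enc <- encode_bio(doc, tok)
  nt <- length(enc$token_ids)
  pairs <- enumerate_pairs(doc, enc, mode = "all", negative_cap = Inf)
  expect_equal(nrow(pairs), nt * (nt + 1) / 2)
  expect_true(all(pairs$i <= pairs$j))
  expect_true(all(pairs$link %in% 0:1) && all(pairs$same %in% 0:1))
  # a four-token document would have 10 pairs
  small <- fg_document("s", "Just four plain words.")
  enc_s <- encode_bio(small, tiny_tokenizer("Just four plain words."))
  n_s <- length(enc_s$token_ids)
  p_s <- enumerate_pairs(small, enc_s, mode = "all")
  expect_equal(nrow(p_s), n_s * (n_s + 1) / 2)
  expect_true(all(p_s$link == 0L))
})

test_that("negative_cap subsamples only link-negative pairs", {
  doc <- worked_example()
  enc <- encode_bio(doc, tiny_tokenizer(doc$text))
  full <- enumerate_pairs(doc, enc, mode = "all", negative_cap = Inf)
  set.seed(1)
  capped <- enumerate_pairs(doc, enc, mode = "all", negative_cap = 1)
  n_pos <- sum(full$link == 1L)
  expect_identical(sum(capped$link == 1L), n_pos)       # positives kept
  expect_identical(sum(capped$same == 1L), sum(full$same == 1L))
  expect_lte(sum(capped$link == 0L & capped$same == 0L), n_pos)
  expect_lt(nrow(capped), nrow(full))
})

test_that("mode 'tagged' pairs distinct mentions and matches the closure", {
  doc <- worked_example()
  enc <- encode_bio(doc, tiny_tokenizer(doc$text))
  pairs <- enumerate_pairs(doc, enc, mode = "tagged")
  toks <- fgie:::mention_token_sets(enc)
  mention_of <- integer(length(enc$token_ids))
  for (k in seq_along(toks)) mention_of[toks[[k]]] <- k
  expect_true(all(mention_of[pairs$i] != 0L))
  expect_true(all(mention_of[pairs$i] != mention_of[pairs$j]))
  # the link bit agrees with the gold pair closure at entity level
  gold <- fg_gold_pairs(doc)
  gk <- paste(pmin(gold$a, gold$b), pmax(gold$a, gold$b))
  ids <- enc$mention_words$id
  got <- paste(pmin(ids[mention_of[pairs$i]], ids[mention_of[pairs$j]]),
               pmax(ids[mention_of[pairs$i]], ids[mention_of[pairs$j]]))
  expect_identical(pairs$link == 1L, got %in% gk)
})

test_that("training reduces the pair loss and is seed-reproducible", {
  corpus <- tiny_link_corpus()
  m1 <- train_linker(corpus, tiny_link_cfg(epochs = 10L, seed = 5L))
  expect_s3_class(m1, "fg_linker")
  expect_lt(m1$history[10], m1$history[1])
  m2 <- train_linker(corpus, tiny_link_cfg(epochs = 10L, seed = 5L))
  expect_identical(m1$theta, m2$theta)
  expect_identical(m1$history, m2$history)
})

test_that("the ablated model (lambda = 0) trains", {
  corpus <- tiny_link_corpus(3)
  m <- train_linker(corpus, tiny_link_cfg(epochs = 3L, lambda = 0))
  expect_length(m$history, 3)
  expect_true(all(is.finite(m$history)))
})

test_that("predicted pairs are unordered, distinct and thresholded", {
  corpus <- tiny_link_corpus(4)
  model <- train_linker(corpus, tiny_link_cfg(epochs = 5L))
  doc <- corpus[[1]]
  pred <- predict_links(model, doc, threshold = 0)
  expect_identical(nrow(pred), nrow(candidate_pairs(doc)))
  expect_true(all(pred$a < pred$b))
  expect_true(all(pred$prob >= 0 & pred$prob <= 1))
  # raising the threshold can only shrink the set
  p5 <- predict_links(model, doc, threshold = 0.5)
  expect_lte(nrow(p5), nrow(pred))
  expect_true(all(paste(p5$a, p5$b) %in% paste(pred$a, pred$b)))
  # mean aggregation returns the same pair universe
  pm <- predict_links(model, doc, threshold = 0, aggregation = "mean")
  expect_identical(pm[c("a", "b")], pred[c("a", "b")])
  expect_false(identical(pm$prob, pred$prob))
})

test_that("zero-initialised heads predict probability one half everywhere", {
  corpus <- tiny_link_corpus(2)
  model <- train_linker(corpus, tiny_link_cfg(epochs = 1L, lr = 0))
  pr <- fg_linker_forward(model, 2:6, c(1L, 2L), c(3L, 4L))
  expect_equal(unname(pr[, "link"]), c(0.5, 0.5))
  # at threshold strictly above 0.5 nothing is predicted
  expect_identical(nrow(predict_links(model, corpus[[1]],
                                      threshold = 0.51)), 0L)
})

test_that("documents with fewer than two mentions yield no pairs", {
  corpus <- tiny_link_corpus(2)
  model <- train_linker(corpus, tiny_link_cfg(epochs = 1L))
  bare <- fg_document("bare", "Nothing is annotated here.")
  expect_identical(nrow(predict_links(model, bare)), 0L)
})

test_that("an overfit linker reproduces its training links", {
  corpus <- tiny_link_corpus(4, seed = 33)
  model <- train_linker(corpus, tiny_link_cfg(epochs = 120L, d_model = 48L,
                                              negative_cap = Inf))
  s <- evaluate_linking(model, corpus)
  expect_gt(s[["f1"]], 0.9)
})
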
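test_that("prf handles zero denominators and perfect scores", {
  expect_equal(unname(prf(0, 0, 0)), c(0, 0, 0, 0, 0, 0))
  expect_equal(prf(10, 0, 0)[["f1"]], 1)
  s <- prf(3, 1, 2)
  expect_equal(s[["precision"]], 3 / 4)
  expect_equal(s[["recall"]], 3 / 5)
  expect_equal(s[["f1"]], 2 * (3 / 4) * (3 / 5) / (3 / 4 + 3 / 5))
  expect_named(s, c("precision", "recall", "f1", "tp", "fp", "fn"))
})

test_that("tagging counts equal the marginal formulation on random data", {
  # independent oracle: with mismatched non-O pairs counting as both FP and
  # FN, the counts must satisfy fp = #non-O predictions - tp and
  # fn = #non-O golds - tp
  set.seed(11)
  labs <- c("O", "B-X", "I-X", "B-Y")
  for (rep in 1:1000) {
    n <- sample(1:12, 1)
    pred <- sample(labs, n, replace = TRUE)
    gold <- sample(labs, n, replace = TRUE)
    cnt <- fgie:::sequence_counts(pred, gold)
    tp <- sum(pred == gold & gold != "O")
    expect_identical(unname(cnt),
                     c(tp, sum(pred != "O") - tp, sum(gold != "O") - tp))
  }
})

test_that("tagging_prf over head lists adds a micro-average row", {
  pred <- list(a = c("B-X", "O", "B-Y"), b = c("O", "O", "B-Z"))
  gold <- list(a = c("B-X", "B-X", "B-X"), b = c("O", "O", "B-Z"))
  out <- tagging_prf(pred, gold)
  expect_identical(out$head, c("a", "b", "overall"))
  # head a: tp 1, fn 1, mismatch at position 3 -> fp 1 fn 1 more
  expect_equal(out[out$head == "a", c("tp", "fp", "fn")],
               data.frame(tp = 1, fp = 1, fn = 2, row.names = 1L))
  ov <- out[out$head == "overall", ]
  expect_equal(ov$tp, 2)
  expect_equal(ov$precision, 2 / 3)  # tp 2 of 3 non-O predictions
})

test_that("splits partition the corpus reproducibly", {
  sp <- make_splits(103, holdout_frac = 0.1, n_folds = 4, seed = 42)
  expect_length(sp$holdout, 10)
  expect_setequal(c(sp$holdout, sp$train), 1:103)
  expect_length(intersect(sp$holdout, sp$train), 0)
  expect_setequal(unlist(sp$folds), sp$train)
  sizes <- lengths(sp$folds)
  expect_lte(max(sizes) - min(sizes), 1)
  # pairwise disjoint
  expect_identical(sum(sizes), length(sp$train))
  expect_identical(sp, make_splits(103, holdout_frac = 0.1, n_folds = 4,
                                   seed = 42))
  expect_error(make_splits(4), "at least 5")
  # a list argument uses its length
  expect_length(make_splits(as.list(1:50), seed = 1)$holdout, 5)
})

test_that("worked-example baseline scores P=1/2, R=1, F1=2/3", {
  doc <- worked_example()
  expect_identical(nrow(candidate_pairs(doc)), 36L)
  bp <- baseline_pairs(doc)
  expect_identical(nrow(bp), 36L)  # one sentence: every candidate pair
  s <- linking_prf(bp, fg_gold_pairs(doc), candidates = candidate_pairs(doc))
  expect_equal(unname(s[1:3]), c(0.5, 1, 2 / 3))
  expect_equal(unname(evaluate_linking("baseline", list(doc))[1:3]),
               c(0.5, 1, 2 / 3))
  # document scope coincides on a one-sentence abstract
  expect_identical(nrow(baseline_pairs(doc, scope = "document")), 36L)
})

test_that("linking_prf is order- and duplicate-insensitive, checks candidates", {
  pred <- data.frame(a = c("T2", "T1", "T2"), b = c("T1", "T2", "T1"))
  gold <- data.frame(a = "T1", b = "T2")
  expect_equal(linking_prf(pred, gold)[["f1"]], 1)
  cand <- data.frame(a = "T1", b = "T3")
  expect_error(linking_prf(pred, gold, candidates = cand), "candidate")
  # empty prediction sets
  empty <- data.frame(a = character(), b = character())
  expect_equal(unname(linking_prf(empty, gold)[1:3]), c(0, 0, 0))
  expect_equal(linking_prf(empty, empty)[["tp"]], 0)
})

test_that("the baseline cannot recall cross-sentence groups", {
  cfg <- fg_synth_config(n_docs = 25, experiments_per_doc = 1,
                         groups_per_experiment = 2:3, p_multisentence = 1,
                         p_distractor = 0, p_unlinked = 0)
  corpus <- generate_corpus(cfg, seed = 3)
  cs <- corpus_summary(corpus)
  # each experiment's first group stays in the perturbing-action sentence,
  # so with 2-3 groups the attainable fraction is between 1/2 and 2/3
  expect_gt(cs$cross_sentence_group_fraction, 0.4)
  s <- evaluate_linking("baseline", corpus)
  expect_lt(s[["recall"]], 1)
  # document scope recovers full recall at the cost of precision
  sd_ <- evaluate_linking("baseline", corpus, scope = "document")
  expect_equal(sd_[["recall"]], 1)
  expect_lte(sd_[["precision"]], s[["precision"]])
})

test_that("crossval rotates every document through the test fold once", {
  corpus <- as.list(letters[1:11])
  seen_test <- character()
  res <- crossval(
    corpus,
    train_fn = function(train) {
      expect_length(train, 11 - length(setdiff(letters[1:11], unlist(train))))
      unlist(train)
    },
    eval_fn = function(model, test) {
      expect_length(intersect(model, unlist(test)), 0)
      seen_test <<- c(seen_test, unlist(test))
      c(score = length(test))
    },
    n_folds = 4, seed = 9)
  expect_setequal(seen_test, letters[1:11])
  expect_length(res$per_fold, 4)
  expect_equal(unname(res$mean), 11 / 4)
})

test_that("crossval averages data.frame results element-wise", {
  corpus <- as.list(1:8)
  k <- 0
  res <- crossval(corpus,
                  train_fn = function(train) NULL,
                  eval_fn = function(model, test) {
                    k <<- k + 1
                    data.frame(head = c("x", "y"), f1 = c(k, 2 * k))
                  },
                  n_folds = 4, seed = 1)
  expect_equal(res$mean$f1, c(mean(1:4), 2 * mean(1:4)))
  expect_identical(res$mean$head, c("x", "y"))
})

test_that("evaluate_tagger is perfect for a gold-echo model", {
  # a model whose predictions are read back from the gold document must
  # score 1.0 everywhere; route through the real scoring path by training
  # a throwaway model and overriding its label function is heavier than
  # needed — instead check tagging_prf directly on identical label lists
  doc <- worked_example()
  tok <- tiny_tokenizer(doc$text)
  enc <- encode_bio(doc, tok)
  out <- tagging_prf(enc$labels, enc$labels)
  expect_true(all(out$f1[out$tp + out$fn > 0] == 1))
  expect_true(all(out$fp == 0))
})
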
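#' Precision, recall and F1 from counts
#'
#' Undefined ratios (zero denominators) are reported as 0.
#'
#' @param tp,fp,fn non-negative counts.
#' @return named numeric vector `precision`, `recall`, `f1`, `tp`, `fp`,
#'   `fn`.
#' @export
prf <- function(tp, fp, fn) {
  tp <- unname(tp); fp <- unname(fp); fn <- unname(fn)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f, tp = tp, fp = fp, fn = fn)
}

#' Holdout and cross-validation splits
#'
#' The held-out test set is a random sample of `round(holdout_frac * n)`
#' documents; the remainder is dealt round-robin into `n_folds`
#' cross-validation folds, so fold sizes differ by at most one. With a seed
#' the split is reproducible.
#'
#' @param n number of documents (or a list, whose length is used).
#' @param holdout_frac fraction held out (default 0.1).
#' @param n_folds number of folds over the remainder (default 4).
#' @param seed optional RNG seed.
#' @return list with `holdout` (integer indices), `train` (the complement)
#'   and `folds` (list of `n_folds` disjoint index vectors partitioning
#'   `train`).
#' @export
make_splits <- function(n, holdout_frac = 0.1, n_folds = 4L, seed = NULL) {
  if (is.list(n)) n <- length(n)
  if (n < 5) stop("need at least 5 documents to split")
  if (!is.null(seed)) set.seed(seed)
  n_hold <- round(holdout_frac * n)
  holdout <- sort(sample.int(n, n_hold))
  train <- setdiff(seq_len(n), holdout)
  shuffled <- sample(train)
  folds <- lapply(seq_len(n_folds), function(k) {
    sort(shuffled[seq(k, length(shuffled), by = n_folds)])
  })
  list(holdout = holdout, train = train, folds = folds)
}

# tp/fp/fn counts for one pair of label sequences under the double-count
# rule: positions where both are "O" are ignored; a correct non-O label is
# one TP; a non-O prediction against gold "O" is one FP; "O" against a
# non-O gold is one FN; two different non-O labels count as one FP AND one
# FN.
sequence_counts <- function(pred, gold) {
  stopifnot(length(pred) == length(gold))
  po <- pred == "O"
  go <- gold == "O"
  tp <- sum(!po & !go & pred == gold)
  mism <- sum(!po & !go & pred != gold)
  fp <- sum(!po & go) + mism
  fn <- sum(po & !go) + mism
  c(tp = tp, fp = fp, fn = fn)
}

#' Token-level tagging precision/recall/F1
#'
#' Scores one label sequence (or a named list of five, one per head)
#' against gold under the partial-credit rule used throughout: positions
#' where prediction and gold are both `O` do not enter any count; a correct
#' non-`O` label is a true positive; a spurious non-`O` label (gold `O`) a
#' false positive; a missed one (prediction `O`) a false negative; and a
#' position where both are non-`O` but different is counted as a false
#' positive *and* a false negative.
#'
#' @param pred,gold character label vectors of equal length, or named lists
#'   of such vectors (scored per name).
#' @return a `prf` vector, or a data.frame with one row per head (plus a
#'   micro-average row `overall`) when lists are given.
#' @export
tagging_prf <- function(pred, gold) {
  if (!is.list(pred)) {
    cnt <- sequence_counts(pred, gold)
    return(prf(cnt["tp"], cnt["fp"], cnt["fn"]))
  }
  stopifnot(identical(names(pred), names(gold)))
  counts <- vapply(names(pred),
                   function(h) sequence_counts(pred[[h]], gold[[h]]),
                   numeric(3))
  rows <- lapply(names(pred), function(h) {
    data.frame(head = h, t(prf(counts["tp", h], counts["fp", h],
                               counts["fn", h])))
  })
  tot <- rowSums(counts)
  rows[[length(rows) + 1L]] <-
    data.frame(head = "overall", t(prf(tot["tp"], tot["fp"], tot["fn"])))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# per-head gold and predicted label sequences for one document;
# level = "word" applies first-token aggregation, "token" stays sub-word
tagger_doc_labels <- function(model, doc, level = "word") {
  enc <- encode_bio(doc, model$tokenizer, model$schema)
  probs <- windowed_probs(model, enc$token_ids)
  spaces <- fg_label_spaces(model$schema)
  n_out <- if (level == "word") nrow(enc$words) else length(enc$token_ids)
  pred <- lapply(seq_along(spaces), function(h) {
    if (is.null(probs[[h]])) return(rep("O", n_out))
    tok <- spaces[[h]][max.col(probs[[h]], ties.method = "first")]
    if (level == "word") aggregate_tokens_to_words(tok, enc$token_word)
    else tok
  })
  names(pred) <- names(spaces)
  gold <- if (level == "word") enc$labels else token_labels(enc)
  list(pred = pred, gold = gold)
}

#' Evaluate a trained tagger on a corpus
#'
#' Micro-averaged precision/recall/F1 per head over all documents, under
#' the [tagging_prf()] counting rule. Scores are word-level after
#' first-token aggregation by default; `level = "token"` scores the raw
#' sub-word predictions instead.
#'
#' @param model an `fg_tagger`.
#' @param corpus list of gold [fg_document()]s.
#' @param level `"word"` (default) or `"token"`.
#' @return data.frame with columns `head`, `precision`, `recall`, `f1`,
#'   `tp`, `fp`, `fn` (five heads plus `overall`).
#' @export
evaluate_tagger <- function(model, corpus, level = c("word", "token")) {
  level <- match.arg(level)
  spaces <- names(fg_label_spaces(model$schema))
  counts <- matrix(0, 3, length(spaces),
                   dimnames = list(c("tp", "fp", "fn"), spaces))
  for (doc in corpus) {
    pg <- tagger_doc_labels(model, doc, level)
    for (h in spaces) {
      counts[, h] <- counts[, h] + sequence_counts(pg$pred[[h]], pg$gold[[h]])
    }
  }
  rows <- lapply(spaces, function(h) {
    data.frame(head = h, t(prf(counts["tp", h], counts["fp", h],
                               counts["fn", h])))
  })
  tot <- rowSums(counts)
  rows[[length(rows) + 1L]] <-
    data.frame(head = "overall", t(prf(tot["tp"], tot["fp"], tot["fn"])))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-assertion word-level recall
#'
#' For every assertion label, the fraction of gold-labelled word positions
#' (both `B-` and `I-`) that the tagger reproduced exactly. This is the
#' quantity that inverse-frequency loss balancing is meant to move on the
#' rare tail of each vocabulary.
#'
#' @param model an `fg_tagger`.
#' @param corpus list of gold [fg_document()]s.
#' @return data.frame with columns `category`, `assertion`, `n` (gold word
#'   positions), `recalled`, `recall`; assertions that never occur are
#'   omitted.
#' @export
evaluate_assertion_recall <- function(model, corpus) {
  heads <- model$schema$categories
  tally <- list()
  for (doc in corpus) {
    pg <- tagger_doc_labels(model, doc, level = "word")
    for (h in heads) {
      gold <- pg$gold[[h]]
      pred <- pg$pred[[h]]
      on <- gold != "O"
      if (!any(on)) next
      assertion <- sub("^[BI]-", "", gold[on])
      hit <- pred[on] == gold[on]
      for (a in unique(assertion)) {
        key <- paste0(h, "\r", a)
        prev <- tally[[key]] %||% c(n = 0, recalled = 0)
        sel <- assertion == a
        tally[[key]] <- prev + c(n = sum(sel), recalled = sum(hit[sel]))
      }
    }
  }
  if (!length(tally)) {
    return(data.frame(category = character(), assertion = character(),
                      n = numeric(), recalled = numeric(),
                      recall = numeric()))
  }
  parts <- strsplit(names(tally), "\r", fixed = TRUE)
  out <- data.frame(
    category = vapply(parts, `[`, character(1), 1),
    assertion = vapply(parts, `[`, character(1), 2),
    n = vapply(tally, `[[`, numeric(1), "n"),
    recalled = vapply(tally, `[[`, numeric(1), "recalled"),
    stringsAsFactors = FALSE)
  out$recall <- out$recalled / out$n
  out <- out[order(out$category, -out$n), ]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' All candidate entity pairs of a document
#'
#' Every unordered pair of distinct mentions — the decision space of the
#' linking task.
#'
#' @param doc an [fg_document()].
#' @return data.frame with columns `a`, `b` (mention ids, `a < b`).
#' @export
candidate_pairs <- function(doc) {
  ids <- doc$mentions$id
  if (length(ids) < 2) return(data.frame(a = character(), b = character()))
  cmb <- utils::combn(ids, 2)
  data.frame(a = pmin(cmb[1, ], cmb[2, ]), b = pmax(cmb[1, ], cmb[2, ]),
             stringsAsFactors = FALSE)
}

#' Sentence co-occurrence baseline for entity linking
#'
#' The non-learned reference system: every pair of distinct mentions whose
#' spans start in the same sentence is predicted as linked
#' (`scope = "document"` links every candidate pair regardless of
#' sentences).
#'
#' @param doc an [fg_document()].
#' @param scope `"sentence"` (default) or `"document"`.
#' @return data.frame with columns `a`, `b` (mention ids, `a < b`).
#' @export
baseline_pairs <- function(doc, scope = c("sentence", "document")) {
  scope <- match.arg(scope)
  cp <- candidate_pairs(doc)
  if (scope == "document" || !nrow(cp)) return(cp)
  sents <- split_sentences(doc$text)
  sent <- sentence_of(doc$mentions, sents)
  names(sent) <- doc$mentions$id
  keep <- !is.na(sent[cp$a]) & sent[cp$a] == sent[cp$b]
  out <- cp[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Linking precision/recall/F1 for one document's pair sets
#'
#' Exact set comparison of unordered mention-id pairs. When `candidates`
#' is supplied (the tagged-only decision space, e.g. [candidate_pairs()]),
#' predicted or gold pairs outside it raise an error.
#'
#' @param pred,gold data.frames with columns `a`, `b` (order within a pair
#'   irrelevant; duplicates collapsed).
#' @param candidates optional data.frame of admissible pairs.
#' @return a `prf` vector.
#' @export
linking_prf <- function(pred, gold, candidates = NULL) {
  key <- function(df) {
    if (!nrow(df)) return(character())
    unique(paste(pmin(df$a, df$b), pmax(df$a, df$b), sep = "\r"))
  }
  kp <- key(pred)
  kg <- key(gold)
  if (!is.null(candidates)) {
    kc <- key(candidates)
    out <- setdiff(c(kp, kg), kc)
    if (length(out)) {
      stop("pair(s) outside the candidate space: ",
           paste(gsub("\r", "-", out), collapse = ", "))
    }
  }
  prf(tp = sum(kp %in% kg), fp = sum(!kp %in% kg), fn = sum(!kg %in% kp))
}

#' Evaluate a linker (or the baseline) on a corpus
#'
#' Micro-averaged precision/recall/F1 of predicted entity pairs against the
#' gold link-group closure, with gold entity boundaries given. `model` may
#' be an `fg_linker` or `"baseline"` for the sentence co-occurrence
#' baseline.
#'
#' @param model an `fg_linker`, or `"baseline"`.
#' @param corpus list of gold [fg_document()]s.
#' @param threshold decision threshold for the learned model.
#' @param scope baseline scope (see [baseline_pairs()]).
#' @return a `prf` vector.
#' @export
evaluate_linking <- function(model, corpus, threshold = 0.5,
                             scope = "sentence") {
  tp <- fp <- fn <- 0
  for (doc in corpus) {
    pred <- if (identical(model, "baseline")) {
      baseline_pairs(doc, scope)
    } else {
      predict_links(model, doc, threshold = threshold)
    }
    s <- linking_prf(pred, fg_gold_pairs(doc))
    tp <- tp + s["tp"]; fp <- fp + s["fp"]; fn <- fn + s["fn"]
  }
  prf(unname(tp), unname(fp), unname(fn))
}

#' k-fold cross-validation driver
#'
#' Generic rotation: for each fold, `train_fn(train_docs)` fits a model on
#' the other folds and `eval_fn(model, test_docs)` scores it on the held-in
#' fold. Used with [train_tagger()]/[evaluate_tagger()] or
#' [train_linker()]/[evaluate_linking()].
#'
#' @param corpus list of gold [fg_document()]s.
#' @param train_fn function(list of documents) -> model.
#' @param eval_fn function(model, list of documents) -> numeric vector or
#'   one-row-per-head data.frame.
#' @param n_folds number of folds (default 4).
#' @param seed RNG seed for the fold assignment.
#' @return list with `per_fold` (list of `eval_fn` results) and `mean`
#'   (element-wise mean over folds).
#' @export
crossval <- function(corpus, train_fn, eval_fn, n_folds = 4L, seed = 1L) {
  sp <- make_splits(length(corpus), holdout_frac = 0, n_folds = n_folds,
                    seed = seed)
  per_fold <- lapply(seq_len(n_folds), function(k) {
    test_idx <- sp$folds[[k]]
    model <- train_fn(corpus[setdiff(seq_along(corpus), test_idx)])
    eval_fn(model, corpus[test_idx])
  })
  mean_res <- if (is.data.frame(per_fold[[1]])) {
    out <- per_fold[[1]]
    num <- vapply(out, is.numeric, logical(1))
    for (k in seq(2, n_folds)) out[num] <- out[num] + per_fold[[k]][num]
    out[num] <- out[num] / n_folds
    out
  } else {
    Reduce(`+`, per_fold) / n_folds
  }
  list(per_fold = per_fold, mean = mean_res)
}
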
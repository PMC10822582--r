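#' Training configuration for the linking model
#'
#' The relation model classifies concatenated pairs of token embeddings with
#' a link head (are the two tokens part of linked entities?) and an
#' auxiliary same-tag head (are they part of the same entity?). The
#' auxiliary head aids encoder fine-tuning and is never used at inference;
#' `lambda = 0` trains without it (the ablated configuration).
#'
#' @inheritParams fg_tagging_config
#' @param lambda weight of the auxiliary same-tag objective.
#' @param negative_cap during training, retain at most `negative_cap`
#'   randomly chosen link-negative pairs per positive (controls the
#'   quadratic pair explosion); evaluation never subsamples. `Inf` keeps
#'   every pair.
#' @param pair_mode `"all"` (every token pair, the training regime) or
#'   `"tagged"` (both tokens inside gold mentions, the evaluation regime).
#' @param within_mention_linked convention flag: if `TRUE`, token pairs
#'   inside one mention are 1 in the link matrix; default `FALSE` (that
#'   structure is carried by the same-tag objective).
#' @return a config list.
#' @export
fg_linking_config <- function(epochs = 30L, lr = 1e-3, seed = 1L,
                              d_model = 128L, n_layers = 2L, n_heads = 4L,
                              max_len = 512L, loss_exponent = 1, lambda = 1,
                              negative_cap = 5, pair_mode = c("all", "tagged"),
                              within_mention_linked = FALSE,
                              train_encoder = TRUE, clip = 5) {
  list(epochs = as.integer(epochs), lr = lr, seed = as.integer(seed),
       d_model = as.integer(d_model), n_layers = as.integer(n_layers),
       n_heads = as.integer(n_heads), max_len = as.integer(max_len),
       loss_exponent = loss_exponent, lambda = lambda,
       negative_cap = negative_cap, pair_mode = match.arg(pair_mode),
       within_mention_linked = isTRUE(within_mention_linked),
       train_encoder = isTRUE(train_encoder), clip = clip)
}

#' Enumerate token pairs with gold link and same-tag bits
#'
#' Mode `"all"` yields every ordered pair `(i, j)` with `i <= j` over the
#' document's tokens — the training regime — optionally subsampling
#' link-negative pairs to `negative_cap` times the number of positives
#' (pairs that are link- or same-tag-positive are always retained). Mode
#' `"tagged"` restricts to pairs of tokens belonging to two distinct gold
#' mentions (the evaluation regime; self and same-mention pairs excluded
#' per the link-matrix convention) and never subsamples.
#'
#' Subsampling uses the current RNG state; seed the session for
#' reproducibility.
#'
#' @param doc a gold [fg_document()].
#' @param enc its `fg_encoded` form.
#' @param mode `"all"` or `"tagged"`.
#' @param negative_cap ratio of retained negatives to positives
#'   (training only).
#' @param within_mention_linked link-matrix convention flag (see
#'   [build_link_matrix()]).
#' @return data.frame with columns `i`, `j` (token indices, `i <= j`),
#'   `link`, `same` (0/1 gold bits).
#' @export
enumerate_pairs <- function(doc, enc, mode = c("all", "tagged"),
                            negative_cap = Inf,
                            within_mention_linked = FALSE) {
  mode <- match.arg(mode)
  nt <- length(enc$token_ids)
  M <- build_link_matrix(doc, enc, within_mention = within_mention_linked)
  toks <- mention_token_sets(enc)
  mention_of <- integer(nt)
  for (k in seq_along(toks)) mention_of[toks[[k]]] <- k

  if (mode == "all") {
    ut <- upper.tri(M, diag = TRUE)
    i <- row(M)[ut]
    j <- col(M)[ut]
    link <- M[ut]
    same <- as.integer(mention_of[i] != 0L & mention_of[i] == mention_of[j])
    out <- data.frame(i = i, j = j, link = as.integer(link), same = same)
    if (is.finite(negative_cap)) {
      neg <- which(out$link == 0L & out$same == 0L)
      keep_n <- ceiling(negative_cap * sum(out$link == 1L))
      if (length(neg) > keep_n) {
        drop <- sample(neg, length(neg) - keep_n)
        out <- out[-drop, , drop = FALSE]
      }
    }
  } else {
    tagged <- which(mention_of != 0L)
    if (length(tagged) < 2) {
      return(data.frame(i = integer(), j = integer(), link = integer(),
                        same = integer()))
    }
    cmb <- utils::combn(tagged, 2)
    i <- cmb[1, ]
    j <- cmb[2, ]
    keep <- mention_of[i] != mention_of[j]
    i <- i[keep]; j <- j[keep]
    out <- data.frame(i = i, j = j, link = as.integer(M[cbind(i, j)]),
                      same = 0L)
  }
  rownames(out) <- NULL
  out
}

prepare_linking_data <- function(corpus, tokenizer, schema, config) {
  lapply(corpus, function(doc) {
    enc <- encode_bio(doc, tokenizer, schema)
    ids <- enc$token_ids
    if (length(ids) > config$max_len) {
      warning("document ", doc$doc_id, " truncated to ", config$max_len,
              " tokens")
      # drop mentions beyond the window, then re-enumerate on the prefix
      keep_words <- unique(enc$token_word[seq_len(config$max_len)])
      enc$token_ids <- ids[seq_len(config$max_len)]
      enc$token_word <- enc$token_word[seq_len(config$max_len)]
      enc$mention_words <- enc$mention_words[enc$mention_words$we <=
                                               max(keep_words), , drop = FALSE]
      doc$links <- doc$links[apply(doc$links[fg_schema()$categories], 1,
                                   function(ms) all(ms %in% enc$mention_words$id)),
                             , drop = FALSE]
    }
    pairs <- enumerate_pairs(doc, enc, mode = config$pair_mode,
                             negative_cap = config$negative_cap,
                             within_mention_linked = config$within_mention_linked)
    list(ids = as.integer(enc$token_ids), pairs = pairs)
  })
}

#' Train the link-prediction model
#'
#' Trained, validated and tested on gold entity tags: pairs of token
#' embeddings are enumerated per document, class-balanced binary
#' cross-entropy is minimised jointly for the link head and the auxiliary
#' same-tag head, and the encoder is fine-tuned through both. Reproducible
#' under a fixed seed.
#'
#' @param corpus non-empty list of gold [fg_document()]s with link
#'   annotations.
#' @param config an [fg_linking_config()].
#' @param tokenizer an `fg_tokenizer`; trained on `corpus` when `NULL`.
#' @param schema an [fg_schema()].
#' @return an object of class `fg_linker` with `$history` (per-epoch mean
#'   loss per pair).
#' @export
train_linker <- function(corpus, config = fg_linking_config(),
                         tokenizer = NULL, schema = fg_schema()) {
  if (!length(corpus)) stop("empty training corpus")
  set.seed(config$seed)
  if (is.null(tokenizer)) tokenizer <- train_tokenizer(corpus)
  data <- prepare_linking_data(corpus, tokenizer, schema, config)
  data <- data[vapply(data, function(d) nrow(d$pairs) > 0, logical(1))]
  if (!length(data)) stop("no token pairs in the training corpus")

  n_pos_link <- sum(vapply(data, function(d) sum(d$pairs$link), numeric(1)))
  n_all <- sum(vapply(data, function(d) nrow(d$pairs), numeric(1)))
  n_pos_same <- sum(vapply(data, function(d) sum(d$pairs$same), numeric(1)))
  w_link <- compute_loss_weights(c(neg = n_all - n_pos_link, pos = n_pos_link),
                                 exponent = config$loss_exponent)
  w_same <- if (n_pos_same > 0 && n_pos_same < n_all) {
    compute_loss_weights(c(neg = n_all - n_pos_same, pos = n_pos_same),
                         exponent = config$loss_exponent)
  } else c(neg = 1, pos = 1)

  spec <- fg_encoder_spec(length(tokenizer$vocab), config$max_len,
                          config$d_model, config$n_layers, config$n_heads)
  n_enc <- cpp_encoder_param_count(spec)
  theta <- c(init_encoder_params(spec),
             numeric(cpp_linker_param_count(spec) - n_enc))
  st <- adam_init(length(theta))
  enc_idx <- seq_len(n_enc)
  history <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(length(data))
    total <- 0
    npair <- 0
    for (k in ord) {
      d <- data[[k]]
      pr <- d$pairs
      lg <- cpp_linker_loss_grad(theta, spec, d$ids,
                                 as.integer(pr$i), as.integer(pr$j),
                                 as.numeric(pr$link), as.numeric(pr$same),
                                 unname(w_link[pr$link + 1L]),
                                 unname(w_same[pr$same + 1L]),
                                 config$lambda)
      g <- lg$grad
      if (!config$train_encoder) g[enc_idx] <- 0
      upd <- adam_step(theta, g / nrow(pr), st, config$lr, clip = config$clip)
      theta <- upd$theta
      st <- upd$state
      total <- total + lg$loss
      npair <- npair + nrow(pr)
    }
    history[ep] <- total / npair
  }
  structure(list(theta = theta, spec = spec, tokenizer = tokenizer,
                 config = config, schema = schema, history = history,
                 history_df = data.frame(epoch = seq_along(history),
                                         loss = history)),
            class = "fg_linker")
}

#' @export
print.fg_linker <- function(x, ...) {
  cat(sprintf("<fg_linker> d=%d, %d layers; vocab %d; %d epochs (final loss %.4f)\n",
              x$spec$d_model, x$spec$n_layers, x$spec$vocab_size,
              length(x$history), x$history[length(x$history)]))
  invisible(x)
}

#' Link and same-tag probabilities for explicit token pairs
#'
#' @param model an `fg_linker`.
#' @param token_ids integer token ids of one document.
#' @param i,j 1-based token indices of the pairs.
#' @return matrix with columns `link`, `same` of probabilities in `[0, 1]`.
#' @export
fg_linker_forward <- function(model, token_ids, i, j) {
  out <- cpp_linker_forward(model$theta, model$spec, as.integer(token_ids),
                            as.integer(i), as.integer(j))
  colnames(out) <- c("link", "same")
  out
}

#' Predict entity-pair links for a document
#'
#' Token-pair link probabilities are computed for the document's mentions
#' (gold or predicted); an entity pair is linked iff the probability of its
#' first-token pair reaches `threshold` (the default aggregation, matching
#' the tagger's first-token rule), or iff the mean over all cross token
#' pairs does (`aggregation = "mean"`). Output is a set of unordered
#' mention-id pairs: symmetric, never containing self pairs.
#'
#' @param model an `fg_linker`.
#' @param doc an [fg_document()] whose mentions are to be linked (its link
#'   annotations, if any, are ignored).
#' @param threshold decision threshold on the link probability (fixed at
#'   0.5 by default, not tuned).
#' @param aggregation `"first"` or `"mean"`.
#' @return data.frame with columns `a`, `b` (mention ids, `a < b`
#'   lexicographically) and `prob`.
#' @export
predict_links <- function(model, doc, threshold = 0.5,
                          aggregation = c("first", "mean")) {
  aggregation <- match.arg(aggregation)
  enc <- encode_bio(doc, model$tokenizer, model$schema)
  mw <- enc$mention_words
  if (nrow(mw) < 2) {
    return(data.frame(a = character(), b = character(), prob = numeric()))
  }
  toks <- mention_token_sets(enc)
  cmb <- utils::combn(seq_len(nrow(mw)), 2)
  if (aggregation == "first") {
    i <- vapply(cmb[1, ], function(k) min(toks[[k]]), integer(1))
    j <- vapply(cmb[2, ], function(k) min(toks[[k]]), integer(1))
    ii <- pmin(i, j)
    jj <- pmax(i, j)
    probs <- fg_linker_forward(model, enc$token_ids, ii, jj)[, "link"]
  } else {
    probs <- vapply(seq_len(ncol(cmb)), function(p) {
      ta <- toks[[cmb[1, p]]]
      tb <- toks[[cmb[2, p]]]
      grid <- expand.grid(i = ta, j = tb)
      ii <- pmin(grid$i, grid$j)
      jj <- pmax(grid$i, grid$j)
      mean(fg_linker_forward(model, enc$token_ids, ii, jj)[, "link"])
    }, numeric(1))
  }
  a <- mw$id[cmb[1, ]]
  b <- mw$id[cmb[2, ]]
  out <- data.frame(a = pmin(a, b), b = pmax(a, b), prob = probs,
                    stringsAsFactors = FALSE)
  out[out$prob >= threshold, , drop = FALSE]
}
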
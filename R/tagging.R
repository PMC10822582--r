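#' Training configuration for the tagging model
#'
#' Hyperparameters of the named-entity tagger. Defaults are the desk-scale
#' study conditions: a small transformer trained from scratch with Adam at
#' learning rate 1e-3 and full inverse-frequency loss balancing. The five
#' heads (category + four assertion heads) share one encoder by default;
#' `split_heads = TRUE` trains one encoder per head (the architecture
#' ablation), and `head_scales` can switch individual heads off — training
#' without the category head still runs, since the extra head is auxiliary.
#'
#' @param epochs passes over the training corpus.
#' @param lr Adam learning rate.
#' @param seed RNG seed; a fixed seed makes training reproducible on one
#'   device.
#' @param d_model,n_layers,n_heads,max_len encoder shape (see
#'   [fg_encoder_spec()]).
#' @param loss_exponent inverse-frequency exponent in `[0, 1]` passed to
#'   [compute_loss_weights()]; 0 disables balancing.
#' @param head_scales numeric(5) loss multiplier per head, in the
#'   [fg_label_spaces()] order (category first); 0 removes a head from the
#'   objective.
#' @param split_heads train a separate encoder per head instead of a shared
#'   one.
#' @param train_encoder if `FALSE`, the encoder is frozen and only the
#'   linear heads are updated (linear-probe mode).
#' @param clip global gradient-norm clip.
#' @return a config list.
#' @export
fg_tagging_config <- function(epochs = 60L, lr = 1e-3, seed = 1L,
                              d_model = 128L, n_layers = 2L, n_heads = 4L,
                              max_len = 512L, loss_exponent = 1,
                              head_scales = rep(1, 5), split_heads = FALSE,
                              train_encoder = TRUE, clip = 5) {
  stopifnot(length(head_scales) == 5, epochs >= 1)
  list(epochs = as.integer(epochs), lr = lr, seed = as.integer(seed),
       d_model = as.integer(d_model), n_layers = as.integer(n_layers),
       n_heads = as.integer(n_heads), max_len = as.integer(max_len),
       loss_exponent = loss_exponent, head_scales = as.numeric(head_scales),
       split_heads = isTRUE(split_heads),
       train_encoder = isTRUE(train_encoder), clip = clip)
}

# encode a corpus once: token ids + per-head 1-based token label ids
prepare_tagging_data <- function(corpus, tokenizer, schema, max_len) {
  spaces <- fg_label_spaces(schema)
  lapply(corpus, function(doc) {
    enc <- encode_bio(doc, tokenizer, schema)
    tl <- token_labels(enc)
    ids <- enc$token_ids
    lab <- lapply(names(spaces), function(nm) match(tl[[nm]], spaces[[nm]]))
    if (length(ids) > max_len) {
      warning("document ", doc$doc_id, " truncated to ", max_len, " tokens")
      ids <- ids[seq_len(max_len)]
      lab <- lapply(lab, function(x) x[seq_len(max_len)])
    }
    list(ids = as.integer(ids), labels = lapply(lab, as.integer))
  })
}

token_label_counts <- function(data, head_sizes) {
  counts <- lapply(head_sizes, function(C) numeric(C))
  for (d in data) {
    for (h in seq_along(counts)) {
      t <- tabulate(d$labels[[h]], nbins = head_sizes[h])
      counts[[h]] <- counts[[h]] + t
    }
  }
  counts
}

train_tagger_single <- function(data, spec, head_sizes, weights, config) {
  n_enc <- cpp_encoder_param_count(spec)
  theta <- c(init_encoder_params(spec),
             numeric(cpp_tagger_param_count(spec, head_sizes) - n_enc))
  st <- adam_init(length(theta))
  enc_idx <- seq_len(n_enc)
  history <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(length(data))
    total <- 0
    ntok <- 0
    for (k in ord) {
      d <- data[[k]]
      lg <- cpp_tagger_loss_grad(theta, spec, head_sizes, d$ids, d$labels,
                                 weights, config$head_scales)
      g <- lg$grad
      if (!config$train_encoder) g[enc_idx] <- 0
      upd <- adam_step(theta, g / length(d$ids), st, config$lr,
                       clip = config$clip)
      theta <- upd$theta
      st <- upd$state
      total <- total + lg$loss
      ntok <- ntok + length(d$ids)
    }
    history[ep] <- total / ntok
  }
  list(theta = theta, history = history)
}

#' Train the named-entity tagging model
#'
#' Fits the shared encoder and the five linear-softmax heads by per-document
#' Adam steps on the class-weighted cross-entropy objective, the encoder
#' parameters being updated jointly with the heads. A fixed seed reproduces
#' the loss history exactly on one device.
#'
#' @param corpus non-empty list of gold [fg_document()]s.
#' @param config an [fg_tagging_config()].
#' @param tokenizer an `fg_tokenizer`; trained on `corpus` when `NULL`.
#' @param schema an [fg_schema()].
#' @return an object of class `fg_tagger`: parameters, encoder spec,
#'   tokenizer, loss weights, config and per-epoch mean training loss
#'   (`$history`, one value per epoch; a data.frame with `epoch` and `loss`
#'   via `$history_df`).
#' @export
train_tagger <- function(corpus, config = fg_tagging_config(),
                         tokenizer = NULL, schema = fg_schema()) {
  if (!length(corpus)) stop("empty training corpus")
  set.seed(config$seed)
  if (is.null(tokenizer)) tokenizer <- train_tokenizer(corpus)
  head_sizes <- tagging_head_sizes(schema)
  data <- prepare_tagging_data(corpus, tokenizer, schema, config$max_len)
  counts <- token_label_counts(data, head_sizes)
  weights <- lapply(counts, compute_loss_weights,
                    exponent = config$loss_exponent)
  spec <- fg_encoder_spec(length(tokenizer$vocab), config$max_len,
                          config$d_model, config$n_layers, config$n_heads)
  if (config$split_heads) {
    fits <- lapply(seq_along(head_sizes), function(h) {
      sc <- numeric(length(head_sizes))
      sc[h] <- config$head_scales[h]
      if (sc[h] == 0) return(NULL)
      cfg <- config
      cfg$head_scales <- sc
      train_tagger_single(data, spec, head_sizes, weights, cfg)
    })
    theta <- lapply(fits, function(f) if (is.null(f)) NULL else f$theta)
    history <- rowMeans(do.call(cbind, lapply(fits, function(f) {
      if (is.null(f)) NULL else f$history
    })))
  } else {
    fit <- train_tagger_single(data, spec, head_sizes, weights, config)
    theta <- fit$theta
    history <- fit$history
  }
  structure(list(theta = theta, spec = spec, head_sizes = head_sizes,
                 tokenizer = tokenizer, weights = weights, config = config,
                 schema = schema, history = history,
                 history_df = data.frame(epoch = seq_along(history),
                                         loss = history)),
            class = "fg_tagger")
}

#' @export
print.fg_tagger <- function(x, ...) {
  cat(sprintf("<fg_tagger> d=%d, %d layers, %d heads; vocab %d; %d epochs (final loss %.4f)\n",
              x$spec$d_model, x$spec$n_layers, x$spec$n_heads,
              x$spec$vocab_size, length(x$history),
              x$history[length(x$history)]))
  invisible(x)
}

#' Per-token class probabilities from a trained tagger
#'
#' @param model an `fg_tagger`.
#' @param token_ids integer token ids (one window).
#' @return list of five probability matrices (tokens x classes); each row
#'   sums to 1.
#' @export
fg_tagger_forward <- function(model, token_ids) {
  ids <- as.integer(token_ids)
  if (model$config$split_heads) {
    out <- vector("list", length(model$head_sizes))
    for (h in seq_along(out)) {
      if (is.null(model$theta[[h]])) next
      out[[h]] <- cpp_tagger_forward(model$theta[[h]], model$spec,
                                     model$head_sizes, ids)[[h]]
    }
    out
  } else {
    cpp_tagger_forward(model$theta, model$spec, model$head_sizes, ids)
  }
}

# windowed per-token probabilities; overlapping positions resolved
# first-window-wins
windowed_probs <- function(model, ids, overlap = 64L) {
  n <- length(ids)
  L <- model$spec$max_len
  if (n <= L) return(fg_tagger_forward(model, ids))
  overlap <- min(overlap, L %/% 2L)  # keep the stride positive
  stride <- L - overlap
  probs <- NULL
  filled <- 0L
  start <- 1L
  while (filled < n) {
    stop_ <- min(start + L - 1L, n)
    win <- fg_tagger_forward(model, ids[start:stop_])
    if (is.null(probs)) {
      probs <- lapply(win, function(m) {
        out <- matrix(NA_real_, n, ncol(m))
        out[start:stop_, ] <- m
        out
      })
      filled <- stop_
    } else {
      keep <- (filled + 1L):stop_
      for (h in seq_along(probs)) {
        probs[[h]][keep, ] <- win[[h]][keep - start + 1L, , drop = FALSE]
      }
      filled <- stop_
    }
    start <- start + stride
  }
  probs
}

#' Tag an abstract: end-to-end mention prediction
#'
#' Runs the full pipeline: word segmentation, sub-word tokenization,
#' windowed encoder forward pass, first-token aggregation back to words,
#' and BIO decoding into entity mentions with category and assertion
#' labels. The returned document always validates.
#'
#' @param object a trained `fg_tagger`.
#' @param text abstract text (character scalar).
#' @param doc_id id for the returned document.
#' @param ... unused.
#' @return an [fg_document()] with predicted mentions and no links.
#' @export
predict.fg_tagger <- function(object, text, doc_id = "predicted", ...) {
  words <- segment_words(text)
  if (!nrow(words)) return(fg_document(doc_id, text))
  tokens <- tokenize_words(object$tokenizer, words$word)
  token_word <- rep(seq_len(nrow(words)), lengths(tokens))
  ids <- unlist(tokens, use.names = FALSE)
  probs <- windowed_probs(object, ids)
  spaces <- fg_label_spaces(object$schema)
  word_labels <- lapply(seq_along(spaces), function(h) {
    if (is.null(probs[[h]])) return(rep("O", nrow(words)))
    tok_lab <- spaces[[h]][max.col(probs[[h]], ties.method = "first")]
    aggregate_tokens_to_words(tok_lab, token_word)
  })
  names(word_labels) <- names(spaces)
  mentions <- decode_bio(word_labels, words, object$schema)
  fg_document(doc_id, text, mentions)
}
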
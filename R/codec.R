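#' Encode an annotated document into the model-facing representation
#'
#' Produces the five word-level BIO label sequences (one category space over
#' `{B,I} x 4 categories + O`, and four per-category assertion spaces over
#' `{B,I} x assertions + O`), the sub-word tokenization of each word, and the
#' token/word alignment. Words at the start of a marked span carry the `B`
#' label, subsequent words `I`, unmarked words `O`; a word that is `O` in the
#' category space is `O` in all four assertion spaces. Assertion spaces are
#' labelled on all words (the `O` class included) rather than masked to
#' in-category words.
#'
#' Mention boundaries that fall inside a word are snapped outward to word
#' boundaries with a warning.
#'
#' @param doc an [fg_document()].
#' @param tokenizer an `fg_tokenizer` (see [train_tokenizer()]).
#' @param schema an [fg_schema()].
#' @return an object of class `fg_encoded`: list with `doc_id`, `words`
#'   (data.frame `word`,`start`,`end`), `labels` (named list of 5 character
#'   vectors, one label per word), `tokens` (list of integer vectors per
#'   word), `token_ids` (flattened integer vector), `token_word` (integer
#'   map token index -> word index), `mention_words` (data.frame `id`, `ws`,
#'   `we`: word ranges per mention).
#' @export
encode_bio <- function(doc, tokenizer, schema = fg_schema()) {
  words <- segment_words(doc$text)
  nw <- nrow(words)
  spaces <- fg_label_spaces(schema)
  labels <- lapply(spaces, function(sp) rep("O", nw))
  m <- doc$mentions
  mention_words <- data.frame(id = character(), ws = integer(), we = integer(),
                              stringsAsFactors = FALSE)
  for (i in seq_len(nrow(m))) {
    ws <- which(words$start <= m$start[i] & m$start[i] < words$end)
    we <- which(words$start < m$end[i] & m$end[i] <= words$end)
    if (!length(ws)) ws <- which(words$end > m$start[i])[1]
    if (!length(we)) we <- rev(which(words$start < m$end[i]))[1]
    ws <- ws[1]; we <- we[1]
    if (is.na(ws) || is.na(we) || ws > we) {
      warning("mention ", m$id[i], " does not align to any word; skipped")
      next
    }
    if (words$start[ws] != m$start[i] || words$end[we] != m$end[i]) {
      warning("mention ", m$id[i], " snapped outward to word boundaries [",
              words$start[ws], ",", words$end[we], ")")
    }
    cat_ <- m$category[i]
    bi <- c(paste0("B-", cat_), rep(paste0("I-", cat_), we - ws))
    labels$category[ws:we] <- bi
    ba <- c(paste0("B-", m$assertion[i]),
            rep(paste0("I-", m$assertion[i]), we - ws))
    labels[[cat_]][ws:we] <- ba
    mention_words <- rbind(mention_words,
                           data.frame(id = m$id[i], ws = ws, we = we,
                                      stringsAsFactors = FALSE))
  }
  tokens <- tokenize_words(tokenizer, words$word)
  token_word <- rep(seq_len(nw), lengths(tokens))
  structure(list(doc_id = doc$doc_id, words = words, labels = labels,
                 tokens = tokens, token_ids = unlist(tokens, use.names = FALSE),
                 token_word = token_word, mention_words = mention_words),
            class = "fg_encoded")
}

#' @export
print.fg_encoded <- function(x, ...) {
  cat(sprintf("<fg_encoded> %s: %d words, %d tokens\n",
              x$doc_id, nrow(x$words), length(x$token_ids)))
  invisible(x)
}

#' Copy word-level labels onto sub-word tokens
#'
#' Every token of a word carries that word's labels, for all five label
#' spaces.
#'
#' @param enc an `fg_encoded` document.
#' @return named list of 5 character vectors, one label per token.
#' @export
token_labels <- function(enc) {
  lapply(enc$labels, function(lab) lab[enc$token_word])
}

#' Word-level label sequences as integer class ids
#'
#' @param labels named list of 5 character label vectors.
#' @param schema an [fg_schema()].
#' @return named list of integer vectors (1-based ids into the matching
#'   label space from [fg_label_spaces()]).
#' @export
labels_to_ids <- function(labels, schema = fg_schema()) {
  spaces <- fg_label_spaces(schema)
  out <- lapply(names(spaces), function(nm) {
    ids <- match(labels[[nm]], spaces[[nm]])
    if (anyNA(ids)) stop("label outside the '", nm, "' space")
    ids
  })
  stats::setNames(out, names(spaces))
}

#' Build the token-level link matrix
#'
#' Upper-triangular binary matrix over a document's tokens: entry `(i, j)`
#' (with `i <= j`) is 1 iff token `i` and token `j` belong to two *distinct*
#' mentions that co-occur in at least one link group. By default token pairs
#' inside a single mention are 0 — same-mention structure is carried by the
#' BIO labels and the auxiliary same-tag objective; set
#' `within_mention = TRUE` for the alternative convention in which they are
#' also 1.
#'
#' @param doc an [fg_document()].
#' @param enc the matching `fg_encoded` document.
#' @param within_mention set same-mention token pairs to 1 as well.
#' @return an `n_tokens x n_tokens` 0/1 matrix, zero below the diagonal.
#' @export
build_link_matrix <- function(doc, enc, within_mention = FALSE) {
  nt <- length(enc$token_ids)
  M <- matrix(0L, nt, nt)
  toks <- mention_token_sets(enc)
  gp <- fg_gold_pairs(doc)
  for (k in seq_len(nrow(gp))) {
    ta <- toks[[gp$a[k]]]
    tb <- toks[[gp$b[k]]]
    for (i in ta) for (j in tb) {
      M[min(i, j), max(i, j)] <- 1L
    }
  }
  if (within_mention) {
    for (tt in toks) {
      for (i in tt) for (j in tt[tt >= i]) M[i, j] <- 1L
    }
  }
  M
}

#' Token indices covered by each mention
#' @param enc an `fg_encoded` document.
#' @return named list (by mention id) of integer token-index vectors.
#' @keywords internal
mention_token_sets <- function(enc) {
  mw <- enc$mention_words
  out <- lapply(seq_len(nrow(mw)), function(i) {
    which(enc$token_word >= mw$ws[i] & enc$token_word <= mw$we[i])
  })
  stats::setNames(out, mw$id)
}

#' Convert per-token predictions to per-word predictions
#'
#' Applies the first-token rule: each word's prediction is the prediction of
#' its first sub-word token. Accepts either a vector of labels (one per
#' token) or a score matrix with one row per token.
#'
#' @param token_pred character/integer vector of length `n_tokens`, or a
#'   matrix with `n_tokens` rows.
#' @param token_word integer map from token index to word index.
#' @return the per-word predictions (vector or matrix with one row per
#'   word).
#' @export
aggregate_tokens_to_words <- function(token_pred, token_word) {
  first <- which(!duplicated(token_word))
  if (is.matrix(token_pred)) token_pred[first, , drop = FALSE]
  else token_pred[first]
}

#' Decode word-level BIO labels back into entity mentions
#'
#' Accepts possibly inconsistent model output: maximal `B I*` runs in the
#' category space become mentions (an orphan `I` label opens a run like a
#' `B`); the mention's assertion is the majority assertion over the run's
#' non-`O` labels in the matching assertion space, ties resolved in favour
#' of the assertion seen earliest in the run. A run whose assertion space is
#' all `O` falls back to the category's first assertion.
#'
#' @param word_labels named list of 5 character label vectors (as in
#'   `fg_encoded$labels`).
#' @param words data.frame `word`,`start`,`end` from [segment_words()].
#' @param schema an [fg_schema()].
#' @param id_prefix prefix for generated mention ids.
#' @return data.frame of mentions (`id`, `category`, `assertion`, `start`,
#'   `end`).
#' @export
decode_bio <- function(word_labels, words, schema = fg_schema(),
                       id_prefix = "T") {
  catlab <- word_labels$category
  nw <- length(catlab)
  runs <- list()
  i <- 1L
  while (i <= nw) {
    if (catlab[i] == "O") { i <- i + 1L; next }
    cat_ <- sub("^[BI]-", "", catlab[i])
    j <- i + 1L
    while (j <= nw && catlab[j] == paste0("I-", cat_)) j <- j + 1L
    runs[[length(runs) + 1L]] <- list(category = cat_, ws = i, we = j - 1L)
    i <- j
  }
  if (!length(runs)) {
    return(data.frame(id = character(), category = character(),
                      assertion = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_along(runs), function(k) {
    r <- runs[[k]]
    alab <- word_labels[[r$category]][r$ws:r$we]
    ass <- sub("^[BI]-", "", alab[alab != "O"])
    assertion <- if (length(ass)) majority_first(ass) else
      schema$assertions[[r$category]][1]
    data.frame(id = paste0(id_prefix, k), category = r$category,
               assertion = assertion, start = words$start[r$ws],
               end = words$end[r$we], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# majority vote; ties broken by earliest first occurrence in x
majority_first <- function(x) {
  tab <- table(x)
  best <- names(tab)[tab == max(tab)]
  x[x %in% best][1]
}
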
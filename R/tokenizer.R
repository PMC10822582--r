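#' Train a sub-word tokenizer on a corpus
#'
#' The tokenizer contract used throughout the package is: a word string maps
#' deterministically to one or more integer token ids, and every token of a
#' word is aligned back to that word. The desk-scale implementation keeps
#' frequent whole words as single tokens and decomposes everything else by
#' greedy longest-match into word-initial and `##`-prefixed continuation
#' pieces, with single characters as the fallback so any word can always be
#' tokenized. At full scale the same contract is filled by the pretrained
#' biomedical encoder's own tokenizer (see [full_scale_config()]).
#'
#' @param texts character vector of raw texts (or list of [fg_document()],
#'   whose `$text` fields are used).
#' @param vocab_size maximum vocabulary size (default 5000).
#' @param min_count minimum word frequency for a whole-word vocabulary entry.
#' @return an object of class `fg_tokenizer`.
#' @export
train_tokenizer <- function(texts, vocab_size = 5000, min_count = 2) {
  if (is.list(texts) && length(texts) && inherits(texts[[1]], "fg_document")) {
    texts <- vapply(texts, `[[`, character(1), "text")
  }
  words <- unlist(lapply(texts, function(t) segment_words(t)$word))
  tab <- table(words)
  # radix ordering is locale-independent, so the vocabulary (and with it
  # every downstream token id) does not depend on LC_COLLATE
  o <- order(-as.vector(tab), names(tab), method = "radix")
  freq <- stats::setNames(as.vector(tab)[o], names(tab)[o])
  chars <- sort(unique(unlist(strsplit(names(freq), ""))), method = "radix")
  base <- c("[UNK]", chars, paste0("##", chars))
  whole <- names(freq)[freq >= min_count]
  whole <- setdiff(whole, base)
  room <- max(0L, vocab_size - length(base))
  vocab <- c(base, utils::head(whole, room))
  structure(list(vocab = vocab, unk_id = 1L,
                 index = stats::setNames(seq_along(vocab), vocab)),
            class = "fg_tokenizer")
}

#' @export
print.fg_tokenizer <- function(x, ...) {
  cat(sprintf("<fg_tokenizer> vocabulary of %d pieces\n", length(x$vocab)))
  invisible(x)
}

#' Tokenize words into sub-word token ids
#'
#' @param tokenizer an `fg_tokenizer`.
#' @param words character vector of words.
#' @return list of integer vectors, one per word (ids are 1-based into
#'   `tokenizer$vocab`).
#' @export
tokenize_words <- function(tokenizer, words) {
  idx <- tokenizer$index
  lapply(words, function(w) {
    hit <- idx[w]
    if (!is.na(hit)) return(unname(hit))
    # greedy longest-match decomposition
    out <- integer()
    pos <- 1L
    nw <- nchar(w)
    first <- TRUE
    while (pos <= nw) {
      found <- FALSE
      for (len in seq(min(nw - pos + 1L, 12L), 1L)) {
        piece <- substring(w, pos, pos + len - 1L)
        key <- if (first) piece else paste0("##", piece)
        hit <- idx[key]
        if (!is.na(hit)) {
          out <- c(out, unname(hit))
          pos <- pos + len
          first <- FALSE
          found <- TRUE
          break
        }
      }
      if (!found) {
        out <- c(out, tokenizer$unk_id)
        pos <- pos + 1L
        first <- FALSE
      }
    }
    out
  })
}
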
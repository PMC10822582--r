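#' Segment text into words with character offsets
#'
#' Words are maximal runs of non-space characters, with sentence punctuation
#' (`. , ; : ( ) ! ?`) split off as single-character words. Internal symbols
#' are kept, so genotype notation like `-/-` or `G1/S` survives as one word.
#' Concatenating the words with their gaps reconstructs the text exactly.
#'
#' @param text a character scalar.
#' @return data.frame with columns `word`, `start`, `end` (0-based half-open
#'   character offsets).
#' @export
segment_words <- function(text) {
  if (!nzchar(text)) {
    return(data.frame(word = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  pat <- "[^\\s.,;:()!?]+|[.,;:()!?]"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(data.frame(word = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  data.frame(word = substring(text, start + 1L, start + len),
             start = start, end = start + len, stringsAsFactors = FALSE)
}

#' Split text into sentences with character offsets
#'
#' Rule-based splitter: a sentence ends at `.`, `!` or `?` followed by
#' whitespace and an upper-case letter or digit, unless the full stop
#' terminates a known abbreviation (`e.g.`, `i.e.`, `et al.`, `Fig.`, `cf.`,
#' `vs.`, `ca.`, `approx.`, single initials) or sits inside a number.
#'
#' @param text a character scalar.
#' @return data.frame with columns `start`, `end` (0-based half-open
#'   offsets); sentences cover the text without overlap (gaps are
#'   whitespace).
#' @export
split_sentences <- function(text) {
  n <- nchar(text)
  if (!n) return(data.frame(start = integer(), end = integer()))
  abbrev <- c("e.g", "i.e", "al", "Fig", "Figs", "cf", "vs", "ca", "approx",
              "No", "Dr", "St")
  chars <- strsplit(text, "")[[1]]
  ends <- integer()
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c(".", "!", "?")) {
      nxt <- if (i < n) chars[i + 1L] else ""
      nxt2 <- if (i + 1L < n) substring(text, i + 2L, i + 2L) else ""
      boundary <- i == n ||
        (grepl("^\\s$", nxt) && grepl("^[A-Z0-9(\"']$", nxt2))
      if (boundary && ch == ".") {
        # abbreviation / initial / decimal guard
        before <- sub(".*?([A-Za-z.]+)$", "\\1", substring(text, max(1L, i - 12L), i - 1L))
        token <- sub("^.*\\s", "", before)
        if (token %in% abbrev || grepl("^[A-Z]$", token)) boundary <- FALSE
        if (i > 1L && grepl("[0-9]", chars[i - 1L]) && grepl("^[0-9]$", nxt)) {
          boundary <- FALSE
        }
      }
      if (boundary) ends <- c(ends, i)
    }
    i <- i + 1L
  }
  if (!length(ends) || ends[length(ends)] < n) ends <- c(ends, n)
  starts <- c(1L, ends[-length(ends)] + 1L)
  # trim leading whitespace of each sentence
  out <- data.frame(start = integer(length(ends)), end = ends)
  for (k in seq_along(ends)) {
    s <- starts[k]
    while (s < ends[k] && grepl("^\\s$", chars[s])) s <- s + 1L
    out$start[k] <- s - 1L   # to 0-based
  }
  keep <- out$start < out$end
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Index of the sentence containing each character span
#'
#' @param spans data.frame with `start`, `end` (0-based half-open).
#' @param sentences output of [split_sentences()].
#' @return integer vector: sentence index of each span's start (NA if text
#'   has no sentences).
#' @keywords internal
sentence_of <- function(spans, sentences) {
  vapply(seq_len(nrow(spans)), function(i) {
    hit <- which(sentences$start <= spans$start[i] & spans$start[i] < sentences$end)
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
}
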
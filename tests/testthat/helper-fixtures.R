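# Shared fixtures.
#
# worked_example(): the canonical single-sentence abstract used throughout
# the documentation: one RNAi perturbation of a lncRNA with four observed
# outcomes in the same cell line, annotated with 9 entities and 4 link
# groups that all share the perturbing action. Its gold pair closure has
# 18 pairs out of the 36 candidate pairs.

worked_example_text <- function() {
  paste("Silencing Lnc-EPIC1 by siRNA targeting could significantly inhibit",
        "the cell growth and colony formation ability of PC cells and",
        "induced G1/S cell cycle arrest and apoptosis in PC cells.")
}

# locate the n-th occurrence of `phrase` in `text`, 0-based half-open
phrase_span <- function(text, phrase, occurrence = 1L) {
  hits <- gregexpr(phrase, text, fixed = TRUE)[[1]]
  stopifnot(hits[1] != -1, length(hits) >= occurrence)
  start <- hits[occurrence] - 1L
  c(start = start, end = start + nchar(phrase))
}

worked_example <- function() {
  text <- worked_example_text()
  mk <- function(id, category, assertion, phrase, occ = 1L) {
    sp <- phrase_span(text, phrase, occ)
    data.frame(id = id, category = category, assertion = assertion,
               start = sp["start"], end = sp["end"],
               stringsAsFactors = FALSE)
  }
  mentions <- rbind(
    mk("T1", "PerturbingAction", "RNAi/knockdown",
       "Silencing Lnc-EPIC1 by siRNA targeting"),
    mk("T2", "Effect", "Negative", "significantly inhibit"),
    mk("T3", "Phenotype", "Cell growth", "cell growth"),
    mk("T4", "Phenotype", "Colony formation", "colony formation ability"),
    mk("T5", "Context", "Transformed cells", "PC cells", 1L),
    mk("T6", "Effect", "Positive", "induced"),
    mk("T7", "Phenotype", "Cell cycle arrest", "G1/S cell cycle arrest"),
    mk("T8", "Phenotype", "Apoptosis", "apoptosis"),
    mk("T9", "Context", "Transformed cells", "PC cells", 2L)
  )
  links <- data.frame(
    id = c("L1", "L2", "L3", "L4"),
    PerturbingAction = "T1",
    Context = c("T5", "T5", "T9", "T9"),
    Effect = c("T2", "T2", "T6", "T6"),
    Phenotype = c("T3", "T4", "T7", "T8"),
    stringsAsFactors = FALSE
  )
  fg_document("worked-example", text, mentions, links)
}

# a tiny deterministic tokenizer for codec tests
tiny_tokenizer <- function(texts) {
  train_tokenizer(texts, vocab_size = 500, min_count = 1)
}
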
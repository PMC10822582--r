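#' Configuration of the synthetic annotated-corpus generator
#'
#' The generator writes abstract-like documents whose experiment sentences
#' follow the annotation schema: each experiment has one perturbing-action
#' phrase and one or more (effect, phenotype, context) clauses, every clause
#' forming a link group that reuses the experiment's perturbing action — the
#' pattern in which one perturbation drives several observed outcomes.
#' Defaults are the study conditions.
#'
#' @param n_docs corpus size (default 800, the released-corpus scale).
#' @param experiments_per_doc integer vector to sample the number of
#'   experiments per document from.
#' @param groups_per_experiment integer vector to sample the number of link
#'   groups per experiment from.
#' @param p_multisentence probability that a group beyond an experiment's
#'   first is rendered as its own follow-up sentence (anaphoric, with no
#'   repeated perturbing-action mention), creating cross-sentence links.
#' @param p_distractor probability of an unannotated framing sentence at
#'   the start and at the end of a document.
#' @param p_unlinked probability that an experiment slot is rendered as
#'   framing prose mentioning a phenotype and a context without any
#'   perturbation: annotated entities outside a complete experiment
#'   description, which therefore belong to no link group.
#' @param assertion_skew Zipf exponent of the assertion distribution inside
#'   each category: sampling weight of the `r`-th assertion is
#'   `1 / r^assertion_skew`; 0 is uniform. The default 1 makes late-listed
#'   assertions rare, as in real abstracts.
#' @return a config list.
#' @export
fg_synth_config <- function(n_docs = 800L, experiments_per_doc = 1:2,
                            groups_per_experiment = 1:4,
                            p_multisentence = 0.25, p_distractor = 0.3,
                            p_unlinked = 0.2, assertion_skew = 1) {
  list(n_docs = as.integer(n_docs),
       experiments_per_doc = as.integer(experiments_per_doc),
       groups_per_experiment = as.integer(groups_per_experiment),
       p_multisentence = p_multisentence, p_distractor = p_distractor,
       p_unlinked = p_unlinked, assertion_skew = assertion_skew)
}

# ---- lexicons ---------------------------------------------------------

synth_gene_pool <- function() {
  pre <- c("TR", "KL", "MB", "SX", "PD", "RH", "ZN", "ACT", "FY", "GV",
           "LNC", "MIR", "WD", "EPH", "CSK")
  as.vector(outer(pre, 1:9, paste0))
}

synth_drug_pool <- function() {
  pre <- c("vora", "selu", "drima", "palbo", "tozi", "refa", "quina", "milo")
  suf <- c("tinib", "ciclib", "sertib", "parib")
  as.vector(outer(pre, suf, paste0))
}

# perturbing-action phrase templates; {G} gene, {D} drug
synth_pa_templates <- function() {
  list(
    "Gene loss-of-function" = c("knockout of {G}", "genetic ablation of {G}",
                                "{G} deletion"),
    "Gene gain-of-function" = c("overexpression of {G}",
                                "ectopic expression of {G}"),
    "RNAi/knockdown" = c("siRNA-mediated knockdown of {G}",
                         "silencing of {G} by shRNA", "{G} knockdown"),
    "Pharmacological inhibition" = c(
      "pharmacological inhibition of {G} with {D}",
      "treatment with the {G} inhibitor {D}"),
    "Pharmacological augmentation" = c(
      "pharmacological activation of {G} by {D}",
      "treatment with the {G} agonist {D}"),
    "Other" = c("mutation of {G}", "aberrant splicing of {G}")
  )
}

synth_effect_phrases <- function() {
  list(
    Positive = c("significantly promoted", "markedly increased", "enhanced"),
    Negative = c("significantly inhibited", "suppressed", "markedly reduced"),
    Regulates = c("regulated", "modulated"),
    Rescues = c("rescued", "restored"),
    "No effect" = c("did not affect", "had no effect on")
  )
}

synth_context_phrases <- function() {
  list(
    Patient = c("patients", "patients with advanced disease"),
    Organism = c("nude mice", "zebrafish embryos"),
    "Tissue/organ" = c("liver tissue", "colonic epithelium"),
    Neoplasm = c("primary tumours", "carcinoma specimens"),
    Graft = c("syngeneic allografts", "allografts"),
    Xenograft = c("subcutaneous xenografts", "xenograft models"),
    Cells = c("primary fibroblasts", "normal epithelial cells"),
    "Transformed cells" = c("cancer cells", "transformed cell lines"),
    Organoid = c("patient-derived organoids", "intestinal organoids"),
    "In vitro" = c("in vitro"),
    "In vivo" = c("in vivo")
  )
}

synth_phenotype_phrases <- function(schema = fg_schema()) {
  extra <- list(
    Apoptosis = "apoptotic cell death",
    "Cell cycle arrest" = "G1/S cell cycle arrest",
    "Epithelial-mesenchymal transition" = "EMT",
    "Tumour growth" = "tumor growth",
    Proliferation = "cell proliferation",
    Invasion = "invasive capacity",
    Migration = "migratory capacity",
    "Colony formation" = "colony formation ability"
  )
  out <- lapply(schema$assertions$Phenotype, function(a) {
    c(tolower(a), extra[[a]])
  })
  stats::setNames(out, schema$assertions$Phenotype)
}

synth_distractors <- function() {
  c("The underlying molecular mechanism remains incompletely understood.",
    "These findings point to a potential therapeutic vulnerability.",
    "Recent work has linked this pathway to poor clinical outcome.",
    "We therefore examined the functional consequences of this dependency.",
    "Taken together, the data support a central role for this axis.")
}

# ---- generation -------------------------------------------------------

# Zipf-weighted assertion index within one category
sample_assertion <- function(vocab, skew) {
  w <- 1 / seq_along(vocab)^skew
  sample(seq_along(vocab), 1L, prob = w / sum(w))
}

# a chunk is list(text, category = NULL, assertion = NULL)
chunk <- function(text, category = NULL, assertion = NULL) {
  list(text = text, category = category, assertion = assertion)
}

fill_pa <- function(template, genes, drugs) {
  out <- sub("{G}", sample(genes, 1L), template, fixed = TRUE)
  sub("{D}", sample(drugs, 1L), out, fixed = TRUE)
}

#' Generate a synthetic annotated corpus
#'
#' Produces `config$n_docs` validated [fg_document()]s whose annotations
#' exercise the whole schema: all four categories, skewed assertion
#' distributions, perturbing actions shared by several link groups,
#' cross-sentence groups, annotated-but-unlinked entities and unannotated
#' distractor sentences. The true annotation counts accumulated during
#' generation are attached as `attr(corpus, "bookkeeping")` (same shape as
#' [corpus_stats()]) so parsing and counting can be verified independently.
#'
#' @param config an [fg_synth_config()].
#' @param seed RNG seed (generation is fully reproducible).
#' @param schema an [fg_schema()].
#' @return list of [fg_document()] with a `bookkeeping` attribute.
#' @export
generate_corpus <- function(config = fg_synth_config(), seed = 1L,
                            schema = fg_schema()) {
  set.seed(seed)
  genes <- synth_gene_pool()
  drugs <- synth_drug_pool()
  pa_tpl <- synth_pa_templates()
  eff <- synth_effect_phrases()
  ctx <- synth_context_phrases()
  phe <- synth_phenotype_phrases(schema)
  distract <- synth_distractors()

  book <- list(
    n_docs = config$n_docs, n_mentions = 0L, n_linked_mentions = 0L,
    n_link_groups = 0L,
    per_category = stats::setNames(integer(4), schema$categories),
    per_assertion = lapply(schema$assertions,
                           function(a) stats::setNames(integer(length(a)), a))
  )

  docs <- vector("list", config$n_docs)
  for (d in seq_len(config$n_docs)) {
    sentences <- list()   # each: list of chunks
    groups <- list()      # each: character(4) mention keys, names = categories
    # mention keys are "<sentence>:<chunk>" resolved to ids after layout
    new_clause <- function(e_a, p_a, c_a) {
      list(chunk(sample(eff[[e_a]], 1L), "Effect", e_a),
           chunk(sample(phe[[p_a]], 1L), "Phenotype", p_a),
           chunk("in"),
           chunk(sample(ctx[[c_a]], 1L), "Context", c_a))
    }

    if (stats::runif(1) < config$p_distractor) {
      sentences[[length(sentences) + 1L]] <- list(chunk(sample(distract, 1L)))
    }
    # draw from the given value set (sample() on a numeric scalar would
    # draw from 1:x instead)
    draw <- function(x) if (length(x) == 1L) x else sample(x, 1L)
    n_exp <- draw(config$experiments_per_doc)
    for (e in seq_len(n_exp)) {
      pa_a <- schema$assertions$PerturbingAction[[
        sample_assertion(schema$assertions$PerturbingAction,
                         config$assertion_skew)]]
      pa_chunk <- chunk(fill_pa(sample(pa_tpl[[pa_a]], 1L), genes, drugs),
                        "PerturbingAction", pa_a)
      n_grp <- draw(config$groups_per_experiment)
      if (stats::runif(1) < config$p_unlinked) {
        # entities mentioned outside a complete experiment description:
        # framing prose references a phenotype and context without any
        # perturbation, so the mentions are annotated but not linkable
        p_a <- schema$assertions$Phenotype[[
          sample_assertion(schema$assertions$Phenotype, config$assertion_skew)]]
        c_a <- schema$assertions$Context[[
          sample_assertion(schema$assertions$Context, config$assertion_skew)]]
        lead <- sample(c("little is known about", "previous reports described",
                         "conflicting data exist regarding",
                         "earlier work characterised"), 1L)
        sentences[[length(sentences) + 1L]] <- list(
          chunk(lead),
          chunk(sample(phe[[p_a]], 1L), "Phenotype", p_a),
          chunk("in"),
          chunk(sample(ctx[[c_a]], 1L), "Context", c_a))
        next
      }
      clauses <- lapply(seq_len(n_grp), function(g) {
        new_clause(
          schema$assertions$Effect[[
            sample_assertion(schema$assertions$Effect, config$assertion_skew)]],
          schema$assertions$Phenotype[[
            sample_assertion(schema$assertions$Phenotype, config$assertion_skew)]],
          schema$assertions$Context[[
            sample_assertion(schema$assertions$Context, config$assertion_skew)]])
      })
      # first sentence: PA + first clause (+ in-sentence extra clauses)
      main <- c(list(pa_chunk), clauses[[1]])
      follow <- list()
      if (n_grp > 1) {
        for (g in seq(2, n_grp)) {
          if (stats::runif(1) < config$p_multisentence) {
            follow[[length(follow) + 1L]] <-
              c(list(chunk("It also")), clauses[[g]])
          } else {
            main <- c(main, list(chunk("and")), clauses[[g]])
          }
        }
      }
      exp_sent <- c(list(main), follow)
      first_sent_idx <- length(sentences) + 1L
      sentences <- c(sentences, exp_sent)
      # one group per clause, all sharing the PA mention
      pa_key <- paste0(first_sent_idx, ":1")
      for (si in seq_along(exp_sent)) {
        cks <- exp_sent[[si]]
        kk <- which(vapply(cks, function(x) !is.null(x$category), logical(1)))
        kk <- kk[vapply(cks[kk], `[[`, character(1), "category") !=
                   "PerturbingAction"]
        # chunks come in clause order: Effect, Phenotype, Context triples
        for (start in seq(1, length(kk), by = 3)) {
          trio <- cks[kk[start:(start + 2)]]
          keys <- paste0(first_sent_idx + si - 1L, ":", kk[start:(start + 2)])
          names(keys) <- vapply(trio, `[[`, character(1), "category")
          groups[[length(groups) + 1L]] <-
            c(PerturbingAction = pa_key, keys)[schema$categories]
        }
      }
    }
    if (stats::runif(1) < config$p_distractor) {
      sentences[[length(sentences) + 1L]] <- list(chunk(sample(distract, 1L)))
    }

    # ---- layout: join chunks with spaces, end each sentence with "." ----
    text <- ""
    mention_rows <- list()
    key_to_id <- character()
    for (si in seq_along(sentences)) {
      for (ci in seq_along(sentences[[si]])) {
        ck <- sentences[[si]][[ci]]
        if (ci == 1L) {
          # sentence-initial capitalisation (keeps the splitter's boundary
          # rule satisfied and matches real abstracts)
          ck$text <- paste0(toupper(substring(ck$text, 1, 1)),
                            substring(ck$text, 2))
        }
        if (nzchar(text)) text <- paste0(text, " ")
        start <- nchar(text)
        text <- paste0(text, ck$text)
        if (!is.null(ck$category)) {
          id <- paste0("T", length(mention_rows) + 1L)
          mention_rows[[length(mention_rows) + 1L]] <-
            data.frame(id = id, category = ck$category,
                       assertion = ck$assertion, start = start,
                       end = nchar(text), stringsAsFactors = FALSE)
          key_to_id[paste0(si, ":", ci)] <- id
          book$per_category[ck$category] <-
            book$per_category[ck$category] + 1L
          book$per_assertion[[ck$category]][ck$assertion] <-
            book$per_assertion[[ck$category]][ck$assertion] + 1L
        }
      }
      if (!grepl("\\.$", text)) text <- paste0(text, ".")
    }
    book$n_mentions <- book$n_mentions + length(mention_rows)

    links <- NULL
    if (length(groups)) {
      links <- do.call(rbind, lapply(seq_along(groups), function(k) {
        ids <- key_to_id[groups[[k]]]
        as.data.frame(c(list(id = paste0("L", k)),
                        as.list(stats::setNames(ids, schema$categories))),
                      stringsAsFactors = FALSE)
      }))
      book$n_link_groups <- book$n_link_groups + length(groups)
      book$n_linked_mentions <- book$n_linked_mentions +
        length(unique(unlist(lapply(groups, function(g) key_to_id[g]))))
    }
    docs[[d]] <- fg_document(sprintf("synth-%04d", d), text,
                             do.call(rbind, mention_rows), links,
                             schema = schema)
  }
  attr(docs, "bookkeeping") <- structure(book, class = "fg_corpus_stats")
  docs
}
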
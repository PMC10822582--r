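#' The annotation schema: four entity categories and their assertions
#'
#' An experiment description is annotated with four categories of entity:
#' a *perturbing action* (an experimental manipulation of a named gene),
#' the *context* it was performed in (cells, organisms, xenografts, ...),
#' the *phenotype* it changed (apoptosis, proliferation, ...) and the
#' *effect* direction (positive, negative, ...). Each marked entity
#' additionally carries one assertion label from its category's controlled
#' vocabulary: 6 perturbing-action, 11 context, 5 effect and 31 phenotype
#' assertions.
#'
#' @return A list with elements `categories` (character vector of the four
#'   category names, in canonical order) and `assertions` (named list mapping
#'   each category to its ordered assertion vocabulary).
#' @examples
#' sch <- fg_schema()
#' lengths(sch$assertions)
#' @export
fg_schema <- function() {
  categories <- c("PerturbingAction", "Context", "Effect", "Phenotype")
  assertions <- list(
    PerturbingAction = c(
      "Gene loss-of-function", "Gene gain-of-function", "RNAi/knockdown",
      "Pharmacological inhibition", "Pharmacological augmentation", "Other"
    ),
    Context = c(
      "Patient", "Organism", "Tissue/organ", "Neoplasm", "Graft", "Xenograft",
      "Cells", "Transformed cells", "Organoid", "In vitro", "In vivo"
    ),
    Effect = c("Positive", "Negative", "Regulates", "Rescues", "No effect"),
    Phenotype = c(
      # cell-death terms
      "Apoptosis", "Anoikis", "Autophagy", "Cell death", "Entosis",
      "Ferroptosis", "Mitophagy", "Necroptosis", "Necrosis", "Oncosis",
      "Pyroptosis",
      # cancer terms
      "Metastasis", "Transformation", "Tumour growth", "Tumourigenesis",
      "Tumour initiation", "Tumour progression", "Tumour regression",
      # general cell-biology terms
      "Adhesion", "Cell cycle arrest", "Cell growth", "Cell survival",
      "Colony formation", "Differentiation",
      "Epithelial-mesenchymal transition", "Invasion", "Migration",
      "Proliferation", "Quiescence", "Self-renewal", "Senescence"
    )
  )
  structure(list(categories = categories, assertions = assertions),
            class = "fg_schema")
}

#' @export
print.fg_schema <- function(x, ...) {
  cat("<fg_schema> 4 categories\n")
  for (cat_ in x$categories) {
    cat(sprintf("  %-17s %2d assertions\n", cat_, length(x$assertions[[cat_]])))
  }
  invisible(x)
}

#' Canonicalise a category or assertion name
#'
#' Matching is case-insensitive and tolerant of hyphen/space variation so that
#' labels from external annotation files map onto the canonical vocabulary.
#'
#' @param x character vector of labels.
#' @param choices canonical vocabulary to match into.
#' @return character vector of canonical names; `NA` where no match exists.
#' @keywords internal
fg_match_label <- function(x, choices) {
  norm <- function(s) gsub("[^a-z0-9]+", "", tolower(s))
  choices[match(norm(x), norm(choices))]
}

#' BIO label space for the category head
#'
#' The first label space tags each word with its entity category: `O` plus
#' `B-`/`I-` variants of the four categories (9 labels).
#'
#' @param schema an [fg_schema()].
#' @return character vector of labels, `O` first.
#' @export
fg_category_space <- function(schema = fg_schema()) {
  c("O", as.vector(rbind(paste0("B-", schema$categories),
                         paste0("I-", schema$categories))))
}

#' BIO label space for one assertion head
#'
#' Each category has its own assertion head whose label space is `O` plus
#' `B-`/`I-` variants of that category's assertions.
#'
#' @param category one of the four category names.
#' @inheritParams fg_category_space
#' @return character vector of labels, `O` first.
#' @export
fg_assertion_space <- function(category, schema = fg_schema()) {
  stopifnot(category %in% schema$categories)
  a <- schema$assertions[[category]]
  c("O", as.vector(rbind(paste0("B-", a), paste0("I-", a))))
}

#' All five BIO label spaces
#'
#' @inheritParams fg_category_space
#' @return named list: `category` plus one element per category name.
#' @export
fg_label_spaces <- function(schema = fg_schema()) {
  spaces <- c(list(category = fg_category_space(schema)),
              lapply(stats::setNames(schema$categories, schema$categories),
                     fg_assertion_space, schema = schema))
  spaces
}
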
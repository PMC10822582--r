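#' Read gene-mention annotations from a tab-separated file
#'
#' Gene grounding comes from an external gene tagger whose output is a TSV
#' with one row per gene mention: document id, 0-based half-open character
#' span and gene symbol. Extra columns are ignored.
#'
#' @param path file path.
#' @return data.frame with columns `doc_id`, `start`, `end`, `gene`.
#' @export
read_gene_mentions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("doc_id", "start", "end", "gene")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("gene-mention file lacks column(s): ", paste(miss, collapse = ", "))
  }
  df$doc_id <- as.character(df$doc_id)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$gene <- as.character(df$gene)
  df[need]
}

#' Attach gene symbols to a document's perturbing-action mentions
#'
#' A perturbing action is grounded to the gene whose mention span overlaps
#' it (the gene symbol sits inside phrases like "knockdown of X"). When
#' several gene mentions overlap one perturbing action, the leftmost wins;
#' perturbing actions without any overlapping gene get `NA`.
#'
#' @param doc an [fg_document()].
#' @param gene_mentions data.frame as from [read_gene_mentions()] (rows for
#'   other documents are ignored via `doc_id`).
#' @return data.frame with columns `id` (mention id) and `gene`, one row
#'   per perturbing-action mention.
#' @export
attach_genes <- function(doc, gene_mentions) {
  g <- gene_mentions[gene_mentions$doc_id == doc$doc_id, , drop = FALSE]
  g <- g[order(g$start), , drop = FALSE]
  pa <- doc$mentions[doc$mentions$category == "PerturbingAction", ,
                     drop = FALSE]
  gene <- vapply(seq_len(nrow(pa)), function(i) {
    hit <- which(g$start < pa$end[i] & pa$start[i] < g$end)
    if (length(hit)) g$gene[hit[1]] else NA_character_
  }, character(1))
  data.frame(id = pa$id, gene = gene, stringsAsFactors = FALSE)
}

#' Flatten extracted link groups into case-study records
#'
#' One record per link group: the grounded gene plus the assertion labels
#' of the group's four members. This is the unit that case-study
#' aggregations count.
#'
#' @param corpus list of [fg_document()]s (gold or predicted) with link
#'   groups.
#' @param gene_mentions optional data.frame from [read_gene_mentions()];
#'   without it, `gene` is `NA` throughout.
#' @return data.frame with columns `doc_id`, `link_id`, `gene`,
#'   `perturbing_action`, `context`, `effect`, `phenotype` (assertion
#'   labels).
#' @export
build_records <- function(corpus, gene_mentions = NULL) {
  schema <- fg_schema()
  rows <- lapply(corpus, function(doc) {
    l <- doc$links
    if (!nrow(l)) return(NULL)
    genes <- if (is.null(gene_mentions)) {
      data.frame(id = character(), gene = character())
    } else attach_genes(doc, gene_mentions)
    assertion_of <- stats::setNames(doc$mentions$assertion, doc$mentions$id)
    data.frame(
      doc_id = doc$doc_id, link_id = l$id,
      gene = genes$gene[match(l$PerturbingAction, genes$id)],
      perturbing_action = unname(assertion_of[l$PerturbingAction]),
      context = unname(assertion_of[l$Context]),
      effect = unname(assertion_of[l$Effect]),
      phenotype = unname(assertion_of[l$Phenotype]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(doc_id = character(), link_id = character(),
                      gene = character(), perturbing_action = character(),
                      context = character(), effect = character(),
                      phenotype = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Keep only fully grounded case-study records
#'
#' @param records data.frame from [build_records()].
#' @return the rows whose `gene` is known.
#' @export
filter_complete <- function(records) {
  out <- records[!is.na(records$gene) & nzchar(records$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Coarse groupings of the context vocabulary
#'
#' Two orthogonal binary groupings used in aggregate analyses. `"assay"`
#' splits contexts into in-vitro-like (`Cells`, `Transformed cells`,
#' `In vitro`, `Organoid`) and in-vivo-like (`Organism`, `Neoplasm`,
#' `Tissue/organ`, `In vivo`, `Xenograft`). `"malignancy"` splits them into
#' non-cancer (`Organism`, `Tissue/organ`, `Cells`, `Organoid`,
#' `In vitro`, `In vivo`) and cancer (`Transformed cells`, `Neoplasm`,
#' `Xenograft`). Context assertions outside a grouping (`Patient`;
#' `Graft`) fall into `"Unclassified"`.
#'
#' @param context character vector of context assertion labels.
#' @param scheme `"assay"` or `"malignancy"`.
#' @return character vector: `"In vitro-like"`/`"In vivo-like"` or
#'   `"Cancer"`/`"Non-cancer"`, with `"Unclassified"` for the rest.
#' @export
context_group <- function(context, scheme = c("assay", "malignancy")) {
  scheme <- match.arg(scheme)
  groups <- if (scheme == "assay") {
    list("In vitro-like" = c("Cells", "Transformed cells", "In vitro",
                             "Organoid"),
         "In vivo-like" = c("Organism", "Neoplasm", "Tissue/organ",
                            "In vivo", "Xenograft"))
  } else {
    list("Non-cancer" = c("Organism", "Tissue/organ", "Cells", "Organoid",
                          "In vitro", "In vivo"),
         "Cancer" = c("Transformed cells", "Neoplasm", "Xenograft"))
  }
  out <- rep("Unclassified", length(context))
  for (nm in names(groups)) out[context %in% groups[[nm]]] <- nm
  out
}

#' Aggregate case-study records into counts
#'
#' Counts records per gene (`by = "gene"`) or per gene and
#' perturbing-action assertion (`by = "gene_pa"`), cross-tabulated with
#' effect direction and the two context groupings of [context_group()].
#'
#' @param records data.frame from [build_records()] (usually after
#'   [filter_complete()]).
#' @param by `"gene"` or `"gene_pa"`.
#' @return data.frame of group keys plus `n` (record count), `n_positive`,
#'   `n_negative` (effect directions), `n_in_vitro`, `n_in_vivo`,
#'   `n_cancer`, `n_non_cancer` (context groupings; unclassified contexts
#'   count only in `n`), sorted by decreasing `n`.
#' @export
case_study_counts <- function(records, by = c("gene", "gene_pa")) {
  by <- match.arg(by)
  keys <- if (by == "gene") "gene" else c("gene", "perturbing_action")
  assay <- context_group(records$context, "assay")
  malig <- context_group(records$context, "malignancy")
  key <- do.call(paste, c(records[keys], sep = "\r"))
  # tapply groups in sorted key order; build the key frame to match
  agg <- function(x) as.vector(tapply(as.numeric(x), key, sum))
  uk <- which(!duplicated(key))
  out <- records[uk[match(sort(unique(key)), key[uk])], keys, drop = FALSE]
  out$n <- agg(rep(1L, nrow(records)))
  out$n_positive <- agg(records$effect == "Positive")
  out$n_negative <- agg(records$effect == "Negative")
  out$n_in_vitro <- agg(assay == "In vitro-like")
  out$n_in_vivo <- agg(assay == "In vivo-like")
  out$n_cancer <- agg(malig == "Cancer")
  out$n_non_cancer <- agg(malig == "Non-cancer")
  out <- out[order(-out$n), , drop = FALSE]
  rownames(out) <- NULL
  out
}
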
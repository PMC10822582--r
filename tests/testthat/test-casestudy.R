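gene_tsv <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("gene-mention files are read and validated", {
  df <- data.frame(doc_id = "worked-example", start = 10L, end = 19L,
                   gene = "EPIC1", extra = "ignored")
  gm <- read_gene_mentions(gene_tsv(df))
  expect_named(gm, c("doc_id", "start", "end", "gene"))
  expect_identical(gm$gene, "EPIC1")
  bad <- data.frame(doc_id = "x", begin = 1L)
  expect_error(read_gene_mentions(gene_tsv(bad)), "lacks column")
})

test_that("genes attach to overlapping perturbing actions, leftmost first", {
  doc <- worked_example()
  # "Lnc-EPIC1" sits inside the perturbing-action span [0, 38)
  gm <- data.frame(doc_id = "worked-example", start = 10L, end = 19L,
                   gene = "EPIC1", stringsAsFactors = FALSE)
  att <- attach_genes(doc, gm)
  expect_identical(att, data.frame(id = "T1", gene = "EPIC1",
                                   stringsAsFactors = FALSE))
  # non-overlapping and other-document mentions are ignored
  gm2 <- rbind(gm, data.frame(doc_id = "worked-example", start = 100L,
                              end = 105L, gene = "WRONG"),
               data.frame(doc_id = "other", start = 10L, end = 19L,
                          gene = "OTHER"))
  expect_identical(attach_genes(doc, gm2)$gene, "EPIC1")
  # two overlapping genes: the leftmost wins
  gm3 <- rbind(data.frame(doc_id = "worked-example", start = 20L, end = 25L,
                          gene = "LATER"), gm)
  expect_identical(attach_genes(doc, gm3)$gene, "EPIC1")
  # no overlap at all gives NA
  expect_true(is.na(attach_genes(doc, gm[0, ])$gene))
})

test_that("build_records flattens one row per link group", {
  doc <- worked_example()
  gm <- data.frame(doc_id = "worked-example", start = 10L, end = 19L,
                   gene = "EPIC1", stringsAsFactors = FALSE)
  rec <- build_records(list(doc), gm)
  expect_identical(nrow(rec), 4L)
  expect_identical(unique(rec$gene), "EPIC1")
  expect_identical(unique(rec$perturbing_action), "RNAi/knockdown")
  expect_identical(unique(rec$context), "Transformed cells")
  expect_setequal(rec$effect, c("Negative", "Positive"))
  expect_setequal(rec$phenotype, c("Cell growth", "Colony formation",
                                   "Cell cycle arrest", "Apoptosis"))
  # without gene mentions the gene column is NA but rows remain
  rec2 <- build_records(list(doc))
  expect_identical(nrow(rec2), 4L)
  expect_true(all(is.na(rec2$gene)))
  expect_identical(nrow(filter_complete(rec2)), 0L)
  expect_identical(nrow(filter_complete(rec)), 4L)
  # a corpus with no links yields an empty, well-typed frame
  empty <- build_records(list(fg_document("e", "No annotations.")))
  expect_identical(nrow(empty), 0L)
  expect_named(empty, c("doc_id", "link_id", "gene", "perturbing_action",
                        "context", "effect", "phenotype"))
})

test_that("context groupings split the vocabulary as documented", {
  ctx <- c("Cells", "Transformed cells", "Neoplasm", "Organism",
           "Patient", "Xenograft", "In vitro", "Graft")
  expect_identical(context_group(ctx, "assay"),
                   c("In vitro-like", "In vitro-like", "In vivo-like",
                     "In vivo-like", "Unclassified", "In vivo-like",
                     "In vitro-like", "Unclassified"))
  expect_identical(context_group(ctx, "malignancy"),
                   c("Non-cancer", "Cancer", "Cancer", "Non-cancer",
                     "Unclassified", "Cancer", "Non-cancer", "Unclassified"))
  # every context assertion lands in exactly one group per scheme
  vocab <- fg_schema()$assertions$Context
  for (scheme in c("assay", "malignancy")) {
    g <- context_group(vocab, scheme)
    expect_length(g, length(vocab))
    expect_true(all(nzchar(g)))
  }
})

test_that("case_study_counts aggregates by gene and by gene/perturbation", {
  rec <- data.frame(
    doc_id = "d", link_id = paste0("L", 1:5),
    gene = c("A", "A", "A", "B", "B"),
    perturbing_action = c("RNAi/knockdown", "RNAi/knockdown", "Drug/agonism",
                          "RNAi/knockdown", "RNAi/knockdown"),
    context = c("Transformed cells", "Xenograft", "Patient", "Cells",
                "Neoplasm"),
    effect = c("Negative", "Negative", "Positive", "Negative", "Positive"),
    phenotype = "Cell growth", stringsAsFactors = FALSE)
  by_gene <- case_study_counts(rec, by = "gene")
  expect_identical(by_gene$gene, c("A", "B"))   # sorted by decreasing n
  expect_identical(by_gene$n, c(3, 2))
  a <- by_gene[by_gene$gene == "A", ]
  expect_identical(a$n_negative, 2)
  expect_identical(a$n_positive, 1)
  expect_identical(a$n_in_vitro, 1)  # Transformed cells
  expect_identical(a$n_in_vivo, 1)   # Xenograft; Patient is unclassified
  expect_identical(a$n_cancer, 2)
  expect_identical(a$n_non_cancer, 0)
  by_pa <- case_study_counts(rec, by = "gene_pa")
  expect_identical(nrow(by_pa), 3L)
  expect_identical(by_pa$n[by_pa$gene == "A" &
                             by_pa$perturbing_action == "RNAi/knockdown"], 2)
})
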
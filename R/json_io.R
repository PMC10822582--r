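#' JSON interchange format
#'
#' One JSON object per document. The schema is frozen as:
#' ```
#' {
#'   "doc_id":   "...",
#'   "text":     "...",
#'   "mentions": [{"id","category","assertion","start","end","surface"}, ...],
#'   "links":    [{"id", "members": {"PerturbingAction": "...", "Context": "...",
#'                                   "Effect": "...", "Phenotype": "..."}}, ...]
#' }
#' ```
#' Spans are 0-based half-open character offsets into `text`.
#' `read_json_doc(write_json_doc(d))` is the identity for every valid
#' document.
#'
#' @param doc an [fg_document()].
#' @param pretty pretty-print the JSON.
#' @return `write_json_doc`: a JSON string. `read_json_doc`: a validated
#'   [fg_document()].
#' @name json_interchange
NULL

#' @rdname json_interchange
#' @export
write_json_doc <- function(doc, pretty = FALSE) {
  m <- doc$mentions
  mentions <- lapply(seq_len(nrow(m)), function(i) {
    list(id = m$id[i], category = m$category[i], assertion = m$assertion[i],
         start = m$start[i], end = m$end[i], surface = m$surface[i])
  })
  l <- doc$links
  cats <- fg_schema()$categories
  links <- lapply(seq_len(nrow(l)), function(i) {
    list(id = l$id[i],
         members = as.list(stats::setNames(unlist(l[i, cats]), cats)))
  })
  obj <- list(doc_id = doc$doc_id, text = doc$text,
              mentions = mentions, links = links)
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = pretty,
                                null = "null"))
}

#' @rdname json_interchange
#' @param json a JSON string (or path handled by [jsonlite::fromJSON()]'s
#'   string form is *not* accepted: pass text).
#' @param schema an [fg_schema()].
#' @export
read_json_doc <- function(json, schema = fg_schema()) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  for (key in c("doc_id", "text", "mentions", "links")) {
    if (is.null(obj[[key]])) stop("JSON document missing required key '", key, "'")
  }
  mentions <- if (length(obj$mentions)) {
    do.call(rbind, lapply(obj$mentions, function(mm) {
      for (key in c("id", "category", "assertion", "start", "end")) {
        if (is.null(mm[[key]])) {
          stop("mention object missing required key '", key, "'")
        }
      }
      data.frame(id = mm$id, category = mm$category, assertion = mm$assertion,
                 start = mm$start, end = mm$end, stringsAsFactors = FALSE)
    }))
  } else NULL
  links <- if (length(obj$links)) {
    do.call(rbind, lapply(obj$links, function(ll) {
      if (is.null(ll$id)) stop("link object missing required key 'id'")
      if (is.null(ll$members)) stop("link object missing required key 'members'")
      row <- list(id = ll$id)
      for (cat_ in schema$categories) {
        row[[cat_]] <- if (is.null(ll$members[[cat_]])) NA_character_ else
          ll$members[[cat_]]
      }
      as.data.frame(row, stringsAsFactors = FALSE)
    }))
  } else NULL
  fg_document(obj$doc_id, obj$text, mentions, links, schema = schema)
}

#' Write a corpus to a directory, one JSON file per document
#'
#' @param docs list of [fg_document()].
#' @param dir output directory (created if needed).
#' @param format `"json"` or `"xml"`.
#' @return the file paths, invisibly.
#' @export
write_corpus <- function(docs, dir, format = c("json", "xml")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(docs, function(d) {
    p <- file.path(dir, paste0(d$doc_id, ".", format))
    if (format == "json") writeLines(write_json_doc(d), p)
    else write_standoff_xml(d, p)
    p
  }, character(1))
  invisible(paths)
}
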
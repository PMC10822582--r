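#' Read a MAE-style standoff XML annotation file
#'
#' Parses one abstract annotated in the standoff convention produced by the
#' MAE annotation tool: a root element holding a `TEXT` node with the raw
#' abstract, and a `TAGS` node containing one element per marked entity
#' (element name = category, attributes `id`, `spans="start~end"`, `text`,
#' and the assertion) plus `LINK` elements whose `*ID` attributes reference
#' four entity tags, one per category.
#'
#' Span convention: source files carry 0-based half-open `start~end` offsets;
#' this reader is the single place where the external convention is mapped
#' onto the package's internal 0-based half-open spans (here: the identity).
#' Discontinuous spans (`"s1~e1,s2~e2"`) are rejected: the schema marks
#' contiguous phrases only.
#'
#' @param path path to the XML file.
#' @param doc_id document id; defaults to the file name without extension.
#' @param schema an [fg_schema()].
#' @return a validated [fg_document()].
#' @export
read_standoff_xml <- function(path, doc_id = NULL,
                              schema = fg_schema()) {
  x <- xml2::read_xml(path)
  if (is.null(doc_id)) doc_id <- sub("\\.[^.]*$", "", basename(path))

  text_node <- xml2::xml_find_first(x, ".//*[translate(local-name(),'text','TEXT')='TEXT']")
  if (inherits(text_node, "xml_missing")) stop("no TEXT element in ", path)
  text <- xml2::xml_text(text_node)

  tags_node <- xml2::xml_find_first(x, ".//*[translate(local-name(),'tags','TAGS')='TAGS']")
  children <- if (inherits(tags_node, "xml_missing")) list() else
    xml2::xml_children(tags_node)

  mentions <- empty_mentions()
  links <- empty_links(schema)
  for (node in children) {
    nm <- xml2::xml_name(node)
    if (toupper(nm) == "LINK") {
      links <- rbind(links, parse_link_node(node, schema))
    } else {
      mentions <- rbind(mentions, parse_extent_node(node, nm, text, schema))
    }
  }
  fg_document(doc_id, text, mentions, links, schema = schema)
}

parse_extent_node <- function(node, nm, text, schema) {
  id <- xml2::xml_attr(node, "id")
  category <- fg_match_label(nm, schema$categories)
  if (is.na(category)) {
    stop("tag ", id, ": unknown category element '", nm, "'")
  }
  spans <- xml2::xml_attr(node, "spans")
  if (is.na(spans)) stop("tag ", id, ": missing spans attribute")
  if (grepl(",", spans, fixed = TRUE)) {
    stop("tag ", id, ": discontinuous span '", spans,
         "' (only contiguous phrases are markable)")
  }
  se <- suppressWarnings(as.integer(strsplit(spans, "~", fixed = TRUE)[[1]]))
  if (length(se) != 2 || anyNA(se)) stop("tag ", id, ": malformed spans '", spans, "'")
  if (se[1] < 0 || se[2] > nchar(text) || se[1] >= se[2]) {
    stop("tag ", id, ": span [", se[1], ",", se[2], ") outside text of length ",
         nchar(text))
  }
  assertion_raw <- xml2::xml_attr(node, "assertion")
  if (is.na(assertion_raw)) {
    # fall back to any attribute whose value matches the category's vocabulary
    attrs <- xml2::xml_attrs(node)
    attrs <- attrs[!names(attrs) %in% c("id", "spans", "text")]
    hit <- which(!is.na(fg_match_label(attrs, schema$assertions[[category]])))
    if (length(hit)) assertion_raw <- attrs[[hit[1]]]
  }
  assertion <- fg_match_label(assertion_raw, schema$assertions[[category]])
  if (is.na(assertion)) {
    stop("tag ", id, ": assertion '", assertion_raw,
         "' is not in the ", category, " vocabulary")
  }
  data.frame(id = id, category = category, assertion = assertion,
             start = se[1], end = se[2],
             surface = substring(text, se[1] + 1L, se[2]),
             stringsAsFactors = FALSE)
}

parse_link_node <- function(node, schema) {
  id <- xml2::xml_attr(node, "id")
  attrs <- xml2::xml_attrs(node)
  member_attrs <- attrs[grepl("ID$", names(attrs)) & names(attrs) != "id"]
  row <- stats::setNames(as.list(rep(NA_character_, 1 + length(schema$categories))),
                         c("id", schema$categories))
  row$id <- id
  for (k in seq_along(member_attrs)) {
    role <- sub("ID$", "", names(member_attrs)[k])
    cat_ <- fg_match_label(role, schema$categories)
    if (is.na(cat_)) stop("link ", id, ": unknown member role '", role, "'")
    row[[cat_]] <- member_attrs[[k]]
  }
  as.data.frame(row, stringsAsFactors = FALSE)
}

#' Write an annotated document as MAE-style standoff XML
#'
#' Inverse of [read_standoff_xml()]: spans are written 0-based half-open as
#' `start~end`, entity elements are named after their category, and `LINK`
#' elements carry one `<Category>ID` attribute per member.
#'
#' @param doc an [fg_document()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_standoff_xml <- function(doc, path) {
  root <- xml2::xml_new_root("fgie")
  text_node <- xml2::xml_add_child(root, "TEXT")
  xml2::xml_add_child(text_node, xml2::xml_cdata(doc$text))
  tags <- xml2::xml_add_child(root, "TAGS")
  m <- doc$mentions
  for (i in seq_len(nrow(m))) {
    xml2::xml_add_child(tags, m$category[i], id = m$id[i],
                        spans = paste0(m$start[i], "~", m$end[i]),
                        text = m$surface[i], assertion = m$assertion[i])
  }
  l <- doc$links
  cats <- fg_schema()$categories
  for (i in seq_len(nrow(l))) {
    args <- c(list(tags, "LINK", id = l$id[i]),
              stats::setNames(as.list(unlist(l[i, cats])), paste0(cats, "ID")))
    do.call(xml2::xml_add_child, args)
  }
  xml2::write_xml(root, path)
  invisible(path)
}

#' Read a directory of standoff XML or interchange JSON files as a corpus
#'
#' @param dir directory containing `.xml` and/or `.json` files, one document
#'   each.
#' @param schema an [fg_schema()].
#' @return list of [fg_document()].
#' @export
read_corpus <- function(dir, schema = fg_schema()) {
  files <- sort(list.files(dir, pattern = "\\.(xml|json)$", full.names = TRUE))
  lapply(files, function(f) {
    if (grepl("\\.xml$", f)) read_standoff_xml(f, schema = schema)
    else read_json_doc(paste(readLines(f, warn = FALSE), collapse = "\n"),
                       schema = schema)
  })
}
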
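#' Construct an annotated document
#'
#' An annotated document couples an abstract's text with its entity mentions
#' and link groups. Mentions are contiguous character spans (0-based,
#' half-open `[start, end)`) labelled with a category and an assertion from
#' the schema; a link group ties together exactly four mentions, one per
#' category, that jointly describe one experiment. A mention may participate
#' in zero, one or several link groups.
#'
#' @param doc_id document identifier.
#' @param text the abstract text.
#' @param mentions a data.frame with columns `id`, `category`, `assertion`,
#'   `start`, `end` (and optionally `surface`, which is recomputed from the
#'   text); may be `NULL` for no mentions.
#' @param links a data.frame with columns `id`, `PerturbingAction`, `Context`,
#'   `Effect`, `Phenotype`, each holding the mention id filling that role;
#'   may be `NULL`.
#' @param schema an [fg_schema()].
#' @param check if `TRUE` (default), stop on any invariant violation.
#' @return an object of class `fg_document`.
#' @seealso [fg_validate()] for the list of enforced invariants.
#' @export
fg_document <- function(doc_id, text, mentions = NULL, links = NULL,
                        schema = fg_schema(), check = TRUE) {
  mentions <- normalise_mentions(mentions, text)
  links <- normalise_links(links, schema)
  doc <- structure(
    list(doc_id = as.character(doc_id), text = as.character(text),
         mentions = mentions, links = links),
    class = "fg_document"
  )
  if (check) {
    v <- fg_validate(doc, schema)
    if (length(v)) {
      stop("invalid document '", doc_id, "':\n  ",
           paste(v, collapse = "\n  "), call. = FALSE)
    }
  }
  doc
}

empty_mentions <- function() {
  data.frame(id = character(), category = character(), assertion = character(),
             start = integer(), end = integer(), surface = character(),
             stringsAsFactors = FALSE)
}

empty_links <- function(schema = fg_schema()) {
  cols <- c("id", schema$categories)
  as.data.frame(stats::setNames(rep(list(character()), length(cols)), cols),
                stringsAsFactors = FALSE)
}

normalise_mentions <- function(mentions, text) {
  if (is.null(mentions) || nrow(as.data.frame(mentions)) == 0) {
    return(empty_mentions())
  }
  m <- as.data.frame(mentions, stringsAsFactors = FALSE)
  need <- c("id", "category", "assertion", "start", "end")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("mentions lack column(s): ", paste(miss, collapse = ", "))
  m$id <- as.character(m$id)
  m$category <- as.character(m$category)
  m$assertion <- as.character(m$assertion)
  m$start <- as.integer(m$start)
  m$end <- as.integer(m$end)
  ok <- !is.na(m$start) & !is.na(m$end) & m$start >= 0 & m$end <= nchar(text) &
    m$start < m$end
  m$surface <- NA_character_
  m$surface[ok] <- substring(text, m$start[ok] + 1L, m$end[ok])
  rownames(m) <- NULL
  m[, c(need, "surface")]
}

normalise_links <- function(links, schema) {
  if (is.null(links) || nrow(as.data.frame(links)) == 0) {
    return(empty_links(schema))
  }
  l <- as.data.frame(links, stringsAsFactors = FALSE)
  need <- c("id", schema$categories)
  miss <- setdiff(need, names(l))
  if (length(miss)) stop("links lack column(s): ", paste(miss, collapse = ", "))
  for (cc in need) l[[cc]] <- as.character(l[[cc]])
  rownames(l) <- NULL
  l[, need]
}

#' Validate an annotated document
#'
#' Checks every schema invariant and returns the violations as data rather
#' than raising: unique mention/link ids; category and assertion inside the
#' schema vocabulary; non-empty in-bounds spans whose surface matches the
#' text; no overlapping mention spans; link groups with exactly one existing
#' member per category whose category matches its role.
#'
#' @param doc an [fg_document()] (or a bare list with the same fields).
#' @param schema an [fg_schema()].
#' @return character vector of human-readable violations; empty if the
#'   document is valid. Idempotent and side-effect free.
#' @export
fg_validate <- function(doc, schema = fg_schema()) {
  v <- character()
  m <- doc$mentions
  l <- doc$links
  n <- nchar(doc$text)

  if (anyDuplicated(m$id)) {
    v <- c(v, paste0("duplicate mention id(s): ",
                     paste(unique(m$id[duplicated(m$id)]), collapse = ", ")))
  }
  for (i in seq_len(nrow(m))) {
    id <- m$id[i]
    if (!m$category[i] %in% schema$categories) {
      v <- c(v, sprintf("mention %s: unknown category '%s'", id, m$category[i]))
      next
    }
    if (!m$assertion[i] %in% schema$assertions[[m$category[i]]]) {
      v <- c(v, sprintf("mention %s: assertion '%s' not in the %s vocabulary",
                        id, m$assertion[i], m$category[i]))
    }
    if (is.na(m$start[i]) || is.na(m$end[i]) || m$start[i] < 0 ||
        m$end[i] > n || m$start[i] >= m$end[i]) {
      v <- c(v, sprintf("mention %s: span [%s,%s) empty or outside text of length %d",
                        id, m$start[i], m$end[i], n))
    } else {
      surf <- substring(doc$text, m$start[i] + 1L, m$end[i])
      if (!is.na(m$surface[i]) && !identical(surf, m$surface[i])) {
        v <- c(v, sprintf("mention %s: surface '%s' does not match text span '%s'",
                          id, m$surface[i], surf))
      }
    }
  }
  # pairwise span overlap among in-bounds mentions
  if (nrow(m) > 1) {
    for (a in seq_len(nrow(m) - 1L)) {
      for (b in seq(a + 1L, nrow(m))) {
        if (anyNA(c(m$start[a], m$start[b]))) next
        if (m$start[a] < m$end[b] && m$start[b] < m$end[a]) {
          v <- c(v, sprintf("mentions %s and %s overlap ([%d,%d) vs [%d,%d))",
                            m$id[a], m$id[b], m$start[a], m$end[a],
                            m$start[b], m$end[b]))
        }
      }
    }
  }

  if (anyDuplicated(l$id)) {
    v <- c(v, paste0("duplicate link id(s): ",
                     paste(unique(l$id[duplicated(l$id)]), collapse = ", ")))
  }
  for (i in seq_len(nrow(l))) {
    lid <- l$id[i]
    for (cat_ in schema$categories) {
      mid <- l[[cat_]][i]
      if (is.na(mid) || !nzchar(mid)) {
        v <- c(v, sprintf("link %s: missing %s member", lid, cat_))
      } else if (!mid %in% m$id) {
        v <- c(v, sprintf("link %s: %s member '%s' does not exist", lid, cat_, mid))
      } else if (m$category[match(mid, m$id)] != cat_) {
        v <- c(v, sprintf("link %s: member '%s' has category %s, expected %s",
                          lid, mid, m$category[match(mid, m$id)], cat_))
      }
    }
  }
  v
}

#' @export
print.fg_document <- function(x, ...) {
  cat(sprintf("<fg_document> %s: %d chars, %d mentions, %d link groups\n",
              x$doc_id, nchar(x$text), nrow(x$mentions), nrow(x$links)))
  invisible(x)
}

#' Mention ids of a document's link groups, as a list of character vectors
#' @param doc an [fg_document()].
#' @keywords internal
link_member_sets <- function(doc) {
  l <- doc$links
  lapply(seq_len(nrow(l)), function(i) {
    unlist(l[i, fg_schema()$categories], use.names = FALSE)
  })
}

#' Gold entity-pair closure of a document's link groups
#'
#' Two distinct mentions are considered associated when they co-occur in at
#' least one link group. Pairs are unordered and reported with the
#' lexicographically smaller mention id first.
#'
#' @param doc an [fg_document()].
#' @return data.frame with columns `a`, `b` (mention ids), zero rows if no
#'   links.
#' @export
fg_gold_pairs <- function(doc) {
  sets <- link_member_sets(doc)
  if (!length(sets)) return(data.frame(a = character(), b = character()))
  pairs <- do.call(rbind, lapply(sets, function(ms) {
    ms <- unique(ms)
    if (length(ms) < 2) return(NULL)
    t(utils::combn(ms, 2))
  }))
  a <- pmin(pairs[, 1], pairs[, 2])
  b <- pmax(pairs[, 1], pairs[, 2])
  unique(data.frame(a = a, b = b, stringsAsFactors = FALSE))
}
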
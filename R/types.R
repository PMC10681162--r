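#' The twelve-type entity vocabulary
#'
#' Entity mentions fall in two categories: biological entities (Gene, Disease,
#' Protein, Variation, Enzyme, MPA = molecular physiological activity,
#' CPA = cellular physiological activity, Interaction, Pathway) and regulatory
#' expressions (Regulation, PosReg, NegReg). Regulatory expressions and the
#' non-gene/disease biological entities act as trigger words: intermediate
#' nodes through which a gene-disease relation is annotated indirectly.
#'
#' @return character vector of the twelve entity type labels.
#' @export
entity_types <- function() {
  c("Gene", "Disease", "Protein", "Variation", "Enzyme", "MPA", "CPA",
    "Interaction", "Pathway", "Regulation", "PosReg", "NegReg")
}

#' Default gene/disease endpoint types for direct-edge augmentation
#'
#' Direct edges short-circuit trigger-mediated paths between genes and
#' diseases. Protein is excluded by default (configurable in
#' [add_direct_edges()]).
#'
#' @return character vector of endpoint entity types.
#' @export
de_endpoint_types <- function() c("Gene", "Disease")

#' The canonical relation label
#' @return "LinkedOf"
#' @export
canonical_relation <- function() "LinkedOf"

empty_mentions <- function() {
  data.frame(id = character(), start = integer(), end = integer(),
             etype = character(), surface = character(),
             stringsAsFactors = FALSE)
}

empty_relations <- function() {
  data.frame(e0 = character(), e1 = character(),
             rtype = character(), direct = logical(),
             stringsAsFactors = FALSE)
}

#' Construct an annotated document
#'
#' The unit of training and evaluation: text plus typed character-span entity
#' mentions and typed binary relations between them. Spans are 0-based,
#' half-open character intervals over `text`.
#'
#' @param doc_id document identifier.
#' @param text document text.
#' @param mentions data.frame with columns `id`, `start`, `end`, `etype` and
#'   optionally `surface` (filled from `text` if absent).
#' @param relations data.frame with columns `e0`, `e1`, `rtype` and optionally
#'   `direct` (default: `TRUE` iff both endpoints are Gene/Disease mentions).
#' @param validate check all invariants (default TRUE).
#' @return an object of class `annotated_document`.
#' @export
annotated_document <- function(doc_id, text, mentions = empty_mentions(),
                               relations = empty_relations(), validate = TRUE) {
  mentions <- as.data.frame(mentions, stringsAsFactors = FALSE)
  relations <- as.data.frame(relations, stringsAsFactors = FALSE)
  if (nrow(mentions) == 0L) mentions <- empty_mentions()
  if (nrow(relations) == 0L) relations <- empty_relations()
  mentions$start <- as.integer(mentions$start)
  mentions$end <- as.integer(mentions$end)
  if (is.null(mentions$surface) && nrow(mentions) > 0L) {
    mentions$surface <- substring(text, mentions$start + 1L, mentions$end)
  }
  if (is.null(relations$direct)) {
    relations$direct <- if (nrow(relations) == 0L) logical(0) else {
      et <- stats::setNames(mentions$etype, mentions$id)
      unname(et[relations$e0] %in% de_endpoint_types() &
             et[relations$e1] %in% de_endpoint_types())
    }
  }
  relations <- dedupe_relations(relations)
  doc <- structure(
    list(doc_id = as.character(doc_id), text = text,
         mentions = mentions, relations = relations),
    class = "annotated_document")
  if (validate) validate_document(doc)
  doc
}

# Deduplicate (e0, e1, rtype) triples; a duplicate that is direct anywhere
# stays direct (set semantics over the relation graph).
dedupe_relations <- function(relations) {
  if (nrow(relations) == 0L) return(relations)
  key <- paste(relations$e0, relations$e1, relations$rtype, sep = "\r")
  direct <- tapply(relations$direct, key, any)
  keep <- !duplicated(key)
  out <- relations[keep, , drop = FALSE]
  out$direct <- as.logical(direct[paste(out$e0, out$e1, out$rtype, sep = "\r")])
  rownames(out) <- NULL
  out
}

#' Validate an annotated document
#'
#' Checks every structural invariant: spans in range over the text, surfaces
#' equal to the covered text, entity types drawn from the closed twelve-type
#' vocabulary, mention ids unique, relation endpoints resolving to mentions of
#' the document and distinct from each other.
#'
#' @param doc an `annotated_document`.
#' @param check_etype require types in [entity_types()] (default TRUE).
#' @return `doc`, invisibly; stops with an informative error on violation.
#' @export
validate_document <- function(doc, check_etype = TRUE) {
  m <- doc$mentions; r <- doc$relations
  n <- nchar(doc$text)
  if (anyDuplicated(m$id)) {
    stop(sprintf("document '%s': duplicate mention ids: %s", doc$doc_id,
                 paste(unique(m$id[duplicated(m$id)]), collapse = ", ")))
  }
  bad <- which(!(m$start >= 0L & m$start < m$end & m$end <= n))
  if (length(bad)) {
    stop(sprintf("document '%s': mention '%s' span [%d,%d) outside text of length %d",
                 doc$doc_id, m$id[bad[1]], m$start[bad[1]], m$end[bad[1]], n))
  }
  if (nrow(m)) {
    got <- substring(doc$text, m$start + 1L, m$end)
    bad <- which(got != m$surface)
    if (length(bad)) {
      stop(sprintf("document '%s': mention '%s' surface %s does not match text %s",
                   doc$doc_id, m$id[bad[1]], dQuote(m$surface[bad[1]]), dQuote(got[bad[1]])))
    }
  }
  if (check_etype) {
    bad <- setdiff(unique(m$etype), entity_types())
    if (length(bad)) {
      stop(sprintf("document '%s': unknown entity type(s): %s", doc$doc_id,
                   paste(bad, collapse = ", ")))
    }
  }
  if (nrow(r)) {
    unresolved <- setdiff(unique(c(r$e0, r$e1)), m$id)
    if (length(unresolved)) {
      stop(sprintf("document '%s': relation endpoint(s) not among mentions: %s",
                   doc$doc_id, paste(unresolved, collapse = ", ")))
    }
    if (any(r$e0 == r$e1)) {
      stop(sprintf("document '%s': self-relation on mention '%s'",
                   doc$doc_id, r$e0[which(r$e0 == r$e1)[1]]))
    }
  }
  invisible(doc)
}

#' @export
print.annotated_document <- function(x, ...) {
  cat(sprintf("<annotated_document '%s': %d chars, %d mentions, %d relations>\n",
              x$doc_id, nchar(x$text), nrow(x$mentions), nrow(x$relations)))
  invisible(x)
}

#' @export
format.annotated_document <- function(x, ...) {
  sprintf("annotated_document('%s', %d mentions, %d relations)",
          x$doc_id, nrow(x$mentions), nrow(x$relations))
}
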
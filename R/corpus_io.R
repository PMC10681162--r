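#' Read an annotated corpus from PubAnnotation-style JSON
#'
#' Each document is a JSON object
#' `{"id", "text", "denotations": [{"id", "span": {"begin", "end"}, "obj"}],
#'   "relations": [{"id", "subj", "obj", "pred"}]}`
#' with 0-based half-open character spans. A file may hold one document object
#' or an array of them; a directory is read as all its `.json` files. Every
#' record is validated; malformed records raise errors naming the file and the
#' offending mention/relation rather than being dropped.
#'
#' @param path a JSON file or a directory of JSON files.
#' @return list of [annotated_document()] objects.
#' @export
read_corpus <- function(path) {
  if (length(path) == 1L && dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.json$", full.names = TRUE))
    files <- files[basename(files) != "manifest.json"]  # generation sidecar
    if (!length(files)) stop(sprintf("no .json files under '%s'", path))
  } else {
    files <- path
  }
  docs <- list()
  for (f in files) {
    raw <- tryCatch(
      jsonlite::fromJSON(f, simplifyVector = FALSE),
      error = function(e) stop(sprintf("failed to parse '%s': %s", f, conditionMessage(e)))
    )
    recs <- if (!is.null(raw$text) || !is.null(raw$id)) list(raw) else raw
    for (rec in recs) {
      doc <- tryCatch(parse_document_record(rec),
                      error = function(e) stop(sprintf("%s: %s", f, conditionMessage(e))))
      docs[[length(docs) + 1L]] <- doc
    }
  }
  docs
}

parse_document_record <- function(rec) {
  if (is.null(rec$text)) stop("document record missing 'text'")
  doc_id <- as.character(rec$id %||% rec$sourceid %||% "doc")
  dens <- rec$denotations %||% list()
  mentions <- if (length(dens)) {
    data.frame(
      id = vapply(dens, function(d) as.character(d$id), character(1)),
      start = vapply(dens, function(d) as.integer(d$span$begin), integer(1)),
      end = vapply(dens, function(d) as.integer(d$span$end), integer(1)),
      etype = vapply(dens, function(d) as.character(d$obj), character(1)),
      stringsAsFactors = FALSE)
  } else empty_mentions()
  rels <- rec$relations %||% list()
  relations <- if (length(rels)) {
    data.frame(
      e0 = vapply(rels, function(r) as.character(r$subj), character(1)),
      e1 = vapply(rels, function(r) as.character(r$obj), character(1)),
      rtype = vapply(rels, function(r) as.character(r$pred), character(1)),
      direct = vapply(rels, function(r) isTRUE(r$direct), logical(1)),
      stringsAsFactors = FALSE)
  } else empty_relations()
  # the "direct" key is optional in the dialect: recompute default when absent
  if (length(rels) && !any(vapply(rels, function(r) !is.null(r$direct), logical(1)))) {
    relations$direct <- NULL
  }
  annotated_document(doc_id, rec$text, mentions, relations)
}

#' Write an annotated corpus as PubAnnotation-style JSON
#'
#' Emits the same dialect [read_corpus()] reads, one file per document named
#' `<doc_id>.json`, deterministically ordered, so that read after write is the
#' identity on valid corpora.
#'
#' @param corpus list of `annotated_document`s.
#' @param dir output directory (created if needed).
#' @return the written file paths, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(corpus))
  for (i in seq_along(corpus)) {
    doc <- corpus[[i]]
    paths[i] <- file.path(dir, paste0(doc$doc_id, ".json"))
    writeLines(document_to_json(doc), paths[i], useBytes = TRUE)
  }
  invisible(paths)
}

document_to_json <- function(doc) {
  m <- doc$mentions; r <- doc$relations
  dens <- lapply(seq_len(nrow(m)), function(i) list(
    id = m$id[i],
    span = list(begin = m$start[i], end = m$end[i]),
    obj = m$etype[i]))
  rels <- lapply(seq_len(nrow(r)), function(i) {
    out <- list(id = paste0("R", i), subj = r$e0[i], obj = r$e1[i], pred = r$rtype[i])
    out$direct <- r$direct[i]
    out
  })
  jsonlite::toJSON(
    list(id = doc$doc_id, text = doc$text, denotations = dens, relations = rels),
    auto_unbox = TRUE, digits = NA)
}

#' Build a relation/entity schema map
#'
#' Maps source relation labels to the canonical "LinkedOf" vocabulary and
#' source entity labels to the twelve-type vocabulary. The default map carries
#' the AGAC-style normalization ThemeOf -> LinkedOf, CauseOf -> LinkedOf and
#' the long-form entity names used in some corpora.
#'
#' @param relation_map named character vector, source label -> canonical label.
#' @param etype_map named character vector, source type -> canonical type.
#' @return an object of class `schema_map`.
#' @export
schema_map <- function(relation_map = default_relation_map(),
                       etype_map = default_etype_map()) {
  structure(list(relation_map = relation_map, etype_map = etype_map),
            class = "schema_map")
}

#' @rdname schema_map
#' @export
default_relation_map <- function() {
  c(ThemeOf = "LinkedOf", CauseOf = "LinkedOf", LinkedOf = "LinkedOf")
}

#' @rdname schema_map
#' @export
default_etype_map <- function() {
  ids <- entity_types()
  m <- stats::setNames(ids, ids)
  c(m,
    "Molecular Physiological Activity" = "MPA",
    "Cellular Physiological Activity" = "CPA",
    "Positive Regulation" = "PosReg",
    "Negative Regulation" = "NegReg",
    "Var" = "Variation")
}

#' Normalize a document's relation and entity labels
#'
#' Applies a [schema_map()] so that all relation labels become "LinkedOf" and
#' all entity types fall in the twelve-type vocabulary. Relations that become
#' identical triples after mapping are deduplicated; the mention set is
#' preserved exactly (only the `etype` column may be relabelled).
#'
#' @param doc an `annotated_document`.
#' @param map a `schema_map`.
#' @return the normalized `annotated_document`.
#' @export
normalize_schema <- function(doc, map = schema_map()) {
  m <- doc$mentions; r <- doc$relations
  if (nrow(m)) {
    unmapped <- setdiff(unique(m$etype), names(map$etype_map))
    if (length(unmapped)) {
      stop(sprintf("document '%s': no schema mapping for entity type(s): %s",
                   doc$doc_id, paste(unmapped, collapse = ", ")))
    }
    m$etype <- unname(map$etype_map[m$etype])
  }
  if (nrow(r)) {
    unmapped <- setdiff(unique(r$rtype), names(map$relation_map))
    if (length(unmapped)) {
      stop(sprintf("document '%s': no schema mapping for relation label(s): %s",
                   doc$doc_id, paste(unmapped, collapse = ", ")))
    }
    r$rtype <- unname(map$relation_map[r$rtype])
    r$direct <- NULL
  }
  annotated_document(doc$doc_id, doc$text, m, r)
}

#' Augment a document with direct gene-disease edges
#'
#' For every (gene, disease) mention pair connected in the document's relation
#' graph by a path whose interior nodes are all trigger mentions (i.e. not in
#' the endpoint type set), a direct "LinkedOf" edge between the pair is added
#' with `direct = TRUE`. Pre-existing relations are untouched; the operation
#' is idempotent and monotone. The direct edge is stored with the gene as
#' `e0` for determinism.
#'
#' @param doc a schema-normalized `annotated_document`.
#' @param endpoints entity types counting as path endpoints
#'   (default `c("Gene", "Disease")`; add "Protein" to let proteins anchor
#'   direct edges).
#' @param max_path maximum number of interior trigger nodes on a qualifying
#'   path (default `Inf`, i.e. any trigger chain).
#' @return the augmented `annotated_document`.
#' @export
add_direct_edges <- function(doc, endpoints = de_endpoint_types(), max_path = Inf) {
  pairs <- direct_edge_pairs(doc, endpoints = endpoints, max_path = max_path)
  if (!nrow(pairs)) return(doc)
  r <- doc$relations
  new <- data.frame(e0 = pairs$gene, e1 = pairs$disease,
                    rtype = canonical_relation(), direct = TRUE,
                    stringsAsFactors = FALSE)
  annotated_document(doc$doc_id, doc$text, doc$mentions, rbind(r, new))
}

# All (gene, disease) mention-id pairs joined by a trigger-interior path,
# including length-0 interiors (an annotated direct edge). Gene side first.
direct_edge_pairs <- function(doc, endpoints = de_endpoint_types(), max_path = Inf) {
  m <- doc$mentions; r <- doc$relations
  none <- data.frame(gene = character(), disease = character(), stringsAsFactors = FALSE)
  genes <- m$id[m$etype == "Gene" | (("Protein" %in% endpoints) & m$etype == "Protein")]
  diseases <- m$id[m$etype == "Disease"]
  if (!length(genes) || !length(diseases) || !nrow(r)) return(none)
  g <- igraph::graph_from_data_frame(
    r[, c("e0", "e1")], directed = FALSE,
    vertices = data.frame(name = m$id, etype = m$etype, stringsAsFactors = FALSE))
  etype <- igraph::V(g)$etype
  is_trigger <- !(etype %in% endpoints)
  out <- list()
  for (gid in genes) {
    for (did in diseases) {
      if (gid == did) next
      if (trigger_path_exists(g, gid, did, is_trigger, max_path)) {
        out[[length(out) + 1L]] <- c(gid, did)
      }
    }
  }
  if (!length(out)) return(none)
  res <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
  names(res) <- c("gene", "disease")
  res
}

# BFS from `from` over trigger-interior vertices only; `to` may be reached
# directly (path length 1) or through at most max_path trigger nodes.
trigger_path_exists <- function(g, from, to, is_trigger, max_path) {
  vn <- igraph::V(g)$name
  fi <- match(from, vn); ti <- match(to, vn)
  adj <- igraph::adjacent_vertices(g, fi)[[1]]
  if (ti %in% as.integer(adj)) return(TRUE)
  frontier <- intersect(as.integer(adj), which(is_trigger))
  seen <- frontier
  depth <- 1L
  while (length(frontier) && depth <= max_path) {
    nxt <- unique(as.integer(unlist(igraph::adjacent_vertices(g, frontier))))
    if (ti %in% nxt) return(TRUE)
    frontier <- setdiff(intersect(nxt, which(is_trigger)), seen)
    seen <- union(seen, frontier)
    depth <- depth + 1L
  }
  FALSE
}

#' Corpus summary statistics
#'
#' Totals and per-entity-type counts over a corpus, in the spirit of dataset
#' composition tables (e.g. 1,377 documents / 52,709 entities / 43,601
#' relations for the full released gene-disease corpus).
#'
#' @param corpus list of `annotated_document`s.
#' @return list with `documents`, `entities`, `relations`,
#'   `entities_by_type` (named integer vector over the twelve types) and
#'   `gene_disease_fraction`.
#' @export
corpus_stats <- function(corpus) {
  types <- entity_types()
  by_type <- stats::setNames(integer(length(types)), types)
  ents <- 0L; rels <- 0L
  for (doc in corpus) {
    ents <- ents + nrow(doc$mentions)
    rels <- rels + nrow(doc$relations)
    if (nrow(doc$mentions)) {
      tb <- table(factor(doc$mentions$etype, levels = types))
      by_type <- by_type + as.integer(tb)
    }
  }
  gd <- sum(by_type[c("Gene", "Disease")])
  list(documents = length(corpus), entities = ents, relations = rels,
       entities_by_type = by_type,
       gene_disease_fraction = if (ents > 0) gd / ents else NA_real_)
}
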
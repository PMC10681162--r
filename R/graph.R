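#' Knowledge graph of typed, provenance-carrying nodes and edges
#'
#' Nodes are typed entity occurrences (optionally linked to a dictionary
#' identifier); edges are undirected "LinkedOf" relations carrying the doc
#' ids they came from and, for predictions, a link probability. Node ids
#' before identifier linking encode (doc, span, type), so graphs built from
#' the same documents are directly comparable.
#'
#' @param nodes data.frame with columns `node_id`, `etype`, `surface`,
#'   `identifier`, `provenance`.
#' @param edges data.frame with columns `u`, `v`, `rtype`, `provenance`,
#'   `p_link`.
#' @return object of class `knowledge_graph`.
#' @export
knowledge_graph <- function(nodes = empty_kg_nodes(), edges = empty_kg_edges()) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(nodes) == 0L) nodes <- empty_kg_nodes()
  if (nrow(edges) == 0L) edges <- empty_kg_edges()
  if (nrow(edges)) {
    missing <- setdiff(unique(c(edges$u, edges$v)), nodes$node_id)
    if (length(missing)) {
      stop(sprintf("edge endpoint(s) not among nodes: %s",
                   paste(utils::head(missing, 3), collapse = ", ")))
    }
    edges <- canonical_edges(edges)
  }
  if (anyDuplicated(nodes$node_id)) {
    # identical node ids unify: deterministic fields, unioned provenance
    nodes <- do.call(rbind, lapply(split(seq_len(nrow(nodes)), nodes$node_id),
                                   function(ix)
                                     collapse_node_rows(nodes, ix, nodes$node_id[ix[1]])))
  }
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "knowledge_graph")
}

empty_kg_nodes <- function() {
  data.frame(node_id = character(), etype = character(), surface = character(),
             identifier = character(), provenance = character(),
             stringsAsFactors = FALSE)
}

empty_kg_edges <- function() {
  data.frame(u = character(), v = character(), rtype = character(),
             provenance = character(), p_link = numeric(),
             stringsAsFactors = FALSE)
}

# Undirected canonical form: u <= v lexicographically, duplicates collapsed
# (provenance unioned, p_link maximised), self-loops dropped.
canonical_edges <- function(edges) {
  if (!nrow(edges)) return(edges)
  u <- pmin(edges$u, edges$v); v <- pmax(edges$u, edges$v)
  edges$u <- u; edges$v <- v
  edges <- edges[edges$u != edges$v, , drop = FALSE]
  if (!nrow(edges)) return(edges)
  key <- paste(edges$u, edges$v, edges$rtype)
  merge_prov <- vapply(split(edges$provenance, key), function(p)
    paste(sort(unique(unlist(strsplit(p, ";", fixed = TRUE)))), collapse = ";"),
    character(1))
  max_p <- vapply(split(edges$p_link, key), function(p)
    if (all(is.na(p))) NA_real_ else max(p, na.rm = TRUE), numeric(1))
  out <- edges[!duplicated(key), , drop = FALSE]
  k <- paste(out$u, out$v, out$rtype)
  out$provenance <- unname(merge_prov[k])
  out$p_link <- unname(max_p[k])
  out[order(out$u, out$v), , drop = FALSE]
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat(sprintf("<knowledge_graph: %d nodes, %d edges>\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

mention_node_ids <- function(doc_id, mentions) {
  paste(doc_id, mentions$start, mentions$end, mentions$etype, sep = "|")
}

#' Build a knowledge graph from one document
#'
#' With `links = NULL`, the graph carries the document's own annotations:
#' one node per typed mention (keyed by doc, span and type) and one
#' undirected edge per relation. With a `links` data.frame (two mention-id
#' columns plus optional `p_link`), the graph instead represents a model's
#' prediction: nodes from `mentions` (default: the document's mentions) and
#' edges from the predicted pairs. Duplicate relations collapse to one edge.
#'
#' @param doc an `annotated_document`.
#' @param links optional predicted pairs (e.g. the `links` from
#'   [predict_document()]).
#' @param mentions optional mention data.frame overriding `doc$mentions`
#'   (predicted mentions).
#' @return a [knowledge_graph()].
#' @export
build_graph <- function(doc, links = NULL, mentions = NULL) {
  m <- mentions %||% doc$mentions
  nodes <- if (nrow(m)) data.frame(
    node_id = mention_node_ids(doc$doc_id, m),
    etype = m$etype, surface = m$surface,
    identifier = NA_character_, provenance = doc$doc_id,
    stringsAsFactors = FALSE) else empty_kg_nodes()
  id2node <- stats::setNames(nodes$node_id, m$id)
  if (is.null(links)) {
    r <- doc$relations
    edges <- if (nrow(r)) data.frame(
      u = unname(id2node[r$e0]), v = unname(id2node[r$e1]),
      rtype = r$rtype, provenance = doc$doc_id, p_link = NA_real_,
      stringsAsFactors = FALSE) else empty_kg_edges()
  } else {
    edges <- if (nrow(links)) data.frame(
      u = unname(id2node[links[[1]]]), v = unname(id2node[links[[2]]]),
      rtype = canonical_relation(), provenance = doc$doc_id,
      p_link = if (!is.null(links$p_link)) links$p_link else NA_real_,
      stringsAsFactors = FALSE) else empty_kg_edges()
  }
  knowledge_graph(nodes, edges)
}

#' @rdname build_graph
#' @param pairs predicted pair data.frame (first two columns are mention
#'   ids).
#' @export
prediction_graph <- function(doc, pairs, mentions = NULL) {
  build_graph(doc, links = pairs %||% empty_links(), mentions = mentions)
}

#' Gold evaluation graph over a document set
#'
#' Builds the ground-truth graph the evaluator scores against. Under
#' `target = "closure"` (default) the relation target set is the
#' direct-edge closure: a gene-disease pair counts as linked if the gold
#' annotation joins it directly or through a trigger path, so models trained
#' with and without direct-edge augmentation are scored on the same target
#' set. Under `target = "raw"` the edges are the annotation exactly as read.
#'
#' @param docs list of `annotated_document`s.
#' @param target `"closure"` or `"raw"`.
#' @return a [knowledge_graph()] over all documents.
#' @export
gold_graph <- function(docs, target = c("closure", "raw")) {
  target <- match.arg(target)
  gs <- lapply(docs, function(doc) {
    if (target == "closure") {
      doc <- add_direct_edges(doc)
      r <- doc$relations[doc$relations$direct, , drop = FALSE]
      build_graph(annotated_document(doc$doc_id, doc$text, doc$mentions, r,
                                     validate = FALSE))
    } else {
      build_graph(doc)
    }
  })
  graphs_union(gs)
}

#' Union of knowledge graphs (no identifier merging)
#' @param graphs list of `knowledge_graph`s.
#' @return a single `knowledge_graph`.
#' @export
graphs_union <- function(graphs) {
  knowledge_graph(do.call(rbind, c(list(empty_kg_nodes()),
                                   lapply(graphs, `[[`, "nodes"))),
                  do.call(rbind, c(list(empty_kg_edges()),
                                   lapply(graphs, `[[`, "edges"))))
}

#' Compare a prediction graph against a gold graph
#'
#' Entity true positives are nodes matching gold exactly on (document, span,
#' type); relation true positives are predicted edges whose two endpoints
#' match gold nodes and which exist (undirected) in the gold edge set.
#' Precision with zero predictions is reported as 0, not NaN, so fold
#' averaging stays total; F1 is the harmonic mean and 0 whenever TP is 0.
#'
#' @param gold,pred `knowledge_graph`s over the same document set.
#' @return object of class `eval_report`: lists `entity` and `relation`,
#'   each with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
compare_graphs <- function(gold, pred) {
  ent <- prf(length(intersect(pred$nodes$node_id, gold$nodes$node_id)),
             n_pred = nrow(pred$nodes), n_gold = nrow(gold$nodes))
  gkey <- paste(gold$edges$u, gold$edges$v)
  pkey <- paste(pred$edges$u, pred$edges$v)
  rel <- prf(sum(pkey %in% gkey), n_pred = length(pkey), n_gold = length(gkey))
  structure(list(entity = ent, relation = rel), class = "eval_report")
}

prf <- function(tp, n_pred, n_gold) {
  fp <- n_pred - tp; fn <- n_gold - tp
  p <- if (n_pred > 0) tp / n_pred else 0
  r <- if (n_gold > 0) tp / n_gold else 0
  f1 <- if (tp > 0) 2 * p * r / (p + r) else 0
  list(tp = tp, fp = fp, fn = fn, precision = p, recall = r, f1 = f1)
}

#' @export
print.eval_report <- function(x, ...) {
  fmt <- function(nm, m) cat(sprintf(
    "%-8s TP=%d FP=%d FN=%d  P=%.4f R=%.4f F1=%.4f\n",
    nm, m$tp, m$fp, m$fn, m$precision, m$recall, m$f1))
  fmt("entity", x$entity)
  fmt("relation", x$relation)
  invisible(x)
}
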
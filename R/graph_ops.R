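#' Decision-rule configuration
#'
#' An ordered list of named filters applied to a knowledge graph before
#' visualization/export. The registered rules are generic building blocks
#' (threshold on link probability, dropping unlinked nodes, restricting node
#' types, capping node degree); concrete rule sets are user-configured.
#'
#' @param rules list of lists, each with a `name` from [rule_registry()] and
#'   that rule's parameters.
#' @return object of class `rule_config`.
#' @export
rule_config <- function(rules = list()) {
  known <- names(rule_registry())
  for (r in rules) {
    if (is.null(r$name) || !(r$name %in% known)) {
      stop(sprintf("unknown rule '%s'; registered rules: %s",
                   r$name %||% "<missing>", paste(known, collapse = ", ")))
    }
  }
  structure(list(rules = rules), class = "rule_config")
}

#' @rdname rule_config
#' @export
rule_registry <- function() {
  list(
    min_p_link = function(g, p = 0.5) {
      keep <- is.na(g$edges$p_link) | g$edges$p_link >= p
      knowledge_graph(g$nodes, g$edges[keep, , drop = FALSE])
    },
    drop_unlinked_nodes = function(g) {
      keep <- !is.na(g$nodes$identifier)
      ids <- g$nodes$node_id[keep]
      knowledge_graph(g$nodes[keep, , drop = FALSE],
                      g$edges[g$edges$u %in% ids & g$edges$v %in% ids, ,
                              drop = FALSE])
    },
    etype_whitelist = function(g, types = c("Gene", "Protein", "Disease")) {
      keep <- g$nodes$etype %in% types
      ids <- g$nodes$node_id[keep]
      knowledge_graph(g$nodes[keep, , drop = FALSE],
                      g$edges[g$edges$u %in% ids & g$edges$v %in% ids, ,
                              drop = FALSE])
    },
    degree_cap = function(g, max_degree = 50) {
      deg <- table(c(g$edges$u, g$edges$v))
      hubs <- names(deg)[deg > max_degree]
      keep <- !(g$nodes$node_id %in% hubs)
      ids <- g$nodes$node_id[keep]
      knowledge_graph(g$nodes[keep, , drop = FALSE],
                      g$edges[g$edges$u %in% ids & g$edges$v %in% ids, ,
                              drop = FALSE])
    })
}

#' Apply decision rules to a knowledge graph
#'
#' Rules are applied in the order listed; each removes nodes and/or edges
#' (the output is always a subgraph) and the removal counts are logged when
#' `options(spanrel.verbose = TRUE)`.
#'
#' @param g a `knowledge_graph`.
#' @param rules a [rule_config()].
#' @return the filtered `knowledge_graph`.
#' @export
apply_rules <- function(g, rules = rule_config()) {
  reg <- rule_registry()
  for (r in rules$rules) {
    fn <- reg[[r$name]]
    args <- r[setdiff(names(r), "name")]
    before <- c(nrow(g$nodes), nrow(g$edges))
    g <- do.call(fn, c(list(g), args))
    spanrel_log("rules", "%s removed %d nodes, %d edges", r$name,
                before[1] - nrow(g$nodes), before[2] - nrow(g$edges))
  }
  g
}

#' Merge nodes sharing an identifier
#'
#' All nodes carrying the same non-missing identifier collapse into a single
#' node whose provenance is the union; edges re-attach, merge-induced
#' self-loops are dropped, and parallel undirected edges collapse keeping
#' the maximum link probability. Idempotent.
#'
#' @param g a linked `knowledge_graph`.
#' @return the merged `knowledge_graph`.
#' @export
merge_nodes <- function(g) {
  nodes <- g$nodes
  linked <- !is.na(nodes$identifier)
  ns <- ifelse(nodes$etype == "Disease", "disease", "gene")
  new_id <- ifelse(linked, paste0(ns, ":", nodes$identifier), nodes$node_id)
  remap <- stats::setNames(new_id, nodes$node_id)
  merged <- do.call(rbind, lapply(split(seq_len(nrow(nodes)), new_id),
                                  function(ix) collapse_node_rows(nodes, ix, new_id[ix[1]])))
  edges <- g$edges
  if (nrow(edges)) {
    edges$u <- unname(remap[edges$u])
    edges$v <- unname(remap[edges$v])
  }
  knowledge_graph(merged %||% empty_kg_nodes(), edges)
}

# Deterministic representative for a set of node rows collapsing into one:
# fields are chosen by sort order, not input order, so merging is
# order-independent.
collapse_node_rows <- function(nodes, ix, id) {
  data.frame(node_id = id,
             etype = sort(nodes$etype[ix])[1],
             surface = sort(nodes$surface[ix])[1],
             identifier = sort(nodes$identifier[ix])[1],
             provenance = paste(sort(unique(unlist(
               strsplit(nodes$provenance[ix], ";", fixed = TRUE)))),
               collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Reduce trigger nodes to direct edges
#'
#' Removes all trigger-word nodes (anything other than Gene, Protein and
#' Disease) and, for every gene/protein-disease pair connected through a
#' removed trigger chain, adds a direct edge with the provenance of the
#' traversed edges merged. Pre-existing direct edges and the gene/disease
#' nodes are preserved. Idempotent.
#'
#' @param g a `knowledge_graph`.
#' @return the reduced `knowledge_graph`.
#' @export
reduce_triggers <- function(g) {
  keep_types <- c("Gene", "Protein", "Disease")
  nodes <- g$nodes; edges <- g$edges
  is_trigger <- !(nodes$etype %in% keep_types)
  if (!any(is_trigger)) return(knowledge_graph(nodes, edges))
  new_edges <- edges[0, , drop = FALSE]
  if (nrow(edges)) {
    ig <- igraph::graph_from_data_frame(
      edges[, c("u", "v")], directed = FALSE,
      vertices = data.frame(name = nodes$node_id, stringsAsFactors = FALSE))
    trig_ids <- nodes$node_id[is_trigger]
    sub <- igraph::induced_subgraph(ig, trig_ids)
    comp <- igraph::components(sub)
    for (ci in seq_len(comp$no)) {
      members <- igraph::V(sub)$name[comp$membership == ci]
      inc <- edges[edges$u %in% members | edges$v %in% members, , drop = FALSE]
      nbr <- setdiff(unique(c(inc$u, inc$v)), members)
      ntypes <- nodes$etype[match(nbr, nodes$node_id)]
      gp <- nbr[ntypes %in% c("Gene", "Protein")]
      dd <- nbr[ntypes == "Disease"]
      if (!length(gp) || !length(dd)) next
      prov <- paste(sort(unique(unlist(strsplit(inc$provenance, ";", fixed = TRUE)))),
                    collapse = ";")
      pl <- if (all(is.na(inc$p_link))) NA_real_ else max(inc$p_link, na.rm = TRUE)
      for (a in gp) for (b in dd) {
        new_edges <- rbind(new_edges, data.frame(
          u = a, v = b, rtype = canonical_relation(),
          provenance = prov, p_link = pl, stringsAsFactors = FALSE))
      }
    }
  }
  surviving <- nodes[!is_trigger, , drop = FALSE]
  old <- edges[edges$u %in% surviving$node_id & edges$v %in% surviving$node_id, ,
               drop = FALSE]
  knowledge_graph(surviving, rbind(old, new_edges))
}

#' Integrate per-document knowledge graphs
#'
#' Cross-document integration: each graph is trigger-reduced and
#' identifier-merged, then the union is merged again so nodes sharing an
#' identifier collapse across documents (unlinked nodes collapse on
#' lowercased surface within their type). The result is bipartite over
#' gene/protein and disease nodes; edge provenance lists every contributing
#' document and keeps the maximum link probability. Order-independent up to
#' node ordering.
#'
#' @param graphs list of per-document `knowledge_graph`s.
#' @return the integrated `knowledge_graph`.
#' @export
integrate_graphs <- function(graphs) {
  if (!length(graphs)) return(knowledge_graph())
  parts <- lapply(graphs, function(g) merge_nodes(reduce_triggers(g)))
  u <- graphs_union(parts)
  nodes <- u$nodes
  keyed <- ifelse(is.na(nodes$identifier),
                  paste0(ifelse(nodes$etype == "Disease", "disease", "gene"),
                         ":surface:", tolower(nodes$surface)),
                  nodes$node_id)
  remap <- stats::setNames(keyed, nodes$node_id)
  nodes$node_id <- keyed
  edges <- u$edges
  if (nrow(edges)) {
    edges$u <- unname(remap[edges$u])
    edges$v <- unname(remap[edges$v])
  }
  merged <- do.call(rbind, lapply(split(seq_len(nrow(nodes)), nodes$node_id),
                                  function(ix) collapse_node_rows(nodes, ix, nodes$node_id[ix[1]])))
  rownames(merged) <- NULL
  out <- knowledge_graph(merged, edges)
  out$nodes <- out$nodes[order(out$nodes$node_id), , drop = FALSE]
  rownames(out$nodes) <- NULL
  out
}

#' Export a knowledge graph
#'
#' JSON node-link format (deterministic field order) or a TSV edge list
#' with per-edge document counts.
#'
#' @param g a `knowledge_graph`.
#' @param path output file.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_graph <- function(g, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    writeLines(jsonlite::toJSON(list(nodes = g$nodes, edges = g$edges),
                                dataframe = "rows", na = "null",
                                auto_unbox = TRUE, digits = NA),
               path, useBytes = TRUE)
  } else {
    e <- g$edges
    e$n_docs <- vapply(strsplit(e$provenance, ";", fixed = TRUE), length,
                       integer(1))
    utils::write.table(e[, c("u", "v", "n_docs", "provenance", "p_link")],
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
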
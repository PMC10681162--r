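# Fixtures and independent brute-force oracles used across the suite.

# A minimal hand-built document: gene, trigger, disease with a trigger path.
toy_document <- function() {
  text <- "BRCA1 upregulation causes breast cancer in patients"
  annotated_document(
    "toy1", text,
    mentions = data.frame(
      id = c("T1", "T2", "T3"),
      start = c(0L, 6L, 26L), end = c(5L, 18L, 39L),
      etype = c("Gene", "PosReg", "Disease"),
      stringsAsFactors = FALSE),
    relations = data.frame(
      e0 = c("T1", "T2"), e1 = c("T2", "T3"),
      rtype = "LinkedOf", direct = FALSE, stringsAsFactors = FALSE))
}

# Random relation-annotated document over a synthetic mention set; used to
# exercise graph algorithms on arbitrary topologies.
random_relation_doc <- function(n_mentions = 8, n_edges = 8) {
  types <- sample(entity_types(), n_mentions, replace = TRUE)
  words <- sprintf("w%02d", seq_len(n_mentions))
  text <- paste(words, collapse = " ")
  starts <- (seq_len(n_mentions) - 1L) * 4L
  mentions <- data.frame(
    id = sprintf("T%d", seq_len(n_mentions)),
    start = starts, end = starts + 3L, etype = types,
    stringsAsFactors = FALSE)
  pairs <- t(combn(mentions$id, 2))
  take <- sample(nrow(pairs), min(n_edges, nrow(pairs)))
  relations <- data.frame(e0 = pairs[take, 1], e1 = pairs[take, 2],
                          rtype = "LinkedOf", direct = FALSE,
                          stringsAsFactors = FALSE)
  annotated_document(sprintf("rand%d", sample.int(1e6, 1)), text,
                     mentions, relations)
}

# Oracle: enumerate all simple paths between two mentions and check that at
# least one has only trigger-type interior nodes of length <= max_interior.
oracle_trigger_path <- function(doc, from, to, endpoints = c("Gene", "Disease"),
                                max_interior = Inf) {
  adj <- list()
  for (i in seq_len(nrow(doc$relations))) {
    a <- doc$relations$e0[i]; b <- doc$relations$e1[i]
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  etype <- stats::setNames(doc$mentions$etype, doc$mentions$id)
  found <- FALSE
  dfs <- function(node, visited, interior) {
    if (found) return(invisible(NULL))
    for (nb in adj[[node]]) {
      if (nb == to) {
        if (interior <= max_interior) found <<- TRUE
      } else if (!(nb %in% visited) && !(etype[nb] %in% endpoints)) {
        dfs(nb, c(visited, nb), interior + 1L)
      }
    }
  }
  dfs(from, from, 0L)
  found
}

# Oracle: the full direct-edge pair set by brute force.
oracle_de_pairs <- function(doc, endpoints = c("Gene", "Disease"),
                            max_interior = Inf) {
  m <- doc$mentions
  genes <- m$id[m$etype == "Gene"]
  diseases <- m$id[m$etype == "Disease"]
  out <- list()
  for (g in genes) for (d in diseases) {
    if (oracle_trigger_path(doc, g, d, endpoints, max_interior)) {
      out[[length(out) + 1L]] <- paste(g, d)
    }
  }
  as.character(sort(unlist(out)))
}

# Oracle: set-intersection precision/recall/F1 on node and edge key sets.
oracle_compare <- function(gold_nodes, pred_nodes, gold_edges, pred_edges) {
  prf1 <- function(tp, np, ng) {
    p <- if (np > 0) tp / np else 0
    r <- if (ng > 0) tp / ng else 0
    f <- if (tp > 0) 2 * p * r / (p + r) else 0
    c(p = p, r = r, f1 = f)
  }
  ek <- function(e) unique(vapply(e, function(x)
    paste(sort(x), collapse = "~"), character(1)))
  ge <- ek(gold_edges); pe <- ek(pred_edges)
  list(entity = prf1(length(intersect(pred_nodes, gold_nodes)),
                     length(unique(pred_nodes)), length(unique(gold_nodes))),
       relation = prf1(sum(pe %in% ge), length(pe), length(ge)))
}

# Small random knowledge graph over typed nodes (for comparison and
# reduction property tests).
random_kg <- function(n_nodes = 8, n_edges = 8,
                      types = c("Gene", "Disease", "Protein", "Regulation",
                                "PosReg", "MPA")) {
  ids <- sprintf("n%02d", seq_len(n_nodes))
  nodes <- data.frame(node_id = ids,
                      etype = sample(types, n_nodes, replace = TRUE),
                      surface = ids, identifier = NA_character_,
                      provenance = "d1", stringsAsFactors = FALSE)
  pairs <- t(combn(ids, 2))
  take <- sample(nrow(pairs), min(n_edges, nrow(pairs)))
  edges <- data.frame(u = pairs[take, 1], v = pairs[take, 2],
                      rtype = "LinkedOf", provenance = "d1",
                      p_link = NA_real_, stringsAsFactors = FALSE)
  knowledge_graph(nodes, edges)
}

# A tiny trained-free model for structural tests (no training involved).
tiny_model <- function(H = 8, seed = 5) {
  tok <- bpe_train("BRCA1 upregulation causes breast cancer in patients and TP53 loss", 80)
  relex_model(tok, encoder_spec(H = H, layers = 1, heads = 2, ffn = 12),
              seed = seed, max_width = 4, width_dim = 3, hidden = 6)
}
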
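linked_kg <- function() {
  nodes <- data.frame(
    node_id = c("a", "b", "c", "d"),
    etype = c("Gene", "Gene", "Disease", "Disease"),
    surface = c("TP53", "TP53", "melanoma", "glioma"),
    identifier = c("7157", "7157", "EFO:1", "EFO:2"),
    provenance = c("d1", "d2", "d1", "d2"), stringsAsFactors = FALSE)
  edges <- data.frame(
    u = c("a", "b"), v = c("c", "d"), rtype = "LinkedOf",
    provenance = c("d1", "d2"), p_link = c(0.95, 0.5),
    stringsAsFactors = FALSE)
  knowledge_graph(nodes, edges)
}

test_that("decision rules filter as configured and unknown rules error", {
  g <- linked_kg()
  expect_identical(apply_rules(g, rule_config()), g)   # empty list: identity
  thr <- apply_rules(g, rule_config(list(list(name = "min_p_link", p = 0.9))))
  expect_equal(nrow(thr$edges), 1)
  expect_equal(thr$edges$p_link, 0.95)
  g2 <- g
  g2$nodes$identifier[4] <- NA
  dropped <- apply_rules(g2, rule_config(list(list(name = "drop_unlinked_nodes"))))
  expect_equal(nrow(dropped$nodes), 3)
  expect_equal(nrow(dropped$edges), 1)   # edge to the dropped node goes too
  expect_error(rule_config(list(list(name = "no_such_rule"))), "unknown rule")
  # rules always produce a subgraph
  expect_true(all(thr$nodes$node_id %in% g$nodes$node_id))
  expect_true(nrow(thr$edges) <= nrow(g$edges))
})

test_that("nodes sharing an identifier merge with unioned provenance", {
  g <- merge_nodes(linked_kg())
  # two TP53 nodes with one distinct disease edge each -> one node, two edges
  expect_equal(nrow(g$nodes), 3)
  tp53 <- g$nodes[g$nodes$etype == "Gene", ]
  expect_equal(nrow(tp53), 1)
  expect_equal(tp53$provenance, "d1;d2")
  expect_equal(sum(g$edges$u == tp53$node_id | g$edges$v == tp53$node_id), 2)
  # no shared identifiers: identity on structure
  solo <- random_kg(5, 4)
  expect_equal(nrow(merge_nodes(solo)$nodes), 5)
  # idempotence
  expect_identical(merge_nodes(g), g)
})

test_that("trigger reduction shortcuts trigger chains into direct edges", {
  mk <- function(types, edges) {
    ids <- sprintf("n%d", seq_along(types))
    knowledge_graph(
      data.frame(node_id = ids, etype = types, surface = ids,
                 identifier = NA_character_, provenance = "d1",
                 stringsAsFactors = FALSE),
      data.frame(u = ids[edges[, 1]], v = ids[edges[, 2]], rtype = "LinkedOf",
                 provenance = "d1", p_link = NA_real_,
                 stringsAsFactors = FALSE))
  }
  # g - t - d  becomes  g - d
  g1 <- reduce_triggers(mk(c("Gene", "Regulation", "Disease"),
                           rbind(c(1, 2), c(2, 3))))
  expect_equal(nrow(g1$nodes), 2)
  expect_equal(nrow(g1$edges), 1)
  expect_setequal(c(g1$edges$u, g1$edges$v), c("n1", "n3"))
  # no trigger nodes: identity
  g2 <- mk(c("Gene", "Disease"), rbind(c(1, 2)))
  expect_identical(reduce_triggers(g2), g2)
  # two-trigger chain reduces transitively
  g3 <- reduce_triggers(mk(c("Gene", "PosReg", "NegReg", "Disease"),
                           rbind(c(1, 2), c(2, 3), c(3, 4))))
  expect_equal(nrow(g3$edges), 1)
  expect_setequal(c(g3$edges$u, g3$edges$v), c("n1", "n4"))
  # idempotence
  expect_identical(reduce_triggers(g3), g3)
})

test_that("trigger reduction equals a brute-force connectivity oracle on
           random graphs", {
  set.seed(21)
  keep_types <- c("Gene", "Protein", "Disease")
  for (i in 1:30) {
    g <- random_kg(sample(4:9, 1), sample(3:10, 1))
    red <- reduce_triggers(g)
    # oracle: gene/protein-disease pairs joined by a trigger-interior path
    ids <- g$nodes$node_id
    ety <- stats::setNames(g$nodes$etype, ids)
    adj <- list()
    for (k in seq_len(nrow(g$edges))) {
      adj[[g$edges$u[k]]] <- union(adj[[g$edges$u[k]]], g$edges$v[k])
      adj[[g$edges$v[k]]] <- union(adj[[g$edges$v[k]]], g$edges$u[k])
    }
    reach <- function(from, to) {
      seen <- from; frontier <- from
      while (length(frontier)) {
        nxt <- setdiff(unique(unlist(adj[frontier])), seen)
        if (to %in% nxt) return(TRUE)
        frontier <- nxt[!(ety[nxt] %in% keep_types)]
        seen <- union(seen, nxt)
      }
      FALSE
    }
    want <- character(0)
    for (a in ids[ety[ids] %in% c("Gene", "Protein")]) {
      for (b in ids[ety[ids] == "Disease"]) {
        if (reach(a, b)) want <- c(want, paste(sort(c(a, b)), collapse = "~"))
      }
    }
    got <- paste(pmin(red$edges$u, red$edges$v),
                 pmax(red$edges$u, red$edges$v), sep = "~")
    # reduced edges between kept nodes must equal the oracle pair set for
    # gene/protein-disease pairs (edges among same-side nodes may persist)
    gd <- vapply(seq_len(nrow(red$edges)), function(k) {
      ta <- ety[red$edges$u[k]]; tb <- ety[red$edges$v[k]]
      (ta %in% c("Gene", "Protein") && tb == "Disease") ||
        (tb %in% c("Gene", "Protein") && ta == "Disease")
    }, logical(1))
    expect_setequal(got[gd], unique(want))
    # no trigger nodes survive
    expect_false(any(!(red$nodes$etype %in% keep_types)))
  }
})

test_that("integration merges identifier-sharing nodes across documents", {
  d1 <- knowledge_graph(
    data.frame(node_id = c("x1", "x2"), etype = c("Gene", "Disease"),
               surface = c("BRCA1", "breast cancer"),
               identifier = c("672", "EFO:1"), provenance = "d1",
               stringsAsFactors = FALSE),
    data.frame(u = "x1", v = "x2", rtype = "LinkedOf", provenance = "d1",
               p_link = 0.9, stringsAsFactors = FALSE))
  d2 <- knowledge_graph(
    data.frame(node_id = c("y1", "y2"), etype = c("Gene", "Disease"),
               surface = c("brca1", "ovarian cancer"),
               identifier = c("672", "EFO:2"), provenance = "d2",
               stringsAsFactors = FALSE),
    data.frame(u = "y1", v = "y2", rtype = "LinkedOf", provenance = "d2",
               p_link = 0.8, stringsAsFactors = FALSE))
  g <- integrate_graphs(list(d1, d2))
  # same gene id in two docs -> one gene node with two disease edges
  expect_equal(sum(g$nodes$etype == "Gene"), 1)
  expect_equal(nrow(g$edges), 2)
  gene <- g$nodes$node_id[g$nodes$etype == "Gene"]
  expect_equal(sort(g$nodes$provenance[g$nodes$node_id == gene]), "d1;d2")
  # bipartite over gene/protein and disease nodes
  expect_true(all(g$nodes$etype %in% c("Gene", "Protein", "Disease")))
  # permutation invariance
  g_rev <- integrate_graphs(list(d2, d1))
  expect_identical(g$nodes, g_rev$nodes)
  expect_identical(g$edges, g_rev$edges)
  # single document: integrate = merge of the reduced graph
  solo <- integrate_graphs(list(d1))
  expect_equal(nrow(solo$edges), nrow(merge_nodes(reduce_triggers(d1))$edges))
})

test_that("integration is order-independent on random graph collections", {
  set.seed(31)
  for (i in 1:10) {
    gs <- lapply(1:4, function(k) {
      g <- random_kg(sample(3:6, 1), sample(2:6, 1))
      # node ids are document-scoped, as in real prediction graphs
      remap <- stats::setNames(sprintf("doc%d|%s", k, g$nodes$node_id),
                               g$nodes$node_id)
      g$nodes$node_id <- unname(remap[g$nodes$node_id])
      g$edges$u <- unname(remap[g$edges$u])
      g$edges$v <- unname(remap[g$edges$v])
      g$nodes$provenance <- sprintf("doc%d", k)
      g$edges$provenance <- if (nrow(g$edges)) sprintf("doc%d", k) else character(0)
      # link some nodes so cross-document merging has work to do
      g$nodes$identifier <- ifelse(stats::runif(nrow(g$nodes)) < 0.5,
                                   sprintf("ID%d", seq_len(nrow(g$nodes)) %% 3),
                                   NA_character_)
      g
    })
    a <- integrate_graphs(gs)
    b <- integrate_graphs(rev(gs))
    expect_identical(a$nodes, b$nodes)
    expect_identical(a$edges, b$edges)
  }
})
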
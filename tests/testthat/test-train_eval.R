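test_that("k-fold splitting partitions documents with balanced sizes", {
  corp <- as.list(1:10)
  folds <- kfold_split(corp, 5, seed = 1)
  expect_length(folds, 5)
  expect_equal(sort(unlist(folds)), 1:10)
  expect_true(all(lengths(folds) == 2))
  # remainder goes to the earlier folds: 11 docs -> sizes 3,2,2,2,2
  folds11 <- kfold_split(as.list(1:11), 5, seed = 1)
  expect_equal(lengths(folds11), c(3L, 2L, 2L, 2L, 2L))
  expect_equal(sort(unlist(folds11)), 1:11)
  # deterministic under the seed, different under another
  expect_identical(folds, kfold_split(corp, 5, seed = 1))
  expect_false(identical(folds, kfold_split(corp, 5, seed = 2)))
  expect_error(kfold_split(as.list(1:3), 5, seed = 1), "folds")
})

test_that("the learning-rate schedule warms up linearly then decays", {
  expect_equal(lr_schedule(0, 100, lr = 6e-5, warmup = 0.1), 0)
  expect_equal(lr_schedule(10, 100, lr = 6e-5, warmup = 0.1), 6e-5)
  expect_equal(lr_schedule(5, 100, lr = 6e-5, warmup = 0.1), 3e-5)
  expect_equal(lr_schedule(100, 100, lr = 6e-5, warmup = 0.1), 0)
  expect_equal(lr_schedule(55, 100, lr = 6e-5, warmup = 0.1), 3e-5)
  s <- lr_schedule(0:100, 100, lr = 6e-5, warmup = 0.1)
  expect_equal(which.max(s) - 1, 10)
  expect_true(all(diff(s[1:11]) > 0))
  expect_true(all(diff(s[11:101]) < 0))
})

test_that("training is reproducible and rejects empty corpora", {
  corp <- generate_corpus(synth_config(n_docs = 4, seed = 23))
  cfg <- train_config(epochs = 2, batch_size = 2, lr = 1e-3, seed = 5)
  spec <- encoder_spec(H = 16, layers = 1, heads = 2, ffn = 16,
                       seq_encoder = "identity")
  f1 <- train_model(corp, cfg, spec, vocab_size = 120)
  f2 <- train_model(corp, cfg, spec, vocab_size = 120)
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(f1$trace, f2$trace)
  expect_equal(nrow(f1$trace), 2 * 2)
  expect_error(train_model(list(), cfg, spec), "empty corpus")
})

test_that("graphs built from documents have set semantics", {
  doc <- annotated_document(
    "g1", "BRCA1 causes cancer",
    mentions = data.frame(id = c("T1", "T2"), start = c(0L, 13L),
                          end = c(5L, 19L), etype = c("Gene", "Disease")),
    relations = data.frame(e0 = "T1", e1 = "T2", rtype = "LinkedOf",
                           direct = TRUE))
  g <- build_graph(doc)
  expect_equal(nrow(g$nodes), 2)
  expect_equal(nrow(g$edges), 1)
  # duplicate relations collapse to one edge (and reversed counts as same)
  doc2 <- doc
  doc2$relations <- rbind(doc$relations,
                          data.frame(e0 = "T2", e1 = "T1", rtype = "LinkedOf",
                                     direct = TRUE))
  expect_equal(nrow(build_graph(doc2)$edges), 1)
  # gold vs gold is a perfect match
  rep <- compare_graphs(g, build_graph(doc))
  expect_equal(rep$entity$f1, 1)
  expect_equal(rep$relation$f1, 1)
})

test_that("graph comparison reproduces confusion-matrix arithmetic", {
  mk <- function(n_nodes, edges) {
    ids <- sprintf("n%d", seq_len(n_nodes))
    nodes <- data.frame(node_id = ids, etype = "Gene", surface = ids,
                        identifier = NA_character_, provenance = "d",
                        stringsAsFactors = FALSE)
    e <- data.frame(u = ids[edges[, 1]], v = ids[edges[, 2]],
                    rtype = "LinkedOf", provenance = "d", p_link = NA_real_,
                    stringsAsFactors = FALSE)
    knowledge_graph(nodes, e)
  }
  gold <- mk(8, cbind(1:4, 5:8))                   # 4 gold edges
  pred <- mk(8, cbind(c(1, 2, 3, 1, 2), c(5, 6, 7, 6, 5)))  # 5 pred, 3 TP
  rep <- compare_graphs(gold, pred)
  expect_equal(rep$relation$tp, 3)
  expect_equal(rep$relation$precision, 0.6)
  expect_equal(rep$relation$recall, 0.75)
  expect_equal(rep$relation$f1, 2 * 0.6 * 0.75 / (0.6 + 0.75))
  expect_equal(rep$relation$f1, 0.6667, tolerance = 1e-4)
  # empty prediction: P reported as 0 (not NaN), R = 0, F1 = 0
  none <- knowledge_graph()
  rep0 <- compare_graphs(gold, none)
  expect_equal(rep0$relation$precision, 0)
  expect_equal(rep0$relation$recall, 0)
  expect_equal(rep0$relation$f1, 0)
  expect_equal(rep0$entity$precision, 0)
})

test_that("graph comparison equals the set-intersection oracle on random
           graph pairs, with F1 the harmonic mean to 1e-12", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(3:20, 1)
    gold <- random_kg(n, sample(2:12, 1))
    pred <- random_kg(n, sample(2:12, 1))
    # overlap node sets: pred nodes are a sample of gold ids plus extras
    rep <- compare_graphs(gold, pred)
    want <- oracle_compare(
      gold$nodes$node_id, pred$nodes$node_id,
      lapply(seq_len(nrow(gold$edges)), function(k)
        c(gold$edges$u[k], gold$edges$v[k])),
      lapply(seq_len(nrow(pred$edges)), function(k)
        c(pred$edges$u[k], pred$edges$v[k])))
    expect_equal(rep$relation$precision, unname(want$relation["p"]))
    expect_equal(rep$relation$recall, unname(want$relation["r"]))
    expect_equal(rep$relation$f1, unname(want$relation["f1"]))
    p <- rep$relation$precision; r <- rep$relation$recall
    if (rep$relation$tp > 0) {
      expect_equal(rep$relation$f1, 2 * p * r / (p + r), tolerance = 1e-12)
    }
  }
})

test_that("ablation arms share fold assignments byte-identically", {
  corp <- generate_corpus(synth_config(n_docs = 10, seed = 33))
  cfg <- train_config(epochs = 1, batch_size = 4, lr = 1e-3, seed = 3,
                      folds = 5)
  spec <- encoder_spec(H = 8, layers = 1, heads = 2, ffn = 8,
                       seq_encoder = "identity")
  ab <- ablation_run(corp, cfg, spec, vocab_size = 120)
  expect_identical(ab$folds, kfold_split(corp, 5, cfg$seed))
  expect_equal(ab$joint_de$fold, 1:5)
  for (nm in c("joint_de", "joint_node", "onlyre_de", "onlyre_node")) {
    expect_true(all(ab[[nm]]$relation_f1 >= 0 & ab[[nm]]$relation_f1 <= 1))
  }
})
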
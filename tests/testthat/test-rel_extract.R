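test_that("candidate formation is the deduplicated gene x disease cross
           product", {
  m <- data.frame(
    id = c("g1", "g2", "d1", "d2", "d3", "t1"),
    start = c(0, 10, 20, 30, 40, 50), end = c(5, 15, 25, 35, 45, 55),
    etype = c("Gene", "Gene", "Disease", "Disease", "Disease", "Regulation"),
    stringsAsFactors = FALSE)
  cand <- form_candidates(m)
  expect_equal(nrow(cand), 6)
  expect_true(all(cand$gene %in% c("g1", "g2")))
  expect_true(all(cand$disease %in% c("d1", "d2", "d3")))

  expect_equal(nrow(form_candidates(m[m$etype != "Disease", ])), 0)

  # duplicated identical gene spans deduplicate to one candidate per pair
  dup <- rbind(m, data.frame(id = "g1b", start = 0, end = 5, etype = "Gene",
                             stringsAsFactors = FALSE))
  expect_equal(nrow(form_candidates(dup)), 6)

  # proteins join the gene side only when configured
  mp <- rbind(m, data.frame(id = "p1", start = 60, end = 65,
                            etype = "Protein", stringsAsFactors = FALSE))
  expect_equal(nrow(form_candidates(mp)), 6)
  expect_equal(nrow(form_candidates(mp, gene_types = c("Gene", "Protein"))), 9)
})

test_that("between-context is the strict max-pool between spans", {
  emb <- rbind(c(1, 1), c(0, 3), c(2, 1), c(5, 5), c(-1, 0))
  # one token strictly between spans (1,1) and (3,3): token 2
  expect_equal(between_context(c(1, 1), c(3, 3), emb), c(0, 3))
  # two between tokens with values (0,3),(2,1) -> (2,3)
  expect_equal(between_context(c(1, 1), c(4, 4), emb), c(2, 3))
  # order of the two spans does not matter
  expect_equal(between_context(c(4, 4), c(1, 1), emb), c(2, 3))
  # adjacent spans: zero vector
  expect_equal(between_context(c(1, 2), c(3, 4), emb), c(0, 0))
  # overlapping spans: zero vector by policy
  expect_equal(between_context(c(1, 3), c(2, 5), emb), c(0, 0))
})

test_that("attention is a normalized weighted sum inside the convex hull", {
  v <- rbind(c(1, 0), c(0, 1), c(2, 2))
  k <- diag(3)[, 1:3]
  # n = 1: the single value is returned regardless of the query
  one <- attend(c(5, -3, 1), k[1, , drop = FALSE], v[1, , drop = FALSE])
  expect_equal(one$context, v[1, ])
  expect_equal(sum(one$weights), 1)
  # identical keys: uniform weights, context = mean of values
  same <- attend(rnorm(3), matrix(1, 3, 3), v)
  expect_equal(same$weights, rep(1 / 3, 3))
  expect_equal(same$context, colMeans(v))
  # imposed weights reproduce the plain weighted sum
  imp <- attend(NULL, k, v, weights = c(0.5, 0.25, 0.25))
  expect_equal(imp$context, c(1.0, 0.75))
  expect_error(attend(c(1), matrix(0, 0, 1), matrix(0, 0, 1)), "no tokens")
  # convex-hull property on random instances: the context is a convex
  # combination, so each coordinate lies within the value range
  set.seed(7)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    vals <- matrix(rnorm(n * 3), n, 3)
    keys <- matrix(rnorm(n * 4), n, 4)
    a <- attend(rnorm(4), keys, vals)
    expect_true(all(a$weights >= 0))
    expect_equal(sum(a$weights), 1, tolerance = 1e-12)
    expect_true(all(a$context <= apply(vals, 2, max) + 1e-12))
    expect_true(all(a$context >= apply(vals, 2, min) - 1e-12))
  }
})

test_that("link scoring uses the strict 0.5 rule", {
  # zero-weight head: both classes tie at 0.5, so nothing is linked
  zero <- list(W1 = matrix(0, 4, 3), b1 = matrix(0, 1, 3),
               W2 = matrix(0, 3, 2), b2 = matrix(0, 1, 2))
  out <- score_link(rnorm(4), zero)
  expect_equal(out$p_link, 0.5)
  expect_false(out$linked)   # p = 0.5 exactly is NOT a link
  # hand-set head on a 2-feature toy matches independent sigmoid arithmetic
  head <- list(W1 = diag(2), b1 = matrix(0, 1, 2),
               W2 = rbind(c(0, 1), c(0, 0)), b2 = matrix(c(0, 0.3), 1, 2))
  x <- c(0.4, -0.2)
  h <- tanh(x)
  z <- c(h[1] * 0 + h[2] * 0, h[1] * 1 + h[2] * 0 + 0.3)
  want <- exp(z[2]) / sum(exp(z))           # = sigmoid(z2 - z1)
  got <- score_link(x, head)
  expect_equal(got$p_link, want, tolerance = 1e-12)
  expect_equal(got$p_link, 1 / (1 + exp(-(z[2] - z[1]))), tolerance = 1e-12)
  expect_equal(got$linked, want > 0.5)
})

test_that("the joint loss is the exact sum of its components", {
  expect_equal(joint_loss(0, 0)$total, 0)
  out <- joint_loss(1.5, 2.25)
  expect_equal(out$total, 3.75)
  expect_equal(out$ner_loss + out$re_loss, out$total)
  expect_error(joint_loss(Inf, 1), "non-finite")
  expect_error(joint_loss(1, NaN), "non-finite")
})

test_that("perfect predictions drive the tape joint loss to ~0 and the
           attention context stays in the convex hull of the tokens", {
  ns <- asNamespace("spanrel")
  doc <- add_direct_edges(toy_document())
  tok <- bpe_train(doc$text, 60)
  model <- relex_model(tok, encoder_spec(H = 8, layers = 1, heads = 2,
                                         ffn = 12),
                       seed = 3, max_width = 4, width_dim = 3, hidden = 6)
  prep <- ns$prepare_document(model, doc)
  fw <- ns$model_forward(model, prep, neg_spans = 8, neg_pairs = 8)
  expect_equal(fw$total_loss, fw$ner_loss + fw$re_loss, tolerance = 1e-12)
  expect_gte(fw$ner_loss, 0)
  expect_gte(fw$re_loss, 0)
  # attention rows are distributions; context rows live in the hull of KV
  g <- ns$ad_graph()
  X <- ns$encoder_forward(g, model$params, model$spec, prep$tok$ids)
  re <- ns$tape_re_logits(g, model, X, prep,
                          data.frame(gene = "T1", disease = "T3",
                                     stringsAsFactors = FALSE))
  A <- re$attention
  expect_equal(rowSums(A), rep(1, nrow(A)), tolerance = 1e-12)
  expect_true(all(A >= 0))
})
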
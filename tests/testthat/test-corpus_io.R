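test_that("a minimal well-formed document parses and validates", {
  path <- tempfile(fileext = ".json")
  writeLines(paste0(
    '{"id":"d1","text":"BRCA1 causes cancer",',
    '"denotations":[{"id":"T1","span":{"begin":0,"end":5},"obj":"Gene"},',
    '{"id":"T2","span":{"begin":13,"end":19},"obj":"Disease"}],',
    '"relations":[{"id":"R1","subj":"T1","obj":"T2","pred":"LinkedOf"}]}'),
    path)
  docs <- read_corpus(path)
  expect_length(docs, 1)
  doc <- docs[[1]]
  expect_equal(nrow(doc$mentions), 2)
  expect_equal(nrow(doc$relations), 1)
  expect_equal(doc$mentions$surface, c("BRCA1", "cancer"))
  expect_true(all(doc$relations$direct))  # annotated gene-disease is direct
})

test_that("malformed records are rejected with informative errors", {
  path <- tempfile(fileext = ".json")
  writeLines(paste0(
    '{"id":"bad","text":"short",',
    '"denotations":[{"id":"T1","span":{"begin":0,"end":99},"obj":"Gene"}]}'),
    path)
  expect_error(read_corpus(path), "T1")
  writeLines("{not json", path)
  expect_error(read_corpus(path), "parse")
  expect_error(
    annotated_document("d", "abcdef", data.frame(
      id = "T1", start = 2L, end = 2L, etype = "Gene", surface = "")),
    "span")
  expect_error(
    annotated_document("d", "abcdef", data.frame(
      id = c("T1", "T1"), start = c(0L, 1L), end = c(2L, 3L),
      etype = "Gene")),
    "duplicate")
  expect_error(
    annotated_document("d", "abcdef", data.frame(
      id = "T1", start = 0L, end = 3L, etype = "Gadget")),
    "unknown entity type")
})

test_that("read after write is the identity on valid corpora", {
  corp <- generate_corpus(synth_config(n_docs = 8, seed = 42))
  dir <- tempfile()
  write_corpus(corp, dir)
  back <- read_corpus(dir)
  strip <- function(d) list(d$doc_id, d$text, d$mentions, d$relations)
  expect_identical(lapply(back, strip), lapply(corp, strip))
})

test_that("schema normalization maps relation labels and preserves mentions", {
  doc <- annotated_document(
    "agac1", "g1 t1 d1",
    mentions = data.frame(id = c("a", "b", "c"),
                          start = c(0L, 3L, 6L), end = c(2L, 5L, 8L),
                          etype = c("Gene", "Regulation", "Disease")),
    relations = data.frame(e0 = c("a", "b"), e1 = c("b", "c"),
                           rtype = c("ThemeOf", "CauseOf"), direct = FALSE))
  out <- normalize_schema(doc)
  expect_equal(out$relations$rtype, rep("LinkedOf", 2))
  expect_identical(out$mentions, doc$mentions)

  canon <- normalize_schema(out)
  expect_identical(canon$relations, out$relations)

  # ThemeOf(a,b) and CauseOf(a,b) collapse to a single LinkedOf(a,b)
  doc2 <- annotated_document(
    "agac2", "g1 t1",
    mentions = data.frame(id = c("a", "b"), start = c(0L, 3L),
                          end = c(2L, 5L), etype = c("Gene", "Regulation")),
    relations = data.frame(e0 = c("a", "a"), e1 = c("b", "b"),
                           rtype = c("ThemeOf", "CauseOf"), direct = FALSE))
  out2 <- normalize_schema(doc2)
  expect_equal(nrow(out2$relations), 1)
  expect_equal(sort(unique(paste(out2$relations$e0, out2$relations$e1))),
               "a b")
  expect_error(normalize_schema(annotated_document(
    "x", "g1 t1",
    mentions = data.frame(id = c("a", "b"), start = c(0L, 3L), end = c(2L, 5L),
                          etype = c("Gene", "Regulation")),
    relations = data.frame(e0 = "a", e1 = "b", rtype = "Mystery",
                           direct = FALSE))), "Mystery")
})

test_that("direct-edge augmentation matches the trigger-path definition", {
  doc <- add_direct_edges(toy_document())
  de <- doc$relations[doc$relations$direct, ]
  expect_equal(nrow(de), 1)
  expect_equal(de$e0, "T1")   # gene stored first
  expect_equal(de$e1, "T3")

  # gene with no disease: unchanged
  solo <- annotated_document(
    "solo", "BRCA1 alone", data.frame(id = "T1", start = 0L, end = 5L,
                                      etype = "Gene"))
  expect_identical(add_direct_edges(solo)$relations, solo$relations)

  # chain g-t1-t2-d plus an unrelated gene: exactly one new edge
  chain <- annotated_document(
    "chain", "g1 t1 t2 d1 g2",
    mentions = data.frame(
      id = c("g1", "t1", "t2", "d1", "g2"),
      start = c(0L, 3L, 6L, 9L, 12L), end = c(2L, 5L, 8L, 11L, 14L),
      etype = c("Gene", "Regulation", "NegReg", "Disease", "Gene")),
    relations = data.frame(e0 = c("g1", "t1", "t2"), e1 = c("t1", "t2", "d1"),
                           rtype = "LinkedOf", direct = FALSE))
  out <- add_direct_edges(chain)
  de <- out$relations[out$relations$direct, ]
  expect_equal(paste(de$e0, de$e1), "g1 d1")
  # max_path = 1 rejects the two-trigger chain
  out1 <- add_direct_edges(chain, max_path = 1)
  expect_equal(sum(out1$relations$direct), 0)
})

test_that("direct-edge augmentation is idempotent, monotone, and equals the
           brute-force path oracle on random graphs", {
  set.seed(101)
  for (i in 1:25) {
    doc <- random_relation_doc(n_mentions = sample(4:9, 1),
                               n_edges = sample(3:10, 1))
    out <- add_direct_edges(doc)
    # monotone: no edges removed
    key <- function(r) paste(r$e0, r$e1, r$rtype)
    expect_true(all(key(doc$relations) %in% key(out$relations)))
    # idempotent
    expect_identical(add_direct_edges(out)$relations, out$relations)
    # matches the oracle (all direct edges present, incl. pre-annotated)
    got <- out$relations[out$relations$direct, ]
    expect_setequal(sort(paste(got$e0, got$e1)), oracle_de_pairs(doc))
  }
})

test_that("corpus statistics are additive and type-resolved", {
  expect_equal(corpus_stats(list())$entities, 0)
  expect_equal(corpus_stats(list())$documents, 0)
  a <- annotated_document("a", "g1 d1", data.frame(
    id = c("x", "y"), start = c(0L, 3L), end = c(2L, 5L),
    etype = c("Gene", "Disease")))
  b <- annotated_document("b", "g1 t1 d1", data.frame(
    id = c("x", "y", "z"), start = c(0L, 3L, 6L), end = c(2L, 5L, 8L),
    etype = c("Gene", "Regulation", "Disease")))
  st <- corpus_stats(list(a, b))
  expect_equal(st$entities, 5)
  expect_equal(st$documents, 2)
  expect_equal(unname(st$entities_by_type["Gene"]), 2L)
  expect_equal(st$gene_disease_fraction, 4 / 5)
  both <- corpus_stats(list(a, b))
  expect_equal(both$entities,
               corpus_stats(list(a))$entities + corpus_stats(list(b))$entities)
})
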
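#' Default surface-form lexicons for synthetic corpora
#'
#' One lexicon per entity type plus filler vocabulary. A few surfaces are
#' deliberately shared across types (e.g. between Gene and Protein) so that
#' type assignment cannot be solved by lookup alone; the trailing portion of
#' each lexicon can be held out at generation time to probe generalization to
#' unseen surfaces.
#'
#' @return named list of character vectors (one per entity type, plus
#'   `filler`).
#' @export
default_lexicons <- function() {
  genes <- c("BRCA1", "TP53", "EGFR", "KRAS", "MYC", "PTEN", "ALK", "BRAF",
             "CDK4", "NRAS", "RB1", "VHL", "ATM", "MLH1", "JAK2", "FLT3",
             "NOTCH1", "SMAD4", "APC", "RET")
  list(
    Gene = genes,
    Disease = c("breast cancer", "lung cancer", "melanoma", "glioblastoma",
                "leukemia", "lymphoma", "colorectal cancer", "osteosarcoma",
                "neuroblastoma", "retinoblastoma", "pancreatic cancer",
                "ovarian cancer", "gastric cancer", "hepatitis", "anemia",
                "asthma", "diabetes", "epilepsy", "fibrosis", "nephropathy"),
    # shared with Gene on purpose: protein products are written like the gene
    Protein = c(genes[1:6], "p53 protein", "cyclin D1", "caspase 3",
                "beta catenin", "HER2 receptor", "VEGF ligand"),
    Variation = c("V600E mutation", "T790M mutation", "exon 19 deletion",
                  "frameshift variant", "missense substitution",
                  "splice site variant", "nonsense mutation", "G12D mutation",
                  "promoter hypermethylation", "copy number gain"),
    Enzyme = c("kinase", "phosphatase", "ligase", "helicase", "protease",
               "polymerase", "deacetylase", "methyltransferase"),
    MPA = c("phosphorylation", "ubiquitination", "transcription",
            "methylation", "acetylation", "translation", "degradation",
            "dimerization"),
    CPA = c("apoptosis", "proliferation", "autophagy", "angiogenesis",
            "differentiation", "migration", "senescence", "invasion"),
    Interaction = c("binding", "complex formation", "heterodimerization",
                    "protein interaction", "cofactor recruitment"),
    Pathway = c("MAPK pathway", "PI3K signaling", "WNT pathway",
                "JAK STAT signaling", "NFKB pathway", "hedgehog signaling"),
    Regulation = c("regulation", "modulation", "control", "mediation",
                   "alteration", "involvement"),
    PosReg = c("activation", "upregulation", "induction", "overexpression",
               "enhancement", "stimulation", "amplification"),
    NegReg = c("inhibition", "downregulation", "suppression", "silencing",
               "repression", "loss", "attenuation"),
    filler = c("we", "observed", "that", "the", "in", "of", "patients",
               "with", "a", "significant", "role", "for", "this", "study",
               "shows", "samples", "analysis", "revealed", "results",
               "suggest", "cells", "tissue", "expression", "levels", "was",
               "associated", "observed", "during", "clinical", "cohort",
               "marked", "notably", "tumor", "profiles", "data", "further")
  )
}

#' Synthetic corpus configuration
#'
#' Describes a seeded generator whose output has the statistical structure of
#' the twelve-type gene-disease annotation schema: trigger-word-mediated
#' "LinkedOf" relations (gene-trigger, trigger-trigger, trigger-disease
#' edges forming gene-disease paths), gene+disease mentions near 40% of all
#' entities, and a fraction of relation-free negative documents.
#'
#' @param n_docs number of documents.
#' @param seed integer seed; same (config, seed) gives byte-identical corpora.
#' @param sentences_per_doc integer range (min, max) of sentences.
#' @param entity_rate expected non-structural (filler) mentions per sentence.
#' @param gene_disease_fraction target proportion of mentions typed
#'   Gene/Disease (default 0.4, matching the annotated corpus composition).
#' @param relation_rate expected trigger-mediated gene-disease link events per
#'   positive document.
#' @param negative_doc_fraction proportion of documents with no relations.
#' @param chain_prob probability a link event uses a two-trigger chain
#'   (gene - trigger - trigger - disease) rather than a single trigger.
#' @param lexicon_holdout trailing fraction of every lexicon reserved for
#'   `split = "test"` generation.
#' @param vocab lexicons, as [default_lexicons()].
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_docs = 50, seed = 1L,
                         sentences_per_doc = c(2L, 4L),
                         entity_rate = 1.0,
                         gene_disease_fraction = 0.4,
                         relation_rate = 1.3,
                         negative_doc_fraction = 0.15,
                         chain_prob = 0.2,
                         lexicon_holdout = 0.2,
                         vocab = default_lexicons()) {
  stopifnot(n_docs >= 0, entity_rate >= 0, relation_rate >= 0,
            gene_disease_fraction >= 0, gene_disease_fraction <= 1,
            negative_doc_fraction >= 0, negative_doc_fraction <= 1,
            chain_prob >= 0, chain_prob <= 1,
            lexicon_holdout >= 0, lexicon_holdout < 1)
  for (ty in entity_types()) {
    if (!length(vocab[[ty]])) stop(sprintf("empty lexicon for type '%s'", ty))
  }
  if (!length(vocab$filler)) stop("empty filler lexicon")
  structure(list(n_docs = as.integer(n_docs), seed = as.integer(seed),
                 sentences_per_doc = as.integer(sentences_per_doc),
                 entity_rate = entity_rate,
                 gene_disease_fraction = gene_disease_fraction,
                 relation_rate = relation_rate,
                 negative_doc_fraction = negative_doc_fraction,
                 chain_prob = chain_prob,
                 lexicon_holdout = lexicon_holdout,
                 vocab = vocab),
            class = "synth_config")
}

trigger_types <- function() {
  setdiff(entity_types(), c("Gene", "Disease"))
}

lexicon_slice <- function(cfg, type, split) {
  lex <- cfg$vocab[[type]]
  k <- max(1L, floor(length(lex) * (1 - cfg$lexicon_holdout)))
  if (split == "train") lex[seq_len(k)] else if (k < length(lex)) {
    lex[(k + 1L):length(lex)]
  } else lex
}

#' Generate a synthetic annotated corpus
#'
#' Every generated document validates under the corpus invariants. Generated
#' relations are exclusively gene-to-trigger, trigger-to-trigger and
#' trigger-to-disease edges, so gene-disease links exist only through trigger
#' paths (direct edges must be derived by [add_direct_edges()]). Each
#' document records its intended gene-disease link pairs in the
#' `"intended_links"` attribute for use as generator ground truth.
#'
#' Document `i` draws from a substream seeded by `derive_seed(seed, i)`, so
#' individual documents are stable under corpus reordering or resizing.
#'
#' @param cfg a [synth_config()].
#' @param split `"train"` (default) or `"test"`; test documents draw surfaces
#'   from the held-out tail of each lexicon.
#' @return list of `annotated_document`s.
#' @export
generate_corpus <- function(cfg, split = c("train", "test")) {
  split <- match.arg(split)
  if (cfg$n_docs == 0L) return(list())
  lapply(seq_len(cfg$n_docs), function(i) {
    with_seed(derive_seed(cfg$seed, paste0("doc", split, i)),
              generate_document(cfg, sprintf("synth-%s-%04d", split, i), split))
  })
}

generate_document <- function(cfg, doc_id, split) {
  builder <- new.env(parent = emptyenv())
  builder$words <- character(0)       # word strings in order
  builder$mention_rows <- list()      # list(first_word, n_words, etype, surface)
  negative <- stats::runif(1) < cfg$negative_doc_fraction
  n_links <- if (negative) 0L else max(1L, stats::rpois(1, cfg$relation_rate))
  n_sent <- sample(seq(cfg$sentences_per_doc[1], cfg$sentences_per_doc[2]), 1)
  n_sent <- max(n_sent, n_links)

  relations <- list()
  intended <- list()
  link_sents <- if (n_links > 0) sample(n_sent, n_links) else integer(0)
  n_fill_mentions <- stats::rpois(1, cfg$entity_rate * n_sent)
  # steer the document-level Gene/Disease fraction toward the target
  struct_total <- n_links * (2 + 1 + cfg$chain_prob)  # approx mentions from links
  total <- struct_total + n_fill_mentions
  want_gd <- round(cfg$gene_disease_fraction * total) - 2 * n_links
  fill_types <- character(n_fill_mentions)
  if (n_fill_mentions > 0) {
    n_gd <- min(max(want_gd, 0), n_fill_mentions)
    fill_types <- c(sample(c("Gene", "Disease"), n_gd, replace = TRUE),
                    sample(trigger_types(), n_fill_mentions - n_gd, replace = TRUE))
    fill_types <- sample(fill_types)
  }
  fill_sents <- if (n_fill_mentions > 0) sample(n_sent, n_fill_mentions, replace = TRUE) else integer(0)

  mcount <- 0L
  next_mid <- function() { mcount <<- mcount + 1L; sprintf("T%d", mcount) }
  for (s in seq_len(n_sent)) {
    emit_filler(builder, cfg, 1 + stats::rpois(1, 1))
    if (s %in% link_sents) {
      k <- sum(link_sents == s)
      for (j in seq_len(k)) {
        ids <- emit_link_event(builder, cfg, split, next_mid)
        relations <- c(relations, ids$relations)
        intended[[length(intended) + 1L]] <- c(ids$gene, ids$disease)
      }
    }
    for (f in which(fill_sents == s)) {
      emit_filler(builder, cfg, stats::rpois(1, 1))
      emit_mention(builder, cfg, split, fill_types[f], next_mid())
    }
    emit_filler(builder, cfg, 1 + stats::rpois(1, 2))
    builder$words <- c(builder$words, ".")
  }
  assemble_document(builder, cfg, doc_id, relations, intended)
}

emit_filler <- function(builder, cfg, n) {
  if (n > 0) {
    builder$words <- c(builder$words,
                       sample(cfg$vocab$filler, n, replace = TRUE))
  }
}

emit_mention <- function(builder, cfg, split, etype, id) {
  surface <- sample(lexicon_slice(cfg, etype, split), 1)
  ws <- strsplit(surface, " ", fixed = TRUE)[[1]]
  builder$mention_rows[[length(builder$mention_rows) + 1L]] <-
    list(id = id, first = length(builder$words) + 1L, n = length(ws),
         etype = etype, surface = surface)
  builder$words <- c(builder$words, ws)
  id
}

# One trigger-mediated link event: gene .. trigger [.. trigger] .. disease,
# with relations gene->t1 (, t1->t2) , tK->disease.
emit_link_event <- function(builder, cfg, split, next_mid) {
  chain <- stats::runif(1) < cfg$chain_prob
  g <- emit_mention(builder, cfg, split, "Gene", next_mid())
  emit_filler(builder, cfg, 1 + stats::rpois(1, 0.5))
  t1 <- emit_mention(builder, cfg, split,
                     sample(c("Regulation", "PosReg", "NegReg", "MPA", "CPA"), 1),
                     next_mid())
  rels <- list(c(g, t1))
  last <- t1
  if (chain) {
    emit_filler(builder, cfg, 1)
    t2 <- emit_mention(builder, cfg, split,
                       sample(c("Regulation", "PosReg", "NegReg"), 1), next_mid())
    rels[[length(rels) + 1L]] <- c(last, t2)
    last <- t2
  }
  emit_filler(builder, cfg, 1 + stats::rpois(1, 0.5))
  d <- emit_mention(builder, cfg, split, "Disease", next_mid())
  rels[[length(rels) + 1L]] <- c(last, d)
  list(gene = g, disease = d, relations = rels)
}

assemble_document <- function(builder, cfg, doc_id, relations, intended) {
  words <- builder$words
  starts <- integer(length(words)); pos <- 0L
  for (i in seq_along(words)) {
    starts[i] <- pos
    pos <- pos + nchar(words[i]) + 1L   # single space separator
  }
  text <- paste(words, collapse = " ")
  rows <- builder$mention_rows
  mentions <- if (length(rows)) {
    data.frame(
      id = vapply(rows, `[[`, character(1), "id"),
      start = vapply(rows, function(r) starts[r$first], integer(1)),
      end = vapply(rows, function(r) {
        last <- r$first + r$n - 1L
        starts[last] + nchar(words[last])
      }, integer(1)),
      etype = vapply(rows, `[[`, character(1), "etype"),
      surface = vapply(rows, `[[`, character(1), "surface"),
      stringsAsFactors = FALSE)
  } else empty_mentions()
  rel_df <- if (length(relations)) {
    data.frame(e0 = vapply(relations, `[`, character(1), 1),
               e1 = vapply(relations, `[`, character(1), 2),
               rtype = canonical_relation(), direct = FALSE,
               stringsAsFactors = FALSE)
  } else empty_relations()
  doc <- annotated_document(doc_id, text, mentions, rel_df)
  attr(doc, "intended_links") <- if (length(intended)) {
    data.frame(gene = vapply(intended, `[`, character(1), 1),
               disease = vapply(intended, `[`, character(1), 2),
               stringsAsFactors = FALSE)
  } else data.frame(gene = character(), disease = character(),
                    stringsAsFactors = FALSE)
  doc
}

#' Generate a gold corpus plus a corrupted prediction set
#'
#' Produces a gold corpus and a prediction graph per document obtained by
#' corrupting the gold gene-disease link set: each true link is dropped with
#' probability `drop`, and each unlinked gene-disease pair is added as a
#' false link with probability `add`. Against the gold graph, expected recall
#' is `1 - drop` and expected precision is the analytic function of both
#' rates, which makes the graph evaluator testable.
#'
#' @param cfg a [synth_config()].
#' @param drop probability of dropping a true link.
#' @param add probability of adding each non-gold gene-disease pair.
#' @return list with `gold` (documents, direct-edge augmented) and `pred`
#'   (list of `knowledge_graph`s, one per document).
#' @export
generate_eval_pair <- function(cfg, drop = 0, add = 0) {
  stopifnot(drop >= 0, drop <= 1, add >= 0, add <= 1)
  gold <- lapply(generate_corpus(cfg), add_direct_edges)
  pred <- with_seed(derive_seed(cfg$seed, "corrupt"), lapply(gold, function(doc) {
    m <- doc$mentions
    genes <- m$id[m$etype == "Gene"]; diseases <- m$id[m$etype == "Disease"]
    r <- doc$relations
    true_pairs <- r[r$direct, c("e0", "e1"), drop = FALSE]
    keep <- if (nrow(true_pairs)) stats::runif(nrow(true_pairs)) >= drop else logical(0)
    kept <- true_pairs[keep, , drop = FALSE]
    added <- list()
    if (add > 0 && length(genes) && length(diseases)) {
      truth <- paste(true_pairs$e0, true_pairs$e1)
      for (g in genes) for (d in diseases) {
        if (!(paste(g, d) %in% truth) && stats::runif(1) < add) {
          added[[length(added) + 1L]] <- c(g, d)
        }
      }
    }
    pairs <- rbind(kept,
                   if (length(added)) {
                     stats::setNames(as.data.frame(do.call(rbind, added),
                                                   stringsAsFactors = FALSE),
                                     c("e0", "e1"))
                   } else NULL)
    prediction_graph(doc, pairs)
  }))
  list(gold = gold, pred = pred)
}
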
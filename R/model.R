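#' Construct a joint NER + RE model
#'
#' Bundles the subword tokenizer, the tiny contextual encoder, the learned
#' width-embedding table, the shallow span classifier (13 classes) and the
#' attention-augmented relation head into one parameter set trained under a
#' single summed loss.
#'
#' @param tokenizer a [bpe_train()] tokenizer.
#' @param spec an [encoder_spec()].
#' @param seed initialisation seed.
#' @param max_width widest candidate span in subwords (default 10).
#' @param width_dim width-embedding dimension (default 25).
#' @param hidden hidden width of the two shallow heads.
#' @return object of class `relex_model`.
#' @export
relex_model <- function(tokenizer, spec = encoder_spec(), seed = 1L,
                        max_width = 10L, width_dim = 25L, hidden = 64L) {
  H <- spec$H
  M <- length(ner_classes())
  repr_dim <- H + width_dim
  feat_dim <- 2L * repr_dim + 2L * H
  params <- init_encoder_params(spec, length(tokenizer$vocab),
                                derive_seed(seed, "encoder"))
  params <- c(params, with_seed(derive_seed(seed, "heads"), list(
    wtab = rand_mat(max_width, width_dim, 0.1),
    ner.W1 = rand_mat(repr_dim, hidden, 1 / sqrt(repr_dim)),
    ner.b1 = matrix(0, 1, hidden),
    ner.W2 = rand_mat(hidden, M, 1 / sqrt(hidden)),
    ner.b2 = matrix(0, 1, M),
    re.Wq = rand_mat(2L * H, H, 1 / sqrt(2 * H)),
    re.W1 = rand_mat(feat_dim, hidden, 1 / sqrt(feat_dim)),
    re.b1 = matrix(0, 1, hidden),
    re.W2 = rand_mat(hidden, 2L, 1 / sqrt(hidden)),
    re.b2 = matrix(0, 1, 2L))))
  structure(list(tokenizer = tokenizer, spec = spec, params = params,
                 max_width = as.integer(max_width),
                 width_dim = as.integer(width_dim),
                 hidden = as.integer(hidden)),
            class = "relex_model")
}

#' @export
print.relex_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<relex_model: H=%d, %d layer(s), %d head(s), vocab %d, %d parameters>\n",
              x$spec$H, x$spec$layers, x$spec$heads,
              length(x$tokenizer$vocab), np))
  invisible(x)
}

# Tokenize a document and align its gold mentions once; cached per doc.
prepare_document <- function(model, doc) {
  tok <- bpe_tokenize(model$tokenizer, doc$text, doc$doc_id)
  m <- doc$mentions
  iv <- if (nrow(m)) {
    t(vapply(seq_len(nrow(m)),
             function(i) align_span(m$start[i], m$end[i], tok),
             integer(2)))
  } else matrix(integer(0), 0, 2)
  list(doc = doc, tok = tok,
       mention_first = iv[, 1], mention_last = iv[, 2])
}

span_rows <- function(first, last) {
  mapply(function(a, b) a:b, first, last, SIMPLIFY = FALSE)
}

between_rows <- function(f1, l1, f2, l2) {
  overlap <- f1 <= l2 && f2 <= l1
  if (overlap) return(integer(0))
  lo <- if (l1 < f2) l1 else l2
  hi <- if (l1 < f2) f2 else f1
  if (hi - lo < 2L) integer(0) else (lo + 1L):(hi - 1L)
}

# Batched span representations on the tape: max-pool + width embedding.
tape_span_reprs <- function(g, model, X, first, last) {
  W <- ad_param(g, model$params$wtab, "wtab")
  pooled <- ad_span_maxpool(g, X, span_rows(first, last))
  widx <- pmin(last - first + 1L, nrow(model$params$wtab))
  list(pooled = pooled,
       repr = ad_cbind(g, list(pooled, ad_rows(g, W, widx))))
}

# Gold-pair label lookup: an unordered mention-id pair is a positive iff a
# LinkedOf relation joins it in `relations`.
pair_is_linked <- function(pairs, relations) {
  if (!nrow(pairs)) return(logical(0))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  truth <- if (nrow(relations)) key(relations$e0, relations$e1) else character(0)
  key(pairs$gene, pairs$disease) %in% truth
}

# One forward pass on the tape for a prepared document. Returns loss nodes
# and the graph; used for both joint and onlyRE training.
#
# NER observations: all gold mention spans plus up to `neg_spans` sampled
# non-entity spans. RE candidates: gold gene x disease cross pairs labelled
# by the (possibly direct-edge-augmented) gold relation set, negatives capped
# at `neg_pairs`.
model_forward <- function(model, prep, neg_spans = 100L, neg_pairs = 50L,
                          only_re = FALSE, reduction = "sum") {
  doc <- prep$doc; tok <- prep$tok
  g <- ad_graph()
  X <- encoder_forward(g, model$params, model$spec, tok$ids)
  n <- tok$n
  M <- length(ner_classes())
  loss_ner <- ad_const(g, matrix(0, 1, 1))
  if (!only_re) {
    gold_first <- prep$mention_first; gold_last <- prep$mention_last
    gold_lab <- match(doc$mentions$etype, ner_classes())
    cand <- enumerate_spans(n, model$max_width)
    gold_key <- paste(gold_first, gold_last)
    neg <- cand[!(paste(cand$first, cand$last) %in% gold_key), , drop = FALSE]
    if (nrow(neg) > neg_spans) {
      neg <- neg[sample(nrow(neg), neg_spans), , drop = FALSE]
    }
    first <- c(gold_first, neg$first)
    last <- c(gold_last, neg$last)
    labels <- c(gold_lab, rep(M, nrow(neg)))
    if (length(labels)) {
      sr <- tape_span_reprs(g, model, X, first, last)
      h <- ad_tanh(g, ad_add(g, ad_matmul(g, sr$repr,
                                          ad_param(g, model$params$ner.W1, "ner.W1")),
                             ad_param(g, model$params$ner.b1, "ner.b1")))
      logits <- ad_add(g, ad_matmul(g, h, ad_param(g, model$params$ner.W2, "ner.W2")),
                       ad_param(g, model$params$ner.b2, "ner.b2"))
      loss_ner <- ad_ce_sum(g, logits, labels)
      if (reduction == "mean") loss_ner <- ad_scale(g, loss_ner, 1 / length(labels))
    }
  }
  pairs <- form_candidates(doc$mentions)
  loss_re <- ad_const(g, matrix(0, 1, 1))
  if (nrow(pairs)) {
    linked <- pair_is_linked(pairs, doc$relations[doc$relations$direct, , drop = FALSE])
    keep <- which(linked)
    negs <- which(!linked)
    if (length(negs) > neg_pairs) negs <- sample(negs, neg_pairs)
    sel <- c(keep, negs)
    pairs <- pairs[sel, , drop = FALSE]
    linked <- linked[sel]
    if (nrow(pairs)) {
      re <- tape_re_logits(g, model, X, prep, pairs)
      loss_re <- ad_ce_sum(g, re$logits, ifelse(linked, 2L, 1L))
      if (reduction == "mean") loss_re <- ad_scale(g, loss_re, 1 / nrow(pairs))
    }
  }
  total <- ad_add(g, loss_ner, loss_re)
  list(g = g, loss = total,
       ner_loss = loss_ner$value[1, 1], re_loss = loss_re$value[1, 1],
       total_loss = total$value[1, 1])
}

# Relation-head logits for a set of candidate mention-id pairs, batched:
# features = gene repr ++ disease repr ++ between max-pool ++ attention
# context (query = projected pooled pair, keys/values = seq-encoded tokens).
tape_re_logits <- function(g, model, X, prep, pairs, mention_iv = NULL) {
  p <- model$params
  if (is.null(mention_iv)) {
    mention_iv <- data.frame(id = prep$doc$mentions$id,
                             first = prep$mention_first,
                             last = prep$mention_last,
                             stringsAsFactors = FALSE)
  }
  gi <- match(pairs$gene, mention_iv$id)
  di <- match(pairs$disease, mention_iv$id)
  gf <- mention_iv$first[gi]; gl <- mention_iv$last[gi]
  df <- mention_iv$first[di]; dl <- mention_iv$last[di]
  sg <- tape_span_reprs(g, model, X, gf, gl)
  sd <- tape_span_reprs(g, model, X, df, dl)
  btw <- ad_span_maxpool(g, X, mapply(between_rows, gf, gl, df, dl,
                                      SIMPLIFY = FALSE))
  KV <- seq_encoder_forward(g, p, model$spec, X)
  Q <- ad_matmul(g, ad_cbind(g, list(sg$pooled, sd$pooled)),
                 ad_param(g, p$re.Wq, "re.Wq"))
  S <- ad_scale(g, ad_matmul(g, Q, ad_transpose(g, KV)), 1 / sqrt(model$spec$H))
  A <- ad_softmax_rows(g, S)
  ctx <- ad_matmul(g, A, KV)
  feats <- ad_cbind(g, list(sg$repr, sd$repr, btw, ctx))
  h <- ad_tanh(g, ad_add(g, ad_matmul(g, feats, ad_param(g, p$re.W1, "re.W1")),
                         ad_param(g, p$re.b1, "re.b1")))
  logits <- ad_add(g, ad_matmul(g, h, ad_param(g, p$re.W2, "re.W2")),
                   ad_param(g, p$re.b2, "re.b2"))
  list(logits = logits, attention = A$value)
}

#' Predict entities and gene-disease links for one document
#'
#' Runs the full inference path: tokenize, encode, classify every candidate
#' span up to the width cap, keep non-`"O"` predictions (for spans predicted
#' as several overlapping entities, each span keeps its single argmax type),
#' form gene x disease pairs (from predicted mentions, or from gold mentions
#' in `onlyRE` mode) and score links with the strict `p_link > 0.5` rule.
#'
#' @param model a trained [relex_model()].
#' @param doc an `annotated_document` (gold annotations are only used when
#'   `entities = "gold"`) or a plain string.
#' @param entities `"predicted"` (default) or `"gold"` (the onlyRE regime).
#' @return list with `mentions` (data.frame: id, start, end, etype, surface,
#'   score) and `links` (data.frame: gene, disease, p_link) plus the
#'   tokenization.
#' @export
predict_document <- function(model, doc, entities = c("predicted", "gold")) {
  entities <- match.arg(entities)
  if (is.character(doc)) doc <- annotated_document("query", doc)
  tok <- bpe_tokenize(model$tokenizer, doc$text, doc$doc_id)
  g <- ad_graph()
  if (tok$n == 0L) {
    return(list(mentions = empty_pred_mentions(), links = empty_links(), tok = tok))
  }
  X <- encoder_forward(g, model$params, model$spec, tok$ids)
  M <- length(ner_classes())
  if (entities == "gold") {
    pm <- doc$mentions
    if (nrow(pm)) {
      iv <- t(vapply(seq_len(nrow(pm)), function(i)
        align_span(pm$start[i], pm$end[i], tok), integer(2)))
      mentions <- data.frame(id = pm$id, start = pm$start, end = pm$end,
                             etype = pm$etype, surface = pm$surface,
                             score = 1, stringsAsFactors = FALSE)
      mention_iv <- data.frame(id = pm$id, first = iv[, 1], last = iv[, 2],
                               stringsAsFactors = FALSE)
    } else {
      mentions <- empty_pred_mentions()
      mention_iv <- data.frame(id = character(), first = integer(),
                               last = integer(), stringsAsFactors = FALSE)
    }
  } else {
    cand <- enumerate_spans(tok$n, model$max_width)
    sr <- tape_span_reprs(g, model, X, cand$first, cand$last)
    h <- tanh(affine(sr$repr$value, model$params$ner.W1, model$params$ner.b1))
    z <- affine(h, model$params$ner.W2, model$params$ner.b2)
    z <- z - apply(z, 1L, max)
    p <- exp(z) / rowSums(exp(z))
    ci <- max.col(p, ties.method = "first")
    keep <- which(ci != M)
    if (length(keep)) {
      mentions <- data.frame(
        id = sprintf("P%d", seq_along(keep)),
        start = tok$starts[cand$first[keep]],
        end = tok$ends[cand$last[keep]],
        etype = ner_classes()[ci[keep]],
        surface = substring(doc$text, tok$starts[cand$first[keep]] + 1L,
                            tok$ends[cand$last[keep]]),
        score = p[cbind(keep, ci[keep])],
        first = cand$first[keep], last = cand$last[keep],
        stringsAsFactors = FALSE)
      # identical-span conflicts cannot arise (one argmax per span), but
      # identical (start,end) can via distinct token snappings: keep the best
      mentions <- mentions[order(-mentions$score), , drop = FALSE]
      mentions <- mentions[!duplicated(mentions[, c("start", "end")]), , drop = FALSE]
      mentions <- mentions[order(mentions$start, mentions$end), , drop = FALSE]
      rownames(mentions) <- NULL
    } else {
      mentions <- cbind(empty_pred_mentions(),
                        data.frame(first = integer(), last = integer()))
    }
    mention_iv <- mentions[, c("id", "first", "last")]
    mentions$first <- mentions$last <- NULL
  }
  pairs <- form_candidates(mentions)
  links <- empty_links()
  if (nrow(pairs)) {
    re <- tape_re_logits(g, model, X, NULL, pairs, mention_iv = mention_iv)
    z <- re$logits$value
    z <- z - apply(z, 1L, max)
    p2 <- exp(z) / rowSums(exp(z))
    links <- data.frame(gene = pairs$gene, disease = pairs$disease,
                        p_link = p2[, 2], stringsAsFactors = FALSE)
    links <- links[links$p_link > 0.5, , drop = FALSE]  # strictly greater
    rownames(links) <- NULL
  }
  list(mentions = mentions, links = links, tok = tok)
}

affine <- function(x, W, b) {
  x %*% W + matrix(b, nrow(x), ncol(W), byrow = TRUE)
}

empty_pred_mentions <- function() {
  data.frame(id = character(), start = integer(), end = integer(),
             etype = character(), surface = character(), score = numeric(),
             stringsAsFactors = FALSE)
}

empty_links <- function() {
  data.frame(gene = character(), disease = character(), p_link = numeric(),
             stringsAsFactors = FALSE)
}
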
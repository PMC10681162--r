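#' Form gene-disease relation candidates
#'
#' All cross pairs of gene and disease mentions within one document, gene
#' first, one candidate per unique (gene span, disease span) pair. Mentions
#' duplicated at identical coordinates deduplicate.
#'
#' @param mentions data.frame with columns `id`, `start`, `end`, `etype`.
#' @param gene_types entity types on the gene side (default `"Gene"`).
#' @return data.frame with columns `gene`, `disease` (mention ids).
#' @export
form_candidates <- function(mentions, gene_types = "Gene") {
  g <- mentions[mentions$etype %in% gene_types, , drop = FALSE]
  d <- mentions[mentions$etype == "Disease", , drop = FALSE]
  g <- g[!duplicated(g[, c("start", "end")]), , drop = FALSE]
  d <- d[!duplicated(d[, c("start", "end")]), , drop = FALSE]
  if (!nrow(g) || !nrow(d)) {
    return(data.frame(gene = character(), disease = character(),
                      stringsAsFactors = FALSE))
  }
  out <- expand.grid(gene = g$id, disease = d$id,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[out$gene != out$disease, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Max-pooled context between two spans
#'
#' Element-wise max over the embeddings of tokens strictly between the two
#' (token-aligned) spans. Adjacent spans, with no token in between, and
#' overlapping spans both yield the zero vector, the max-pool identity under
#' the empty-pool convention.
#'
#' @param span_a,span_b integer `c(first, last)` token intervals (1-based,
#'   inclusive), in either order.
#' @param embeddings n x H token matrix.
#' @return numeric vector of length H.
#' @export
between_context <- function(span_a, span_b, embeddings) {
  H <- ncol(embeddings)
  overlap <- span_a[1] <= span_b[2] && span_b[1] <= span_a[2]
  if (overlap) {
    spanrel_log("between_context", "overlapping spans; zero context")
    return(numeric(H))
  }
  lo <- if (span_a[2] < span_b[1]) span_a[2] else span_b[2]
  hi <- if (span_a[2] < span_b[1]) span_b[1] else span_a[1]
  if (hi - lo < 2L) return(numeric(H))
  apply(embeddings[(lo + 1L):(hi - 1L), , drop = FALSE], 2L, max)
}

#' Attention-weighted context pooling
#'
#' Computes `context = sum_i w_i * x_i` over the document's token encodings,
#' the weighted-sum form of attention. Weights default to a softmax over
#' scaled dot products of the query with the keys (non-negative, summing to
#' one, so the context lies in the convex hull of the values); a fixed weight
#' vector may be imposed instead.
#'
#' @param query numeric vector (key dimension).
#' @param keys n x Dk matrix.
#' @param values n x Dv matrix.
#' @param weights optional fixed weights (length n, summing to 1).
#' @return list with `weights` and `context`.
#' @export
attend <- function(query, keys, values, weights = NULL) {
  n <- nrow(keys)
  if (n == 0L) stop("no tokens to attend over")
  stopifnot(nrow(values) == n)
  if (is.null(weights)) {
    s <- drop(keys %*% matrix(query, ncol = 1)) / sqrt(length(query))
    s <- s - max(s)
    weights <- exp(s) / sum(exp(s))
  } else {
    stopifnot(length(weights) == n, all(weights >= 0),
              abs(sum(weights) - 1) < 1e-8)
  }
  list(weights = weights, context = drop(crossprod(values, weights)))
}

#' Score a relation candidate
#'
#' The four concatenated feature vectors (gene span representation, disease
#' span representation, between-context, attention context) pass through a
#' shallow two-class head; the final softmax gives the link probability, and
#' two entities are predicted linked iff `p_link` is strictly greater than
#' 0.5.
#'
#' @param features numeric feature vector.
#' @param head list with `W1`, `b1`, `W2`, `b2` (two output columns; the
#'   second is the positive/link class).
#' @return list with `p_link` and `linked` (`p_link > 0.5`, strict).
#' @export
score_link <- function(features, head) {
  h <- tanh(matrix(features, 1) %*% head$W1 + head$b1)
  z <- drop(h %*% head$W2 + head$b2)
  z <- z - max(z)
  p <- exp(z) / sum(exp(z))
  p_link <- unname(p[2])
  list(p_link = p_link, linked = p_link > 0.5)
}

#' Joint loss of the collaborative model
#'
#' The final training loss adds the relation head's binary cross-entropy to
#' the NER head's summed cross-entropy; gradients flow through both heads
#' into the shared encoder.
#'
#' @param ner scalar NER loss.
#' @param re_bce scalar RE binary cross-entropy.
#' @return list with components `ner_loss`, `re_loss`, `total`.
#' @export
joint_loss <- function(ner, re_bce) {
  if (!is.finite(ner) || !is.finite(re_bce)) {
    stop(sprintf("non-finite loss component (ner=%g, re=%g)", ner, re_bce))
  }
  list(ner_loss = ner, re_loss = re_bce, total = ner + re_bce)
}
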
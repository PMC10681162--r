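#' NER classification label set
#'
#' The twelve entity types plus the non-entity class `"O"`, in fixed order;
#' ties at the argmax break toward the lowest class index.
#'
#' @return character vector of length 13.
#' @export
ner_classes <- function() c(entity_types(), "O")

#' Enumerate all candidate spans
#'
#' Every token sub-sequence of width 1..`max_width` is a candidate entity, in
#' the span-based NER formulation; the count is
#' `sum over w of (n - w + 1)` for feasible widths.
#'
#' @param n token count.
#' @param max_width widest span considered (longer sub-sequences are ever
#'   less likely to be entities, so a cap is standard).
#' @return data.frame with 1-based inclusive token columns `first`, `last`
#'   and `width`.
#' @export
enumerate_spans <- function(n, max_width = 10L) {
  stopifnot(n >= 0, max_width >= 1)
  if (n == 0L) {
    return(data.frame(first = integer(), last = integer(), width = integer()))
  }
  out <- do.call(rbind, lapply(seq_len(min(max_width, n)), function(w) {
    first <- seq_len(n - w + 1L)
    data.frame(first = first, last = first + w - 1L, width = w)
  }))
  rownames(out) <- NULL
  out
}

#' Build a span representation
#'
#' Element-wise max-pooling over the span's token embeddings, concatenated
#' with a learned width embedding; widths beyond the table clamp to its last
#' row.
#'
#' @param first,last 1-based inclusive token interval.
#' @param embeddings n x H matrix of token vectors.
#' @param width_table max_width x W width-embedding matrix.
#' @return numeric vector of length `H + W`.
#' @export
span_representation <- function(first, last, embeddings, width_table) {
  stopifnot(first >= 1, last >= first, last <= nrow(embeddings))
  sub <- embeddings[first:last, , drop = FALSE]
  pooled <- apply(sub, 2L, max)
  w <- min(last - first + 1L, nrow(width_table))
  c(pooled, width_table[w, ])
}

#' Classify a span representation
#'
#' A shallow classifier (one tanh hidden layer) scores the thirteen classes;
#' probabilities come from a softmax. The argmax is the predicted type, with
#' deterministic ties toward the lowest class index; spans predicted `"O"`
#' are not forwarded to relation extraction.
#'
#' @param repr span representation vector (length H + W).
#' @param head list with matrices `W1`, `b1`, `W2`, `b2`.
#' @return list with `probs` (named over [ner_classes()]), `class_index`, and
#'   `label`.
#' @export
classify_span <- function(repr, head) {
  h <- tanh(matrix(repr, 1) %*% head$W1 + head$b1)
  z <- drop(h %*% head$W2 + head$b2)
  z <- z - max(z)
  p <- exp(z) / sum(exp(z))
  ci <- which.max(p)
  list(probs = stats::setNames(p, ner_classes()),
       class_index = ci, label = ner_classes()[ci])
}

#' Summed cross-entropy NER loss
#'
#' The span classifier trains by minimising
#' `-sum over observations o, types t of y[o,t] * log p[o,t]`, i.e. the sum
#' (not mean) of per-span cross-entropies over all scored spans (gold spans
#' plus sampled non-entity spans). Probabilities are clamped at `eps` before
#' the log.
#'
#' @param probs S x M matrix of class probabilities, one row per scored span.
#' @param gold integer vector of gold class indices (1-based).
#' @param reduction `"sum"` (default; the objective is written as a plain sum) or `"mean"`.
#' @param eps clamp for log(0).
#' @return non-negative scalar.
#' @export
ner_loss <- function(probs, gold, reduction = c("sum", "mean"), eps = 1e-12) {
  reduction <- match.arg(reduction)
  if (length(gold) == 0L) return(0)
  stopifnot(nrow(probs) == length(gold))
  picked <- probs[cbind(seq_along(gold), as.integer(gold))]
  per <- -log(pmax(picked, eps))
  if (reduction == "sum") sum(per) else mean(per)
}
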
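#' Contextual encoder specification
#'
#' Describes the encoder that turns subword ids into contextual token vectors
#' ("knowledge vectors"). The default `tiny` kind is a small trainable
#' transformer (token + position embeddings, multi-head scaled-dot-product
#' self-attention with residual connections and a tanh feed-forward block)
#' sized for minutes-scale CPU training; the encoder contract (token ids in,
#' an n x H matrix out) is the only coupling point a pretrained adapter would
#' need to satisfy.
#'
#' @param kind `"tiny"` (trainable, default).
#' @param H hidden width.
#' @param layers number of transformer layers.
#' @param heads attention heads (must divide `H`).
#' @param ffn feed-forward inner width.
#' @param max_len maximum tokens encoded in one window; longer inputs use a
#'   sliding window with overlap mean-merging in [encode()].
#' @param seq_encoder `"birnn"` (a bidirectional recurrent layer producing
#'   the keys/values for relation attention) or `"identity"` (pass the
#'   encoder output through unchanged).
#' @return object of class `encoder_spec`.
#' @export
encoder_spec <- function(kind = "tiny", H = 64L, layers = 2L, heads = 2L,
                         ffn = 128L, max_len = 512L,
                         seq_encoder = c("birnn", "identity")) {
  seq_encoder <- match.arg(seq_encoder)
  stopifnot(H > 0, layers >= 1, heads >= 1, H %% heads == 0, ffn > 0,
            H %% 2 == 0)
  structure(list(kind = kind, H = as.integer(H), layers = as.integer(layers),
                 heads = as.integer(heads), ffn = as.integer(ffn),
                 max_len = as.integer(max_len), seq_encoder = seq_encoder),
            class = "encoder_spec")
}

rand_mat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

# Seeded Gaussian initialisation; weight matrices use 1/sqrt(fan_in) scaling,
# output projections of residual branches are damped.
init_encoder_params <- function(spec, vocab_size, seed) {
  with_seed(seed, {
    H <- spec$H; FF <- spec$ffn
    p <- list(
      emb = rand_mat(vocab_size, H, 0.1),
      pos = rand_mat(spec$max_len, H, 0.1))
    for (l in seq_len(spec$layers)) {
      pre <- sprintf("l%d.", l)
      p[[paste0(pre, "Wq")]] <- rand_mat(H, H, 1 / sqrt(H))
      p[[paste0(pre, "Wk")]] <- rand_mat(H, H, 1 / sqrt(H))
      p[[paste0(pre, "Wv")]] <- rand_mat(H, H, 1 / sqrt(H))
      p[[paste0(pre, "Wo")]] <- rand_mat(H, H, 0.5 / sqrt(H))
      p[[paste0(pre, "W1")]] <- rand_mat(H, FF, 1 / sqrt(H))
      p[[paste0(pre, "b1")]] <- matrix(0, 1, FF)
      p[[paste0(pre, "W2")]] <- rand_mat(FF, H, 0.5 / sqrt(FF))
      p[[paste0(pre, "b2")]] <- matrix(0, 1, H)
    }
    if (spec$seq_encoder == "birnn") {
      Hr <- H %/% 2L
      p$rnn.Wf <- rand_mat(H, Hr, 1 / sqrt(H))
      p$rnn.Uf <- rand_mat(Hr, Hr, 1 / sqrt(Hr))
      p$rnn.bf <- matrix(0, 1, Hr)
      p$rnn.Wb <- rand_mat(H, Hr, 1 / sqrt(H))
      p$rnn.Ub <- rand_mat(Hr, Hr, 1 / sqrt(Hr))
      p$rnn.bb <- matrix(0, 1, Hr)
      p$rnn.Wkv <- rand_mat(H, H, 1 / sqrt(H))
      p$rnn.bkv <- matrix(0, 1, H)
    }
    p
  })
}

# Transformer forward over one window of token ids; returns the n x H node.
encoder_forward <- function(g, params, spec, ids) {
  n <- length(ids)
  stopifnot(n >= 1, n <= spec$max_len)
  H <- spec$H
  dh <- H %/% spec$heads
  E <- ad_param(g, params$emb, "emb")
  P <- ad_param(g, params$pos, "pos")
  X <- ad_add(g, ad_rows(g, E, ids), ad_rows(g, P, seq_len(n)))
  for (l in seq_len(spec$layers)) {
    pre <- sprintf("l%d.", l)
    pm <- function(nm) ad_param(g, params[[paste0(pre, nm)]], paste0(pre, nm))
    Q <- ad_matmul(g, X, pm("Wq"))
    K <- ad_matmul(g, X, pm("Wk"))
    V <- ad_matmul(g, X, pm("Wv"))
    outs <- vector("list", spec$heads)
    for (h in seq_len(spec$heads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      Qh <- ad_cols(g, Q, cols)
      Kh <- ad_cols(g, K, cols)
      Vh <- ad_cols(g, V, cols)
      S <- ad_scale(g, ad_matmul(g, Qh, ad_transpose(g, Kh)), 1 / sqrt(dh))
      A <- ad_softmax_rows(g, S)
      outs[[h]] <- ad_matmul(g, A, Vh)
    }
    O <- if (spec$heads > 1L) ad_cbind(g, outs) else outs[[1]]
    X <- ad_add(g, X, ad_matmul(g, O, pm("Wo")))
    FFh <- ad_tanh(g, ad_add(g, ad_matmul(g, X, pm("W1")), pm("b1")))
    X <- ad_add(g, X, ad_add(g, ad_matmul(g, FFh, pm("W2")), pm("b2")))
  }
  X
}

# Sequence encoder for relation-attention keys/values: a bidirectional tanh
# recurrent layer over the encoder output (or identity pass-through).
seq_encoder_forward <- function(g, params, spec, X) {
  if (spec$seq_encoder == "identity") return(X)
  n <- nrow(X$value)
  Hr <- spec$H %/% 2L
  run_dir <- function(W, U, b, order) {
    Wn <- ad_param(g, params[[W]], W)
    Un <- ad_param(g, params[[U]], U)
    bn <- ad_param(g, params[[b]], b)
    XW <- ad_matmul(g, X, Wn)
    h <- ad_const(g, matrix(0, 1, Hr))
    hs <- vector("list", n)
    for (t in order) {
      h <- ad_tanh(g, ad_add(g, ad_add(g, ad_rows(g, XW, t),
                                       ad_matmul(g, h, Un)), bn))
      hs[[t]] <- h
    }
    ad_rbind(g, hs)
  }
  Hf <- run_dir("rnn.Wf", "rnn.Uf", "rnn.bf", seq_len(n))
  Hb <- run_dir("rnn.Wb", "rnn.Ub", "rnn.bb", rev(seq_len(n)))
  ad_add(g, ad_matmul(g, ad_cbind(g, list(Hf, Hb)),
                      ad_param(g, params$rnn.Wkv, "rnn.Wkv")),
         ad_param(g, params$rnn.bkv, "rnn.bkv"))
}

#' Encode a tokenized document into contextual vectors
#'
#' Inference-mode forward pass: deterministic given parameters and input.
#' Documents longer than the encoder window are processed with a half-window
#' stride; vectors of tokens covered by several windows are mean-merged.
#'
#' @param tokdoc a `tokenized_document`.
#' @param model a [relex_model()] (or a list with `params` and `spec`).
#' @return an n x H numeric matrix, one row per token.
#' @export
encode <- function(tokdoc, model) {
  spec <- model$spec; params <- model$params
  n <- tokdoc$n
  if (n == 0L) return(matrix(0, 0L, spec$H))
  win <- spec$max_len
  if (n <= win) {
    g <- ad_graph()
    return(encoder_forward(g, params, spec, tokdoc$ids)$value)
  }
  stride <- max(1L, win %/% 2L)
  acc <- matrix(0, n, spec$H)
  cnt <- numeric(n)
  start <- 1L
  repeat {
    end <- min(start + win - 1L, n)
    g <- ad_graph()
    val <- encoder_forward(g, params, spec, tokdoc$ids[start:end])$value
    acc[start:end, ] <- acc[start:end, ] + val
    cnt[start:end] <- cnt[start:end] + 1
    if (end == n) break
    start <- start + stride
  }
  acc / cnt
}
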
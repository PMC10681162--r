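#' Training configuration
#'
#' Joint optimisation settings. The optimizer is AdamW with linear learning
#' rate warmup over the first `warmup` proportion of steps followed by
#' linear decay; the default initial rate of 6e-5 is the customary
#' fine-tuning setting for large pretrained encoders, while from-scratch
#' desk-scale training of the tiny encoder typically uses a larger rate
#' (see the methods vignette).
#'
#' @param epochs passes over the training documents.
#' @param batch_size documents per optimizer step.
#' @param lr initial learning rate.
#' @param warmup warmup proportion in [0, 1].
#' @param weight_decay decoupled weight decay.
#' @param seed seed controlling document order, negative sampling and
#'   initialisation (streams derived by keyed hashing).
#' @param folds cross-validation folds (k >= 2).
#' @param de_augment apply [add_direct_edges()] to training documents, so
#'   the relation head learns from direct gene-disease labels.
#' @param only_re train only the relation head on gold entities (the onlyRE
#'   regime); the NER loss is dropped from the sum.
#' @param neg_spans sampled non-entity spans per document per pass.
#' @param neg_pairs negative gene-disease pairs kept per document per pass.
#' @param reduction loss reduction, `"sum"` (the summation form of the objective) or `"mean"`.
#' @param eval_target relation evaluation target set, `"closure"` or
#'   `"raw"` (see [gold_graph()]).
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 20L, batch_size = 4L, lr = 6e-5,
                         warmup = 0.1, weight_decay = 0.01, seed = 1L,
                         folds = 5L, de_augment = TRUE, only_re = FALSE,
                         neg_spans = 100L, neg_pairs = 50L,
                         reduction = c("sum", "mean"),
                         eval_target = c("closure", "raw")) {
  stopifnot(lr > 0, warmup >= 0, warmup <= 1, folds >= 2, epochs >= 1,
            batch_size >= 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 warmup = warmup, weight_decay = weight_decay,
                 seed = as.integer(seed), folds = as.integer(folds),
                 de_augment = isTRUE(de_augment), only_re = isTRUE(only_re),
                 neg_spans = as.integer(neg_spans),
                 neg_pairs = as.integer(neg_pairs),
                 reduction = match.arg(reduction),
                 eval_target = match.arg(eval_target)),
            class = "train_config")
}

#' Learning-rate schedule: linear warmup, then linear decay
#'
#' Zero at step 0, rising linearly to `lr` at the end of warmup
#' (`warmup * total` steps), then decaying linearly to zero at `total`.
#'
#' @param step current step (0-based).
#' @param total total optimizer steps.
#' @param lr peak learning rate.
#' @param warmup warmup proportion.
#' @return the learning rate at `step`.
#' @export
lr_schedule <- function(step, total, lr = 6e-5, warmup = 0.1) {
  w <- warmup * total
  ifelse(step < w, lr * step / max(w, 1e-12),
         lr * pmax(0, (total - step) / max(total - w, 1e-12)))
}

adamw_init <- function() list(m = list(), v = list(), t = 0L)

adamw_step <- function(opt, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 0) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    if (is.null(opt$m[[nm]])) {
      opt$m[[nm]] <- gr * 0
      opt$v[[nm]] <- gr * 0
    }
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * gr
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * gr^2
    upd <- (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
    params[[nm]] <- params[[nm]] - lr * upd - lr * weight_decay * params[[nm]]
  }
  list(opt = opt, params = params)
}

#' Split a corpus into k document-level folds
#'
#' Disjoint folds partitioning the corpus, sizes differing by at most one
#' (earlier folds take the remainder), deterministic under the seed; no
#' document appears in two folds.
#'
#' @param corpus list of documents (any list).
#' @param k number of folds.
#' @param seed shuffle seed.
#' @return list of k integer index vectors.
#' @export
kfold_split <- function(corpus, k = 5L, seed = 1L) {
  n <- length(corpus)
  if (n < k) stop(sprintf("corpus of %d documents cannot form %d folds", n, k))
  idx <- with_seed(derive_seed(seed, "kfold"), sample(n))
  base <- n %/% k
  rem <- n %% k
  sizes <- rep(base, k) + c(rep(1L, rem), rep(0L, k - rem))
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-k] + 1L)
  lapply(seq_len(k), function(i) sort(idx[starts[i]:ends[i]]))
}

#' Train the joint model on an annotated corpus
#'
#' Optimises the shared encoder and both heads under the summed loss with
#' AdamW and the warmup/decay schedule. With `cfg$de_augment`, training
#' documents are direct-edge augmented first (evaluation gold is handled
#' separately; see [gold_graph()]). All randomness (document order, negative
#' sampling) derives from `cfg$seed`, so identical configurations reproduce
#' identical checkpoints on one platform. Aborts with the loss trace if the
#' loss turns non-finite.
#'
#' @param corpus list of validated `annotated_document`s.
#' @param cfg a [train_config()].
#' @param spec an [encoder_spec()].
#' @param tokenizer optional pretrained [bpe_train()] tokenizer; by default
#'   one is trained on the corpus text.
#' @param model optional warm-start [relex_model()].
#' @param vocab_size BPE vocabulary size when training the tokenizer here.
#' @return list with `model` (trained) and `trace` (data.frame of per-step
#'   losses).
#' @export
train_model <- function(corpus, cfg = train_config(), spec = encoder_spec(),
                        tokenizer = NULL, model = NULL, vocab_size = 300L) {
  if (!length(corpus)) stop("cannot train on an empty corpus")
  if (is.null(tokenizer)) {
    tokenizer <- bpe_train(vapply(corpus, `[[`, character(1), "text"),
                           vocab_size = vocab_size)
  }
  if (is.null(model)) {
    model <- relex_model(tokenizer, spec, seed = derive_seed(cfg$seed, "init"))
  }
  docs <- if (cfg$de_augment) lapply(corpus, add_direct_edges) else corpus
  preps <- lapply(docs, function(d) prepare_document(model, d))
  nd <- length(preps)
  steps_per_epoch <- ceiling(nd / cfg$batch_size)
  total_steps <- cfg$epochs * steps_per_epoch
  opt <- adamw_init()
  trace <- vector("list", total_steps)
  step <- 0L
  with_seed(derive_seed(cfg$seed, "train"), {
    for (epoch in seq_len(cfg$epochs)) {
      order <- sample(nd)
      for (b in seq_len(steps_per_epoch)) {
        batch <- order[((b - 1L) * cfg$batch_size + 1L):min(b * cfg$batch_size, nd)]
        grads <- list()
        batch_loss <- 0
        for (di in batch) {
          fw <- model_forward(model, preps[[di]],
                              neg_spans = cfg$neg_spans,
                              neg_pairs = cfg$neg_pairs,
                              only_re = cfg$only_re,
                              reduction = cfg$reduction)
          if (!is.finite(fw$total_loss)) {
            stop(sprintf(
              "training diverged: non-finite loss at epoch %d, step %d (trace has %d steps)",
              epoch, step, step))
          }
          batch_loss <- batch_loss + fw$total_loss
          ad_backward(fw$g, fw$loss)
          for (nm in names(gr <- ad_grads(fw$g))) {
            grads[[nm]] <- if (is.null(grads[[nm]])) gr[[nm]] else grads[[nm]] + gr[[nm]]
          }
        }
        lr_t <- lr_schedule(step, total_steps, cfg$lr, cfg$warmup)
        st <- adamw_step(opt, model$params, grads, lr_t,
                         weight_decay = cfg$weight_decay)
        opt <- st$opt
        model$params <- st$params
        step <- step + 1L
        trace[[step]] <- data.frame(step = step, epoch = epoch,
                                    lr = lr_t, loss = batch_loss / length(batch))
      }
      spanrel_log("train", "epoch %d/%d mean step loss %.4f", epoch,
                  cfg$epochs, trace[[step]]$loss)
    }
  })
  list(model = model, trace = do.call(rbind, trace))
}

# Predict a document set and score it against the gold target set.
evaluate_model <- function(model, docs, cfg) {
  mode <- if (cfg$only_re) "gold" else "predicted"
  preds <- lapply(docs, function(doc) {
    pr <- predict_document(model, doc, entities = mode)
    build_graph(doc, links = pr$links, mentions = pr$mentions)
  })
  gold <- gold_graph(docs, target = cfg$eval_target)
  compare_graphs(gold, graphs_union(preds))
}

#' Cross-validated training and graph-based evaluation
#'
#' Document-level k-fold cross-validation: for each fold, trains on the
#' remaining folds and scores the held-out documents by graph comparison
#' (see [compare_graphs()]). Fold assignment, sampling and initialisation
#' all derive from `cfg$seed`.
#'
#' @param corpus list of `annotated_document`s.
#' @param cfg a [train_config()].
#' @param spec an [encoder_spec()].
#' @param folds optional precomputed [kfold_split()] result (shared across
#'   ablation arms).
#' @param vocab_size BPE vocabulary size.
#' @return data.frame of per-fold metrics with mean/sd rows in
#'   `attr(, "summary")`.
#' @export
cross_validate <- function(corpus, cfg = train_config(), spec = encoder_spec(),
                           folds = NULL, vocab_size = 300L) {
  folds <- folds %||% kfold_split(corpus, cfg$folds, cfg$seed)
  rows <- lapply(seq_along(folds), function(fi) {
    test_idx <- folds[[fi]]
    fit <- train_model(corpus[-test_idx], cfg, spec, vocab_size = vocab_size)
    rep <- evaluate_model(fit$model, corpus[test_idx], cfg)
    data.frame(fold = fi,
               entity_precision = rep$entity$precision,
               entity_recall = rep$entity$recall,
               entity_f1 = rep$entity$f1,
               relation_precision = rep$relation$precision,
               relation_recall = rep$relation$recall,
               relation_f1 = rep$relation$f1)
  })
  out <- do.call(rbind, rows)
  metrics <- setdiff(names(out), "fold")
  attr(out, "summary") <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(out[[m]]), numeric(1)),
    sd = vapply(metrics, function(m) stats::sd(out[[m]]), numeric(1)),
    row.names = NULL)
  out
}

#' Paired ablation: direct-edge augmentation x onlyRE
#'
#' Runs four cross-validated arms (with/without direct-edge augmentation,
#' joint vs onlyRE) over byte-identical fold assignments and seeds, enabling
#' paired comparison of the training signal: the direct-edge arms differ
#' only in the relation labels seen at training time, and all arms are
#' scored against the same evaluation target set.
#'
#' @param corpus list of `annotated_document`s.
#' @param cfg base [train_config()] (its `de_augment`/`only_re` are
#'   overridden per arm).
#' @param spec an [encoder_spec()].
#' @param vocab_size BPE vocabulary size.
#' @return named list of four per-fold data.frames:
#'   `joint_de`, `joint_node`, `onlyre_de`, `onlyre_node`, plus `folds`.
#' @export
ablation_run <- function(corpus, cfg = train_config(), spec = encoder_spec(),
                         vocab_size = 300L) {
  folds <- kfold_split(corpus, cfg$folds, cfg$seed)
  arm <- function(de, ore) {
    acfg <- cfg
    acfg$de_augment <- de
    acfg$only_re <- ore
    cross_validate(corpus, acfg, spec, folds = folds, vocab_size = vocab_size)
  }
  list(joint_de = arm(TRUE, FALSE), joint_node = arm(FALSE, FALSE),
       onlyre_de = arm(TRUE, TRUE), onlyre_node = arm(FALSE, TRUE),
       folds = folds)
}
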
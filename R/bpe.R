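#' Train a byte-pair-encoding tokenizer
#'
#' Learns greedy merges over within-word character pairs from a text corpus.
#' The vocabulary starts from all single characters seen in training plus an
#' unknown marker; merges are added most-frequent-first (ties broken
#' lexicographically for determinism) until `vocab_size` is reached or no
#' pair occurs at least twice. Out-of-vocabulary words at tokenization time
#' decompose into subword pieces; characters never seen in training map to
#' the unknown id but keep their offsets.
#'
#' @param texts character vector of training texts.
#' @param vocab_size target vocabulary size (characters + merged pieces).
#' @return an object of class `bpe_tokenizer`.
#' @export
bpe_train <- function(texts, vocab_size = 400L) {
  words <- unlist(regmatches(texts, gregexpr("\\S+", texts)))
  if (!length(words)) stop("no words in training texts")
  wt <- table(words)
  seqs <- lapply(names(wt), function(w) strsplit(w, "")[[1]])
  counts <- as.integer(wt)
  chars <- sort(unique(unlist(seqs)))
  merges <- list()
  n_merges <- max(0L, vocab_size - length(chars) - 1L)
  while (length(merges) < n_merges) {
    pair_counts <- new.env(parent = emptyenv())
    for (k in seq_along(seqs)) {
      s <- seqs[[k]]
      if (length(s) < 2L) next
      for (i in seq_len(length(s) - 1L)) {
        key <- paste0(s[i], "\r", s[i + 1L])
        pair_counts[[key]] <- (pair_counts[[key]] %||% 0L) + counts[k]
      }
    }
    keys <- ls(pair_counts)
    if (!length(keys)) break
    vals <- vapply(keys, function(k) pair_counts[[k]], integer(1))
    best <- max(vals)
    if (best < 2L) break
    key <- sort(keys[vals == best])[1]
    pair <- strsplit(key, "\r", fixed = TRUE)[[1]]
    merges[[length(merges) + 1L]] <- pair
    seqs <- lapply(seqs, merge_pair, pair)
  }
  vocab <- c("<unk>", chars,
             vapply(merges, function(p) paste0(p[1], p[2]), character(1)))
  vocab <- unique(vocab)
  ranks <- seq_along(merges)
  names(ranks) <- vapply(merges, function(p) paste0(p[1], "\r", p[2]), character(1))
  structure(list(vocab = vocab, merges = merges, merge_rank = ranks),
            class = "bpe_tokenizer")
}

merge_pair <- function(s, pair) {
  if (length(s) < 2L) return(s)
  out <- character(0)
  i <- 1L
  while (i <= length(s)) {
    if (i < length(s) && s[i] == pair[1] && s[i + 1L] == pair[2]) {
      out <- c(out, paste0(s[i], s[i + 1L]))
      i <- i + 2L
    } else {
      out <- c(out, s[i])
      i <- i + 1L
    }
  }
  out
}

# Apply learned merges to one word, lowest-rank first; returns the pieces.
bpe_encode_word <- function(tok, w) {
  s <- strsplit(w, "")[[1]]
  if (!length(tok$merge_rank)) return(s)
  repeat {
    if (length(s) < 2L) break
    keys <- paste0(s[-length(s)], "\r", s[-1L])
    r <- tok$merge_rank[keys]
    if (all(is.na(r))) break
    i <- which.min(r)
    s <- c(if (i > 1L) s[1:(i - 1L)], paste0(s[i], s[i + 1L]),
           if (i + 1L < length(s)) s[(i + 2L):length(s)])
  }
  s
}

#' Tokenize text with character-offset alignment
#'
#' Splits on whitespace, applies BPE merges within words, and records for
#' every subword its 0-based half-open character interval into the original
#' text. Offsets are ascending and non-overlapping; every non-whitespace
#' character is covered by exactly one token.
#'
#' @param tok a [bpe_train()] tokenizer.
#' @param text input text (any unicode string).
#' @param doc_id optional document id carried along.
#' @return object of class `tokenized_document` with fields `tokens`,
#'   `starts`, `ends`, `ids` (vocabulary indices; unknown pieces map to the
#'   `<unk>` id) and `n`.
#' @export
bpe_tokenize <- function(tok, text, doc_id = "doc") {
  stopifnot(inherits(tok, "bpe_tokenizer"))
  m <- gregexpr("\\S+", text)[[1]]
  tokens <- character(0); starts <- integer(0); ends <- integer(0)
  if (m[1] != -1L) {
    ws <- regmatches(text, list(m))[[1]]
    w_start <- as.integer(m) - 1L
    for (i in seq_along(ws)) {
      pieces <- bpe_encode_word(tok, ws[i])
      lens <- nchar(pieces)
      off <- w_start[i] + cumsum(c(0L, lens[-length(lens)]))
      tokens <- c(tokens, pieces)
      starts <- c(starts, off)
      ends <- c(ends, off + lens)
    }
  }
  ids <- match(tokens, tok$vocab)
  ids[is.na(ids)] <- 1L   # <unk>
  structure(list(doc_id = doc_id, tokens = tokens, starts = starts,
                 ends = ends, ids = ids, n = length(tokens)),
            class = "tokenized_document")
}

#' Align a character span to token indices
#'
#' Returns the minimal token interval whose character coverage contains the
#' span: all tokens overlapping `[start, end)`. Mention boundaries that split
#' a subword snap outward to the covering subword. A span overlapping no
#' token (whitespace-only) is an alignment error.
#'
#' @param start,end 0-based half-open character interval.
#' @param tokdoc a `tokenized_document`.
#' @return integer vector `c(first, last)` of 1-based token indices
#'   (inclusive).
#' @export
align_span <- function(start, end, tokdoc) {
  stopifnot(start < end)
  hit <- which(tokdoc$starts < end & tokdoc$ends > start)
  if (!length(hit)) {
    stop(sprintf("span [%d,%d) overlaps no token (whitespace-only?) in '%s'",
                 start, end, tokdoc$doc_id))
  }
  c(min(hit), max(hit))
}
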
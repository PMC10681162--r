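#' Character 3-grams of a string
#'
#' Lowercased sliding window of width 3, with multiset semantics (repeated
#' grams kept). Strings shorter than three characters yield a single padded
#' gram (`"^x$"` style) so that short gene symbols such as "AR" still have a
#' non-empty profile.
#'
#' @param s a string.
#' @return character vector of 3-grams (possibly with duplicates); empty for
#'   the empty string.
#' @export
char_3grams <- function(s) {
  s <- tolower(s)
  n <- nchar(s)
  if (n == 0L) return(character(0))
  if (n < 3L) return(paste0("^", s, "$"))
  substring(s, 1:(n - 2L), 3:n)
}

#' Build an entity-linking dictionary
#'
#' Entries carry a unique identifier, a canonical name and synonyms; a
#' char-3-gram count profile is precomputed for every name/synonym string
#' and an inverted gram index supports candidate pruning during approximate
#' search. Gene namespaces follow NCBI Gene style identifiers, disease
#' namespaces EFO style, but any identifier scheme works.
#'
#' @param entries data.frame with columns `identifier`, `name` and
#'   optionally `synonyms` (a `;`-separated string).
#' @param namespace `"gene"` or `"disease"`.
#' @return object of class `el_dictionary`.
#' @export
build_dictionary <- function(entries, namespace = c("gene", "disease")) {
  namespace <- match.arg(namespace)
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  stopifnot(all(c("identifier", "name") %in% names(entries)))
  if (anyDuplicated(entries$identifier)) {
    stop("identifiers must be unique within a namespace")
  }
  strings <- character(0); owner <- integer(0)
  for (i in seq_len(nrow(entries))) {
    syn <- entries$synonyms[i] %||% NA_character_
    ss <- c(entries$name[i],
            if (!is.na(syn) && nzchar(syn)) strsplit(syn, ";", fixed = TRUE)[[1]])
    ss <- trimws(ss)
    ss <- ss[nzchar(ss)]
    strings <- c(strings, ss)
    owner <- c(owner, rep(i, length(ss)))
  }
  profiles <- lapply(strings, function(s) table(char_3grams(s)))
  index <- new.env(parent = emptyenv())
  for (k in seq_along(profiles)) {
    for (gm in names(profiles[[k]])) {
      index[[gm]] <- c(index[[gm]], k)
    }
  }
  structure(list(entries = entries, namespace = namespace, strings = strings,
                 owner = owner, profiles = profiles, index = index),
            class = "el_dictionary")
}

#' Read a dictionary from TSV
#'
#' Expected columns: identifier, name, then any number of synonym columns
#' (or a single `;`-separated synonyms column). No header required.
#'
#' @param path TSV file path.
#' @param namespace `"gene"` or `"disease"`.
#' @return an `el_dictionary`.
#' @export
read_dictionary <- function(path, namespace = c("gene", "disease")) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           quote = "", colClasses = "character")
  syn <- if (ncol(tab) > 2L) {
    apply(tab[, -(1:2), drop = FALSE], 1L, function(r)
      paste(r[nzchar(r)], collapse = ";"))
  } else ""
  build_dictionary(data.frame(identifier = tab[[1]], name = tab[[2]],
                              synonyms = syn, stringsAsFactors = FALSE),
                   match.arg(namespace))
}

cosine_gram_sim <- function(qa, qb) {
  shared <- intersect(names(qa), names(qb))
  if (!length(shared)) return(0)
  num <- sum(as.numeric(qa[shared]) * as.numeric(qb[shared]))
  num / sqrt(sum(as.numeric(qa)^2) * sum(as.numeric(qb)^2))
}

#' Link a mention surface to a dictionary identifier
#'
#' Approximate nearest-neighbour search over char-3-gram count profiles:
#' candidate entries are pruned through the inverted gram index (any entry
#' sharing at least one gram — every entry with non-zero cosine, so recall
#' against exhaustive search is exact), ranked by cosine similarity, and the
#' best identifier is returned when its similarity reaches `min_sim`.
#' Surfaces sharing no gram with any entry return `NA`. Protein mentions
#' should be linked against the gene namespace: the encoding gene's
#' identifier is endowed.
#'
#' @param surface mention string.
#' @param dict an `el_dictionary`.
#' @param min_sim minimum cosine similarity (default 0.7).
#' @return the identifier string, or `NA_character_`.
#' @export
link_entity <- function(surface, dict, min_sim = 0.7) {
  if (!length(dict$strings)) {
    warning("empty dictionary; all queries link to NA")
    return(NA_character_)
  }
  q <- table(char_3grams(surface))
  if (!length(q)) return(NA_character_)
  cand <- unique(unlist(lapply(names(q), function(gm) dict$index[[gm]])))
  if (!length(cand)) return(NA_character_)
  sims <- vapply(cand, function(k) cosine_gram_sim(q, dict$profiles[[k]]),
                 numeric(1))
  best <- cand[order(-sims, dict$owner[cand])][1]
  if (max(sims) >= min_sim) dict$entries$identifier[dict$owner[best]]
  else NA_character_
}

#' Link the nodes of a knowledge graph
#'
#' Fills node identifiers: Gene and Protein nodes link against the gene
#' dictionary (proteins receive the encoding gene's identifier), Disease
#' nodes against the disease dictionary; trigger nodes stay unlinked.
#'
#' @param g a `knowledge_graph`.
#' @param gene_dict,disease_dict `el_dictionary`s (either may be NULL).
#' @param min_sim cosine threshold.
#' @return the graph with identifiers filled where a link was found.
#' @export
link_graph <- function(g, gene_dict = NULL, disease_dict = NULL, min_sim = 0.7) {
  nodes <- g$nodes
  for (i in seq_len(nrow(nodes))) {
    dict <- switch(nodes$etype[i],
                   Gene = gene_dict, Protein = gene_dict,
                   Disease = disease_dict, NULL)
    if (!is.null(dict)) {
      nodes$identifier[i] <- link_entity(nodes$surface[i], dict, min_sim)
    }
  }
  knowledge_graph(nodes, g$edges)
}
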
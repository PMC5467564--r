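# Cross-document sentence linking. An offline pass scores every sentence
# pair of a corpus with the combined similarity and keeps the pairs above
# a threshold, additionally capping each sentence at its top_k strongest
# links (a link survives when it is within the top_k of at least one
# endpoint, which preserves graph symmetry). The resulting graph lets a
# reader jump from a sentence to topically related sentences in the same
# or other articles. Links are stored once per unordered pair, in
# canonical (lexicographic doc_id, sent_id) order.

#' Linking configuration
#'
#' @param threshold minimal scaled score (0-5 scale) for a link to be kept
#'   (default 3.5).
#' @param top_k keep at most this many links per sentence, best-first
#'   (default 10); a link survives if it makes the cut for either
#'   endpoint.
#' @param include_intra also link sentences within the same document
#'   (default `TRUE`).
#' @param sim the `sim_config` used to score pairs.
#' @return an object of class `link_config`.
#' @export
link_config <- function(threshold = 3.5, top_k = 10L, include_intra = TRUE,
                        sim = sim_config()) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 5,
            is.numeric(top_k), length(top_k) == 1L, top_k >= 1,
            inherits(sim, "sim_config"))
  structure(list(threshold = threshold, top_k = as.integer(top_k),
                 include_intra = isTRUE(include_intra), sim = sim),
            class = "link_config")
}

.empty_links <- function() {
  tibble::tibble(doc_a = character(0), sent_a = character(0),
                 doc_b = character(0), sent_b = character(0),
                 score = numeric(0), cross_document = logical(0))
}

# precompute per-sentence normalized words (and registry) once
.link_sentence_table <- function(corpus, config) {
  sents <- corpus_sentences(corpus)
  tibble::tibble(
    doc_id = vapply(sents, `[[`, "", "doc_id"),
    sent_id = vapply(sents, `[[`, "", "sent_id"),
    words = lapply(sents, .content_words, config = config$sim)
  )
}

.score_pair <- function(words_a, words_b, config) {
  w <- config$sim$weights
  enabled <- names(w)[w > 0]
  count <- function(ws) {
    if (!length(ws)) return(integer(0))
    tab <- table(ws)
    stats::setNames(as.integer(tab), names(tab))
  }
  metrics <- vapply(enabled, function(m) {
    switch(m,
      vsm = cosine(count(words_a), count(words_b)),
      taxonomy = aligned_word_score(
        words_a, words_b,
        function(a, b) lin_similarity(config$sim$taxonomy, a, b)),
      embedding = aligned_word_score(
        words_a, words_b,
        function(a, b) embedding_word_sim(config$sim$vectors, a, b))
    )
  }, numeric(1))
  5 * sum(w[enabled] * metrics) / sum(w[enabled])
}

# score the pairs (i, j), i < j by table position, honoring include_intra;
# returns candidate links (>= threshold) in canonical order
.score_new_pairs <- function(tab, from, config) {
  n <- nrow(tab)
  rows <- list()
  for (i in seq_len(n - 1L)) {
    j_start <- max(i + 1L, from)
    if (j_start > n) next
    for (j in j_start:n) {
      same_doc <- tab$doc_id[i] == tab$doc_id[j]
      if (same_doc && !config$include_intra) next
      s <- .score_pair(tab$words[[i]], tab$words[[j]], config)
      if (s < config$threshold) next
      a <- c(tab$doc_id[i], tab$sent_id[i])
      b <- c(tab$doc_id[j], tab$sent_id[j])
      if (paste(a, collapse = "\r") > paste(b, collapse = "\r")) {
        tmp <- a; a <- b; b <- tmp
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        doc_a = a[1], sent_a = a[2], doc_b = b[1], sent_b = b[2],
        score = s, cross_document = !same_doc)
    }
  }
  dplyr::bind_rows(c(list(.empty_links()), rows))
}

# apply the mutual top_k cap to a candidate set
.apply_top_k <- function(candidates, top_k) {
  cand <- dplyr::arrange(candidates, doc_a, sent_a, doc_b, sent_b)
  if (!nrow(cand)) return(cand)
  key_a <- paste(cand$doc_a, cand$sent_a, sep = "\r")
  key_b <- paste(cand$doc_b, cand$sent_b, sep = "\r")
  keep <- logical(nrow(cand))
  for (k in unique(c(key_a, key_b))) {
    touching <- which(key_a == k | key_b == k)
    ord <- touching[order(-cand$score[touching], touching)]
    keep[ord[seq_len(min(top_k, length(ord)))]] <- TRUE
  }
  cand[keep, , drop = FALSE]
}

#' Build the sentence link graph of a corpus
#'
#' Scores every sentence pair (all pairs, exhaustively — the pass is meant
#' to run offline when a publication enters the corpus), keeps pairs at or
#' above the threshold, and caps each sentence's links at `top_k`. The
#' result is deterministic: same corpus and configuration, same graph.
#'
#' @param corpus a non-empty preprocessed `lit_corpus`.
#' @param config a `link_config`.
#' @return an object of class `link_graph`: list with `corpus_id`,
#'   `config` (snapshot), `sentences` (registry tibble `doc_id`,
#'   `sent_id`), `candidates` (all above-threshold pairs, kept so the
#'   graph can be updated incrementally) and `links` (the capped,
#'   user-facing tibble with `cross_document` flags).
#' @export
build_links <- function(corpus, config = link_config()) {
  stopifnot(inherits(config, "link_config"))
  if (!length(corpus)) stop("empty corpus")
  tab <- .link_sentence_table(corpus, config)
  candidates <- .score_new_pairs(tab, from = 2L, config = config)
  candidates <- dplyr::arrange(candidates, doc_a, sent_a, doc_b, sent_b)
  structure(
    list(corpus_id = attr(corpus, "corpus_id") %||% "corpus",
         config = config,
         sentences = tab[, c("doc_id", "sent_id")],
         candidates = candidates,
         links = .apply_top_k(candidates, config$top_k)),
    class = "link_graph"
  )
}

#' @export
print.link_graph <- function(x, ...) {
  cat(sprintf(
    "<link_graph> %s: %d sentences, %d links (threshold %.2f, top_k %d)\n",
    x$corpus_id, nrow(x$sentences), nrow(x$links),
    x$config$threshold, x$config$top_k))
  invisible(x)
}

#' Add one document to an existing link graph
#'
#' Scores only the new pairs (new-vs-existing and, when `include_intra`,
#' within the new document) and re-applies the top_k cap, so the result is
#' identical to rebuilding the graph from scratch on the enlarged corpus.
#'
#' @param graph a `link_graph` built on `corpus`.
#' @param corpus the preprocessed corpus the graph was built on.
#' @param new_document a preprocessed `lit_document` whose id is not yet
#'   in the corpus.
#' @param config the graph's `link_config` (defaults to it).
#' @return the updated `link_graph`.
#' @export
add_document <- function(graph, corpus, new_document, config = graph$config) {
  if (new_document$doc_id %in% names(corpus)) {
    stop("duplicate doc_id: ", new_document$doc_id)
  }
  enlarged <- as_corpus(c(unclass(corpus), list(new_document)),
                        corpus_id = attr(corpus, "corpus_id"))
  tab <- .link_sentence_table(enlarged, config)
  n_old <- nrow(graph$sentences)
  new_cand <- .score_new_pairs(tab, from = n_old + 1L, config = config)
  candidates <- dplyr::bind_rows(graph$candidates, new_cand)
  candidates <- dplyr::arrange(candidates, doc_a, sent_a, doc_b, sent_b)
  graph$sentences <- tab[, c("doc_id", "sent_id")]
  graph$candidates <- candidates
  graph$links <- .apply_top_k(candidates, config$top_k)
  graph$config <- config
  graph
}

#' Ranked neighbors of a sentence in the link graph
#'
#' @param graph a `link_graph`.
#' @param doc_id,sent_id the query sentence (must exist in the graph).
#' @return an object of class `sentence_neighbors`: list with two tibbles,
#'   `same_document` and `cross_document` (columns `doc_id`, `sent_id`,
#'   `score`), each sorted by descending score with ties in canonical
#'   order.
#' @export
neighbors <- function(graph, doc_id, sent_id) {
  known <- graph$sentences$doc_id == doc_id & graph$sentences$sent_id == sent_id
  if (!any(known)) {
    stop("unknown sentence: ", doc_id, " / ", sent_id)
  }
  ln <- graph$links
  at_a <- ln$doc_a == doc_id & ln$sent_a == sent_id
  at_b <- ln$doc_b == doc_id & ln$sent_b == sent_id
  other <- tibble::tibble(
    doc_id = c(ln$doc_b[at_a], ln$doc_a[at_b]),
    sent_id = c(ln$sent_b[at_a], ln$sent_a[at_b]),
    score = c(ln$score[at_a], ln$score[at_b])
  )
  other <- other[order(-other$score, other$doc_id, other$sent_id), ,
                 drop = FALSE]
  same <- other$doc_id == doc_id
  structure(
    list(same_document = other[same, , drop = FALSE],
         cross_document = other[!same, , drop = FALSE]),
    class = "sentence_neighbors"
  )
}

#' @export
print.sentence_neighbors <- function(x, ...) {
  cat(sprintf("<sentence_neighbors> %d same-document, %d cross-document\n",
              nrow(x$same_document), nrow(x$cross_document)))
  invisible(x)
}

#' Serialize a link graph to versioned JSON
#' @param graph a `link_graph`.
#' @param path output file.
#' @export
write_link_graph <- function(graph, path) {
  cfg <- graph$config
  obj <- list(
    format = "litcurate-link-graph", version = "1",
    corpus_id = graph$corpus_id,
    config = list(threshold = cfg$threshold, top_k = cfg$top_k,
                  include_intra = cfg$include_intra,
                  weights = as.list(cfg$sim$weights),
                  stemming = cfg$sim$stemming,
                  lowercase = cfg$sim$lowercase,
                  stopwords = cfg$sim$stopwords),
    sentences = graph$sentences,
    candidates = graph$candidates,
    links = graph$links
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Load a link graph from JSON
#'
#' Restores the graph structure and a configuration snapshot. Similarity
#' resources (taxonomy, word vectors) are not serialized; supply `sim` to
#' re-attach a scoring configuration if the graph is to be updated with
#' [add_document()] under taxonomy or embedding metrics.
#'
#' @param path file written by [write_link_graph()].
#' @param sim optional `sim_config` replacing the snapshot.
#' @return a `link_graph`.
#' @export
read_link_graph <- function(path, sim = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "litcurate-link-graph")) {
    stop("not a link graph file: ", path)
  }
  as_links <- function(df) {
    if (is.null(df) || !length(df) || !length(df$doc_a %||% character(0))) {
      return(.empty_links())
    }
    tibble::tibble(doc_a = df$doc_a, sent_a = df$sent_a,
                   doc_b = df$doc_b, sent_b = df$sent_b,
                   score = as.numeric(df$score),
                   cross_document = as.logical(df$cross_document))
  }
  if (is.null(sim)) {
    sim <- sim_config(
      weights = unlist(obj$config$weights),
      stemming = obj$config$stemming, lowercase = obj$config$lowercase,
      stopwords = unlist(obj$config$stopwords) %||% character(0)
    )
  }
  structure(
    list(corpus_id = obj$corpus_id,
         config = link_config(threshold = obj$config$threshold,
                              top_k = obj$config$top_k,
                              include_intra = obj$config$include_intra,
                              sim = sim),
         sentences = tibble::tibble(doc_id = obj$sentences$doc_id,
                                    sent_id = obj$sentences$sent_id),
         candidates = as_links(obj$candidates),
         links = as_links(obj$links)),
    class = "link_graph"
  )
}
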
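# Distant-supervision disambiguation. Many surfaces map to several
# database identifiers (a gene and its protein product, paralogues, ...).
# Rather than requiring a hand-annotated corpus, training labels come from
# the reference database itself: when the database links article B to
# entity A, a mention in B whose candidates contain A (and no other linked
# entity) is taken as a correct occurrence of A. A multinomial naive Bayes
# classifier with Laplace smoothing is fit over bag-of-context features;
# at prediction time the posterior is restricted to a mention's candidate
# identifiers.

#' Read document-to-entity reference links from TSV
#' @param path TSV with columns `doc_id` and `entity_id`.
#' @return a tibble of unique (doc_id, entity_id) pairs.
#' @export
read_reference_links <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character")
  stopifnot(all(c("doc_id", "entity_id") %in% names(tab)))
  reference_links(tab)
}

#' Validate reference links
#' @param links data frame with columns `doc_id`, `entity_id`.
#' @return tibble of unique pairs.
#' @export
reference_links <- function(links) {
  links <- tibble::as_tibble(links)[, c("doc_id", "entity_id")]
  dplyr::distinct(links)
}

#' Write reference links to TSV
#' @param links links tibble.
#' @param path output file.
#' @export
write_reference_links <- function(links, path) {
  utils::write.table(reference_links(links), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# split a possibly ";"-joined type label
.split_types <- function(x) unlist(strsplit(x, ";", fixed = TRUE))

#' Extract context features for a mention
#'
#' The feature bag (a multiset, returned as a character vector with
#' repeats) contains: `w:<stem>` for every word token within `window`
#' token positions on either side of the mention (mention tokens excluded,
#' punctuation skipped); `st:<TYPE>` for the entity type(s) of every other
#' mention in the same sentence; and `dt:<TYPE>` for each entity type
#' present in the rest of the document. Features carry no document
#' identifier, so renaming documents cannot leak into the model.
#'
#' @param mention one row of a mentions tibble.
#' @param sentence the sentence record containing the mention.
#' @param doc_mentions all mentions of the same document (may include
#'   `mention` itself).
#' @param window half-width of the token context window (default 5).
#' @return character vector of features (possibly empty).
#' @export
extract_features <- function(mention, sentence, doc_mentions, window = 5L) {
  toks <- sentence$tokens
  n <- nrow(toks)
  span <- seq(mention$start_tok, mention$end_tok - 1L)
  ctx <- setdiff(seq(max(1L, mention$start_tok - window),
                     min(n, mention$end_tok - 1L + window)), span)
  feats <- character(0)
  if (length(ctx)) {
    word <- grepl("[A-Za-z0-9]", toks$surface[ctx])
    feats <- c(feats, paste0("w:", toks$stem[ctx][word]))
  }
  same <- doc_mentions$sent_id == mention$sent_id &
    !(doc_mentions$start_tok == mention$start_tok &
        doc_mentions$end_tok == mention$end_tok)
  if (any(same)) {
    feats <- c(feats, paste0("st:", .split_types(doc_mentions$entity_type[same])))
  }
  elsewhere <- doc_mentions$sent_id != mention$sent_id
  if (any(elsewhere)) {
    types <- sort(unique(.split_types(doc_mentions$entity_type[elsewhere])))
    feats <- c(feats, paste0("dt:", types))
  }
  feats
}

# per-document feature bags for every mention; returns a list aligned with
# the mention rows
.mention_features <- function(corpus, mentions, window) {
  out <- vector("list", nrow(mentions))
  if (!nrow(mentions)) return(out)
  for (doc_id in unique(mentions$doc_id)) {
    rows <- which(mentions$doc_id == doc_id)
    doc <- corpus[[doc_id]]
    doc_mentions <- mentions[rows, ]
    sent_lookup <- stats::setNames(doc$sentences,
                                   vapply(doc$sentences, `[[`, "", "sent_id"))
    for (k in seq_along(rows)) {
      m <- doc_mentions[k, ]
      out[[rows[k]]] <- extract_features(m, sent_lookup[[m$sent_id]],
                                         doc_mentions, window = window)
    }
  }
  out
}

#' Train a disambiguation model by distant supervision
#'
#' Annotates the corpus with `matcher`, then labels mentions using the
#' reference links: a mention becomes a training instance when the
#' intersection of its candidate identifiers with the linked entity set of
#' its document contains exactly one identifier (zero means no evidence;
#' two or more would make the distant label itself ambiguous, so such
#' mentions are skipped). A multinomial naive Bayes model with Laplace
#' smoothing `alpha` is fit over the instances' feature bags. The result
#' is deterministic given (corpus, links, alpha, window).
#'
#' @param corpus a preprocessed `lit_corpus`.
#' @param links reference links tibble (`doc_id`, `entity_id`); every
#'   `doc_id` must exist in the corpus.
#' @param matcher a compiled `term_matcher`.
#' @param alpha Laplace smoothing constant (> 0).
#' @param window context window half-width for [extract_features()].
#' @return an object of class `disambig_model`.
#' @export
train_distant <- function(corpus, links, matcher, alpha = 1, window = 5L) {
  stopifnot(alpha > 0)
  links <- reference_links(links)
  missing <- setdiff(unique(links$doc_id), names(corpus))
  if (length(missing)) {
    stop("links reference absent doc_id(s): ", paste(missing, collapse = ", "))
  }
  mentions <- annotate_corpus(corpus, matcher)
  linked <- split(links$entity_id, links$doc_id)
  labels <- rep(NA_character_, nrow(mentions))
  for (i in seq_len(nrow(mentions))) {
    ids <- intersect(mentions$candidate_ids[[i]],
                     linked[[mentions$doc_id[i]]] %||% character(0))
    if (length(ids) == 1L) labels[i] <- ids
  }
  keep <- !is.na(labels)
  if (!any(keep)) stop("zero training instances: no mention matched the links")
  feats <- .mention_features(corpus, mentions[keep, ], window = window)
  labels <- labels[keep]

  vocab <- sort(unique(unlist(feats)))
  classes <- sort(unique(labels))
  counts <- matrix(0, nrow = length(classes), ncol = length(vocab),
                   dimnames = list(classes, vocab))
  n_inst <- stats::setNames(integer(length(classes)), classes)
  for (i in seq_along(labels)) {
    cl <- labels[i]
    n_inst[cl] <- n_inst[cl] + 1L
    if (length(feats[[i]])) {
      tab <- table(feats[[i]])
      counts[cl, names(tab)] <- counts[cl, names(tab)] + as.integer(tab)
    }
  }
  structure(
    list(version = "1", alpha = alpha, window = window,
         classes = classes, n_instances = n_inst,
         feature_counts = counts, vocab = vocab),
    class = "disambig_model"
  )
}

#' @export
print.disambig_model <- function(x, ...) {
  cat(sprintf(
    "<disambig_model> %d classes, %d features, %d training instances (alpha=%g)\n",
    length(x$classes), length(x$vocab), sum(x$n_instances), x$alpha))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# log P(class) + sum_f n_f log P(f | class), features outside the
# vocabulary ignored (standard multinomial NB)
.nb_log_scores <- function(model, features, classes) {
  feats <- features[features %in% model$vocab]
  tab <- if (length(feats)) table(feats) else NULL
  V <- length(model$vocab)
  totals <- rowSums(model$feature_counts)
  vapply(classes, function(cl) {
    lp <- log(model$n_instances[[cl]]) - log(sum(model$n_instances))
    if (!is.null(tab)) {
      cnt <- model$feature_counts[cl, names(tab)]
      lp <- lp + sum(as.integer(tab) *
                       (log(cnt + model$alpha) -
                          log(totals[[cl]] + model$alpha * V)))
    }
    lp
  }, numeric(1))
}

#' Disambiguate a mention
#'
#' Returns the candidate identifier with the highest naive Bayes posterior,
#' together with the posterior normalized over the candidate set. Mentions
#' with a single candidate bypass the model (score 1). When none of the
#' candidates was seen in training the result is the lexicographically
#' smallest candidate at uniform score, flagged `low_confidence`. Exact
#' posterior ties are broken towards the lexicographically smaller
#' identifier, so the operation is deterministic.
#'
#' @param features feature bag of the mention, see [extract_features()].
#' @param candidate_ids the mention's candidate identifiers (length >= 1).
#' @param model a `disambig_model`.
#' @return a list with `entity_id`, `score` (posterior of the winner, in
#'   \[0, 1\]), `posterior` (named vector over candidates, sums to 1) and
#'   `low_confidence`.
#' @export
disambiguate <- function(features, candidate_ids, model) {
  cand <- sort(unique(candidate_ids))
  if (length(cand) == 1L) {
    return(list(entity_id = cand, score = 1,
                posterior = stats::setNames(1, cand), low_confidence = FALSE))
  }
  seen <- cand[cand %in% model$classes]
  if (!length(seen)) {
    post <- stats::setNames(rep(1 / length(cand), length(cand)), cand)
    return(list(entity_id = cand[1L], score = unname(post[1L]),
                posterior = post, low_confidence = TRUE))
  }
  lp <- .nb_log_scores(model, features, seen)
  w <- exp(lp - max(lp))
  post <- stats::setNames(rep(0, length(cand)), cand)
  post[seen] <- w / sum(w)
  best <- names(post)[which(post >= max(post) - 1e-12)][1L] # names sorted
  list(entity_id = best, score = unname(post[best]),
       posterior = post, low_confidence = FALSE)
}

#' Resolve every ambiguous mention of a corpus
#'
#' Fills `resolved_id` (and a `resolution_score` column) for mentions with
#' two or more candidates using [disambiguate()]; single-candidate
#' mentions keep their immediate resolution with score 1.
#'
#' @param corpus a preprocessed `lit_corpus`.
#' @param mentions mentions tibble from [annotate_corpus()].
#' @param model a `disambig_model`.
#' @return the mentions tibble with `resolved_id`, `resolution_score` and
#'   `low_confidence` filled.
#' @export
resolve_mentions <- function(corpus, mentions, model) {
  feats <- .mention_features(corpus, mentions, window = model$window)
  score <- numeric(nrow(mentions))
  lowc <- logical(nrow(mentions))
  resolved <- mentions$resolved_id
  for (i in seq_len(nrow(mentions))) {
    res <- disambiguate(feats[[i]], mentions$candidate_ids[[i]], model)
    resolved[i] <- res$entity_id
    score[i] <- res$score
    lowc[i] <- res$low_confidence
  }
  mentions$resolved_id <- resolved
  mentions$resolution_score <- score
  mentions$low_confidence <- lowc
  mentions
}

#' Serialize a disambiguation model to versioned JSON
#'
#' The representation is fully deterministic (sorted classes, sorted
#' vocabulary, counts in row-major order), so identical training inputs
#' produce byte-identical files.
#'
#' @param model a `disambig_model`.
#' @param path output file.
#' @export
write_model <- function(model, path) {
  obj <- list(
    format = "litcurate-disambig-model",
    version = model$version,
    alpha = model$alpha,
    window = model$window,
    classes = model$classes,
    n_instances = as.integer(model$n_instances),
    vocab = model$vocab,
    feature_counts = as.integer(t(model$feature_counts))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Load a disambiguation model from JSON
#' @param path file written by [write_model()].
#' @return a `disambig_model` with identical predictions to the original.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "litcurate-disambig-model")) {
    stop("not a disambiguation model file: ", path)
  }
  counts <- matrix(obj$feature_counts, nrow = length(obj$classes),
                   byrow = TRUE, dimnames = list(obj$classes, obj$vocab))
  structure(
    list(version = obj$version, alpha = obj$alpha, window = obj$window,
         classes = obj$classes,
         n_instances = stats::setNames(obj$n_instances, obj$classes),
         feature_counts = counts, vocab = obj$vocab),
    class = "disambig_model"
  )
}
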
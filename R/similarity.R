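# Sentence similarity engine. A sentence is represented by the frequency
# of each (normalized) word it contains — a sparse bag-of-words vector —
# and the basic metric is the cosine between two such vectors. On top of
# that, two word-level semantic metrics (taxonomy information content and
# dense embeddings) are lifted to sentences by greedy best-match word
# alignment. Enabled metrics are combined as a weighted arithmetic mean in
# [0, 1] and scaled to the 0-5 semantic textual similarity scale, where 5
# means the two sentences convey the same meaning and 0 means they are
# unrelated. A Pearson harness evaluates the engine against gold-scored
# sentence pairs.

#' Similarity configuration
#'
#' @param weights named non-negative weights for the metrics `vsm`
#'   (bag-of-words cosine), `taxonomy` (Lin word similarity, aligned) and
#'   `embedding` (word-vector cosine, aligned). A metric with weight 0 is
#'   disabled; at least one weight must be positive. Default: VSM only.
#' @param stemming collapse inflectional variants before counting
#'   (default `TRUE`).
#' @param lowercase lower-case tokens before counting (default `TRUE`).
#' @param stopwords character vector of words to drop (compared after
#'   lower-casing; default none — see [default_stopwords()]).
#' @param taxonomy a `lit_taxonomy`, required when `weights["taxonomy"] > 0`.
#' @param vectors a `word_vectors`, required when `weights["embedding"] > 0`.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(weights = c(vsm = 1, taxonomy = 0, embedding = 0),
                       stemming = TRUE, lowercase = TRUE,
                       stopwords = character(0),
                       taxonomy = NULL, vectors = NULL) {
  full <- c(vsm = 0, taxonomy = 0, embedding = 0)
  stopifnot(is.numeric(weights), !is.null(names(weights)),
            all(names(weights) %in% names(full)))
  full[names(weights)] <- weights
  if (any(full < 0)) stop("metric weights must be non-negative")
  if (sum(full) == 0) stop("all metric weights are zero")
  if (full[["taxonomy"]] > 0 && is.null(taxonomy)) {
    stop("taxonomy metric enabled but no taxonomy supplied")
  }
  if (full[["embedding"]] > 0 && is.null(vectors)) {
    stop("embedding metric enabled but no word vectors supplied")
  }
  structure(
    list(weights = full, stemming = isTRUE(stemming),
         lowercase = isTRUE(lowercase),
         stopwords = tolower(stopwords),
         taxonomy = taxonomy, vectors = vectors),
    class = "sim_config"
  )
}

# normalized content words of a sentence (tokens that are purely
# alphabetic, possibly hyphenated), in token order, duplicates kept
.content_words <- function(sentence, config) {
  toks <- if (is.character(sentence)) tokenize(sentence)
          else sentence$tokens
  if (is.null(toks) || !nrow(toks)) return(character(0))
  keep <- grepl("^[A-Za-z]+(?:-[A-Za-z]+)*$", toks$surface, perl = TRUE)
  words <- toks$surface[keep]
  if (!length(words)) return(character(0))
  words <- words[!(tolower(words) %in% config$stopwords)]
  if (!length(words)) return(character(0))
  if (config$lowercase) words <- tolower(words)
  if (config$stemming) words <- stem(words)
  words
}

#' Build a sentence's bag-of-words vector
#'
#' Counts each normalized content word of the sentence: punctuation and
#' non-alphabetic tokens are dropped, stop words (if configured) removed,
#' and the rest lower-cased and stemmed per the configuration. Each
#' distinct normalized word is one dimension of the vector.
#'
#' @param sentence a preprocessed sentence record, or a plain string
#'   (tokenized on the fly).
#' @param config a `sim_config`.
#' @return a named integer vector of counts (possibly empty), names sorted.
#' @export
vectorize <- function(sentence, config = sim_config()) {
  words <- .content_words(sentence, config)
  if (!length(words)) {
    return(stats::setNames(integer(0), character(0)))
  }
  tab <- table(words)
  stats::setNames(as.integer(tab), names(tab))
}

#' Cosine between two sparse count vectors
#'
#' `dot(v1, v2) / (|v1| * |v2|)`, with the convention that an empty vector
#' has similarity 0 to anything. Symmetric, in \[0, 1\] for count vectors.
#'
#' @param v1,v2 named numeric vectors as from [vectorize()].
#' @return cosine similarity.
#' @export
cosine <- function(v1, v2) {
  if (!length(v1) || !length(v2)) return(0)
  common <- intersect(names(v1), names(v2))
  if (!length(common)) return(0)
  num <- sum(as.numeric(v1[common]) * as.numeric(v2[common]))
  num / sqrt(sum(as.numeric(v1)^2) * sum(as.numeric(v2)^2))
}

#' Align words across two sentences and average their similarities
#'
#' Lifts a word-level similarity to sentences: every content word of one
#' sentence is paired with its best-matching word in the other sentence,
#' the matches are averaged, and the two directions are averaged to keep
#' the score symmetric. Identical normalized words always count as a
#' perfect match, independent of resource coverage. Returns 0 when either
#' sentence has no content words.
#'
#' @param words1,words2 character vectors of normalized content words
#'   (see [vectorize()] for the normalization), or sentence records /
#'   strings together with `config`.
#' @param word_sim_fn symmetric function `(w1, w2) -> similarity in [0,1]`.
#' @param config used to normalize `words1`/`words2` when they are not
#'   already character vectors.
#' @return similarity in \[0, 1\].
#' @export
aligned_word_score <- function(words1, words2, word_sim_fn,
                               config = sim_config()) {
  if (!is.character(words1)) words1 <- .content_words(words1, config)
  if (!is.character(words2)) words2 <- .content_words(words2, config)
  if (!length(words1) || !length(words2)) return(0)
  pair_sim <- function(a, b) {
    if (a == b) return(1)
    min(1, max(0, as.numeric(word_sim_fn(a, b))))
  }
  direction <- function(from, to) {
    mean(vapply(from, function(w) {
      max(vapply(to, function(v) pair_sim(w, v), numeric(1)))
    }, numeric(1)))
  }
  (direction(words1, words2) + direction(words2, words1)) / 2
}

#' Score a sentence pair with the combined similarity
#'
#' Computes every enabled metric in \[0, 1\], combines them as the
#' weighted arithmetic mean, and scales the result by 5 to the semantic
#' textual similarity scale. Identical sentences score 5 under any
#' weighting.
#'
#' @param sent1,sent2 preprocessed sentence records or plain strings.
#' @param config a `sim_config`.
#' @return an object of class `sentence_pair_score`: list with `metrics`
#'   (named raw scores), `weights`, `combined` (weighted mean in \[0, 1\])
#'   and `scaled` (in \[0, 5\]).
#' @export
combined_similarity <- function(sent1, sent2, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  w <- config$weights
  enabled <- names(w)[w > 0]
  words1 <- .content_words(sent1, config)
  words2 <- .content_words(sent2, config)
  metrics <- stats::setNames(numeric(length(enabled)), enabled)
  for (m in enabled) {
    metrics[[m]] <- switch(m,
      vsm = {
        count <- function(ws) {
          if (!length(ws)) return(integer(0))
          tab <- table(ws)
          stats::setNames(as.integer(tab), names(tab))
        }
        cosine(count(words1), count(words2))
      },
      taxonomy = aligned_word_score(
        words1, words2,
        function(a, b) lin_similarity(config$taxonomy, a, b)
      ),
      embedding = aligned_word_score(
        words1, words2,
        function(a, b) embedding_word_sim(config$vectors, a, b)
      )
    )
  }
  combined <- sum(w[enabled] * metrics) / sum(w[enabled])
  structure(
    list(metrics = metrics, weights = w[enabled],
         combined = combined, scaled = 5 * combined),
    class = "sentence_pair_score"
  )
}

#' @export
print.sentence_pair_score <- function(x, ...) {
  cat(sprintf("<sentence_pair_score> scaled %.3f / 5 (%s)\n", x$scaled,
              paste(sprintf("%s=%.3f", names(x$metrics), x$metrics),
                    collapse = ", ")))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' @param xs,ys numeric vectors of equal length >= 2 with non-zero
#'   variance.
#' @return correlation in \[-1, 1\].
#' @export
pearson <- function(xs, ys) {
  stopifnot(is.numeric(xs), is.numeric(ys))
  if (length(xs) != length(ys)) stop("pearson: unequal lengths")
  if (length(xs) < 2L) stop("pearson: need at least 2 observations")
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    stop("pearson: zero variance input")
  }
  stats::cor(xs, ys)
}

#' Read gold sentence pairs from TSV
#' @param path TSV with columns `text1`, `text2`, `score` (0-5).
#' @return tibble with columns `text1`, `text2`, `gold`.
#' @export
read_gold_pairs <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character")
  stopifnot(all(c("text1", "text2", "score") %in% names(tab)))
  out <- tibble::tibble(text1 = tab$text1, text2 = tab$text2,
                        gold = as.numeric(tab$score))
  if (any(out$gold < 0 | out$gold > 5)) stop("gold scores must lie in [0, 5]")
  out
}

#' Write gold sentence pairs to TSV
#' @param pairs tibble with columns `text1`, `text2`, `gold`.
#' @param path output file.
#' @export
write_gold_pairs <- function(pairs, path) {
  tab <- data.frame(text1 = pairs$text1, text2 = pairs$text2,
                    score = pairs$gold, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Evaluate the engine against gold-scored sentence pairs
#'
#' Scores every pair with [combined_similarity()] (scaled to 0-5) and
#' reports the Pearson correlation between system and gold scores.
#'
#' @param gold_pairs tibble with columns `text1`, `text2`, `gold` (>= 2
#'   rows), e.g. from [read_gold_pairs()] or [gen_gold_pairs()].
#' @param config a `sim_config`.
#' @param out_tsv optional path; when given, the per-pair scores are
#'   written as TSV.
#' @return an object of class `sts_report`: list with `pearson_r`, `n`,
#'   and `scores` (tibble `text1`, `text2`, `gold`, `system`).
#' @export
evaluate_sts <- function(gold_pairs, config = sim_config(), out_tsv = NULL) {
  stopifnot(nrow(gold_pairs) >= 2L)
  system <- vapply(seq_len(nrow(gold_pairs)), function(i) {
    combined_similarity(gold_pairs$text1[i], gold_pairs$text2[i],
                        config)$scaled
  }, numeric(1))
  r <- pearson(system, gold_pairs$gold)
  scores <- tibble::tibble(text1 = gold_pairs$text1,
                           text2 = gold_pairs$text2,
                           gold = gold_pairs$gold, system = system)
  if (!is.null(out_tsv)) {
    utils::write.table(scores, out_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  structure(list(pearson_r = r, n = nrow(gold_pairs), scores = scores),
            class = "sts_report")
}

#' @export
print.sts_report <- function(x, ...) {
  cat(sprintf("<sts_report> n = %d pairs, Pearson r = %.4f\n",
              x$n, x$pearson_r))
  invisible(x)
}
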
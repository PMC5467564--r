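# Concept taxonomy with information content. Concepts form a single-rooted
# is-a DAG with per-concept frequency counts; p(c) is the cumulative
# frequency of c and all its descendants over the root total, and
# IC(c) = -log p(c), so IC(root) = 0 and IC grows towards the leaves. Word
# similarity follows the Lin measure: 2 * IC(lcs) / (IC(c1) + IC(c2)),
# with the lowest common subsumer taken as the shared ancestor of maximal
# IC, and ambiguity (a word mapping to several concepts) handled by
# maximizing over sense pairs.

#' Build a taxonomy
#'
#' @param concepts data frame with columns `concept`, `parent` (empty/NA
#'   for the root; several rows per concept allowed for DAG nodes with
#'   multiple parents), `freq` (non-negative usage count of the concept
#'   itself).
#' @param word_map data frame with columns `word`, `concept` mapping words
#'   to the concept(s) expressing their senses.
#' @return an object of class `lit_taxonomy` with derived information
#'   content per concept.
#' @export
taxonomy <- function(concepts, word_map) {
  concepts <- tibble::as_tibble(concepts)
  word_map <- tibble::as_tibble(word_map)
  stopifnot(all(c("concept", "parent", "freq") %in% names(concepts)),
            all(c("word", "concept") %in% names(word_map)))
  concepts$parent[is.na(concepts$parent)] <- ""
  ids <- unique(concepts$concept)
  freq <- vapply(ids, function(id) {
    sum(as.numeric(concepts$freq[concepts$concept == id][1]))
  }, numeric(1))
  names(freq) <- ids
  if (any(freq < 0)) stop("negative concept frequency")

  parents <- lapply(ids, function(id) {
    p <- unique(concepts$parent[concepts$concept == id])
    p <- p[nzchar(p)]
    missing <- setdiff(p, ids)
    if (length(missing)) {
      stop("unknown parent concept(s): ", paste(missing, collapse = ", "))
    }
    p
  })
  names(parents) <- ids
  roots <- ids[vapply(parents, length, integer(1)) == 0L]
  if (length(roots) != 1L) {
    stop("taxonomy must have exactly one root, found: ",
         paste(roots, collapse = ", "))
  }

  # ancestor closure (including self); also rejects cycles
  anc <- stats::setNames(vector("list", length(ids)), ids)
  visit <- function(id, seen = character(0)) {
    if (!is.null(anc[[id]])) return(anc[[id]])
    if (id %in% seen) stop("cycle in taxonomy at concept ", id)
    a <- id
    for (p in parents[[id]]) a <- union(a, visit(p, c(seen, id)))
    anc[[id]] <<- a
    a
  }
  for (id in ids) visit(id)

  # cumulative frequency: own count plus every distinct descendant's
  cum <- vapply(ids, function(id) {
    inside <- vapply(ids, function(x) id %in% anc[[x]], logical(1))
    sum(freq[inside])
  }, numeric(1))
  total <- cum[[roots]]
  if (total <= 0) stop("taxonomy has zero total frequency")
  p <- cum / total
  ic <- ifelse(p > 0, -log(p), Inf)

  structure(
    list(concepts = ids, parents = parents, ancestors = anc,
         freq = freq, cum_freq = cum, p = p, ic = ic,
         root = roots, word_map = word_map),
    class = "lit_taxonomy"
  )
}

#' @export
print.lit_taxonomy <- function(x, ...) {
  cat(sprintf("<lit_taxonomy> %d concepts, %d mapped words, root '%s'\n",
              length(x$concepts), length(unique(x$word_map$word)), x$root))
  invisible(x)
}

#' Information content of a concept
#' @param tax a `lit_taxonomy`.
#' @param concept concept id.
#' @return `-log p(concept)`; 0 for the root.
#' @export
information_content <- function(tax, concept) {
  if (!concept %in% tax$concepts) stop("unknown concept: ", concept)
  unname(tax$ic[[concept]])
}

#' Lin similarity between two words
#'
#' `2 * IC(lcs) / (IC(c1) + IC(c2))`, maximized over the concept pairs of
#' ambiguous words; the lowest common subsumer is the shared ancestor with
#' maximal IC. A word identical to itself on a non-root concept scores 1;
#' word pairs whose only shared ancestor is the root score 0. A word
#' absent from the taxonomy yields 0 with attribute `oov = TRUE`.
#'
#' @param tax a `lit_taxonomy`.
#' @param w1,w2 words.
#' @return similarity in \[0, 1\], with an `oov` attribute flagging
#'   out-of-vocabulary input.
#' @export
lin_similarity <- function(tax, w1, w2) {
  c1 <- tax$word_map$concept[tax$word_map$word == w1]
  c2 <- tax$word_map$concept[tax$word_map$word == w2]
  if (!length(c1) || !length(c2)) {
    return(structure(0, oov = TRUE))
  }
  best <- 0
  for (a in c1) {
    for (b in c2) {
      common <- intersect(tax$ancestors[[a]], tax$ancestors[[b]])
      if (!length(common)) next
      ic_lcs <- max(tax$ic[common][is.finite(tax$ic[common])], 0)
      denom <- tax$ic[[a]] + tax$ic[[b]]
      s <- if (denom > 0 && is.finite(denom)) 2 * ic_lcs / denom
           else if (ic_lcs > 0) 1 else 0
      best <- max(best, min(1, s))
    }
  }
  structure(best, oov = FALSE)
}

#' Read a taxonomy from TSV files
#'
#' @param concepts_path TSV with columns `concept`, `parent`, `freq`
#'   (root row has an empty parent).
#' @param word_map_path TSV with columns `word`, `concept`.
#' @return a `lit_taxonomy`.
#' @export
read_taxonomy <- function(concepts_path, word_map_path) {
  con <- utils::read.delim(concepts_path, header = TRUE, sep = "\t",
                           quote = "", colClasses = "character")
  con$freq <- as.numeric(con$freq)
  wm <- utils::read.delim(word_map_path, header = TRUE, sep = "\t",
                          quote = "", colClasses = "character")
  taxonomy(con, wm)
}

#' Write a taxonomy to TSV files
#' @param tax a `lit_taxonomy`.
#' @inheritParams read_taxonomy
#' @export
write_taxonomy <- function(tax, concepts_path, word_map_path) {
  rows <- list()
  for (id in tax$concepts) {
    ps <- tax$parents[[id]]
    if (!length(ps)) ps <- ""
    for (p in ps) {
      rows[[length(rows) + 1L]] <- data.frame(
        concept = id, parent = p, freq = tax$freq[[id]],
        stringsAsFactors = FALSE)
    }
  }
  utils::write.table(do.call(rbind, rows), concepts_path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(tax$word_map, word_map_path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(concepts_path)
}
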
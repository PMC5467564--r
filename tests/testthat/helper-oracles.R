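# Shared generators and independent oracles used across the suite.

extdata <- function(name) {
  system.file("extdata", name, package = "litcurate", mustWork = TRUE)
}

# --- dependency trees ------------------------------------------------------

# random tree over n tokens: node 1 is the root, every later node attaches
# to an earlier one, then labels are permuted so the root can sit anywhere
random_tree <- function(n, sent_id = "t:s0") {
  stopifnot(n >= 1)
  parent <- c(0L, if (n > 1) vapply(2:n, function(i) {
    sample.int(i - 1L, 1L)
  }, integer(1)))
  perm <- sample.int(n)
  head <- integer(n)
  for (i in seq_len(n)) {
    head[perm[i]] <- if (parent[i] == 0L) 0L else perm[parent[i]]
  }
  dep_tree(sent_id,
           form = paste0("w", seq_len(n)),
           upos = rep("NOUN", n),
           head = head,
           deprel = rep("dep", n))
}

# brute-force LCA: intersect the explicit root paths and take the node
# with the longest own root path (the deepest)
oracle_lca <- function(tree, a, b) {
  pa <- root_path(tree, a)
  pb <- root_path(tree, b)
  common <- intersect(pa, pb)
  depths <- vapply(common, function(i) length(root_path(tree, i)), integer(1))
  common[which.max(depths)]
}

# --- filters ---------------------------------------------------------------

# random filter expression string over a small atom pool
random_filter_string <- function(depth = 3L) {
  atoms <- c("type:TF", "type:GENE", "type:TU", "lexicon:lexa",
             "lexicon:lexb", 'term:"alpha"', 'term:"beta"')
  build <- function(d) {
    if (d <= 0L || runif(1) < 0.35) return(sample(atoms, 1L))
    op <- sample(c("AND", "OR", "NOT"), 1L)
    if (op == "NOT") paste0("NOT (", build(d - 1L), ")")
    else paste0("(", build(d - 1L), ") ", op, " (", build(d - 1L), ")")
  }
  build(depth)
}

# independent filter evaluation: resolve every atom to TRUE/FALSE, then let
# R's own boolean interpreter evaluate the expression
oracle_eval_filter <- function(expr_string, sentence, mentions, lexicons) {
  subst <- expr_string
  atom_value <- function(atom) {
    val <- litcurate::eval_filter(litcurate::parse_filter(atom),
                                  sentence, mentions, lexicons)
    if (val) "TRUE" else "FALSE"
  }
  for (atom in c("type:TF", "type:GENE", "type:TU")) {
    subst <- gsub(atom, atom_value(atom), subst, fixed = TRUE)
  }
  for (atom in c("lexicon:lexa", "lexicon:lexb")) {
    subst <- gsub(atom, atom_value(atom), subst, fixed = TRUE)
  }
  for (atom in c('term:"alpha"', 'term:"beta"')) {
    subst <- gsub(atom, atom_value(atom), subst, fixed = TRUE)
  }
  subst <- gsub("NOT", "!", subst, fixed = TRUE)
  subst <- gsub("AND", "&&", subst, fixed = TRUE)
  subst <- gsub("OR", "||", subst, fixed = TRUE)
  eval(parse(text = subst))
}

# a tiny annotated sentence with controllable content
toy_sentence <- function(text, doc_id = "d1", index = 0L) {
  doc <- preprocess_document(lit_document(doc_id, text))
  doc$sentences[[index + 1L]]
}

# random annotated sentence + mentions for filter fuzzing
random_annotated_sentence <- function() {
  words <- c(sample(c("alpha", "beta", "gamma", "delta", "binds", "acts"),
                    4L, replace = TRUE))
  s <- toy_sentence(paste(words, collapse = " "))
  types <- sample(c("TF", "GENE", "TU"), sample.int(3L, 1L))
  present <- sample(c(TRUE, FALSE), length(types), replace = TRUE)
  types <- types[present]
  mentions <- if (length(types)) {
    tibble::tibble(
      doc_id = "d1", sent_id = s$sent_id,
      start_tok = 1L, end_tok = 2L, char_start = 0L, char_end = 1L,
      matched_surface = "x", entity_type = types,
      candidate_ids = replicate(length(types), "E1", simplify = FALSE),
      resolved_id = "E1"
    )
  } else {
    annotate(preprocess_document(lit_document("d0", "nothing here")),
             compile_dictionary(tibble::tibble(
               term = "zz", entity_id = "Z", entity_type = "Z", source = "s")))
  }
  list(sentence = s, mentions = mentions)
}

filter_test_lexicons <- function() {
  list(lexa = lexicon("lexa", c("alpha", "binds"), match_on = "stem"),
       lexb = lexicon("lexb", c("gamma"), match_on = "stem"))
}

# --- similarity ------------------------------------------------------------

random_sparse_vector <- function(universe = letters[1:8]) {
  keys <- sample(universe, sample.int(length(universe), 1L))
  stats::setNames(sample.int(4L, length(keys), replace = TRUE), keys)
}

oracle_cosine <- function(v1, v2) {
  all_keys <- union(names(v1), names(v2))
  a <- vapply(all_keys, function(k) if (k %in% names(v1)) v1[[k]] else 0,
              numeric(1))
  b <- vapply(all_keys, function(k) if (k %in% names(v2)) v2[[k]] else 0,
              numeric(1))
  if (sum(a) == 0 || sum(b) == 0) return(0)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# random short sentence strings for property tests
random_sentence_text <- function() {
  pool <- c("OxyR", "katG", "activates", "represses", "the", "promoter",
            "stress", "response", "binds", "operon", "cells", "grows")
  paste(sample(pool, sample(3:7, 1L), replace = TRUE), collapse = " ")
}

# --- terminology -----------------------------------------------------------

# independent longest-match annotation: enumerate every window, look keys
# up in a variant table built directly from expand_variants, then apply
# left-to-right longest-match-first selection
oracle_annotate <- function(document, entries) {
  exact <- list()  # keys of short, case-sensitive terms
  folded <- list() # lower-cased keys of longer terms
  for (r in seq_len(nrow(entries))) {
    for (v in expand_variants(entries$term[r])) {
      toks <- tokenize(v)
      key <- paste(toks$surface, collapse = " ")
      if (nchar(entries$term[r]) > 3L) {
        key <- tolower(key)
        folded[[key]] <- sort(unique(c(folded[[key]], entries$entity_id[r])))
      } else {
        exact[[key]] <- sort(unique(c(exact[[key]], entries$entity_id[r])))
      }
    }
  }
  lookup <- function(surfaces) {
    key <- paste(surfaces, collapse = " ")
    sort(unique(c(exact[[key]], folded[[tolower(key)]])))
  }
  out <- list()
  for (s in document$sentences) {
    n <- nrow(s$tokens)
    i <- 1L
    while (i <= n) {
      matched <- FALSE
      for (len in rev(seq_len(min(4L, n - i + 1L)))) {
        ids <- lookup(s$tokens$surface[i:(i + len - 1L)])
        if (length(ids)) {
          out[[length(out) + 1L]] <- data.frame(
            sent_id = s$sent_id, start_tok = i, end_tok = i + len,
            ids = paste(ids, collapse = ";"), stringsAsFactors = FALSE)
          i <- i + len
          matched <- TRUE
          break
        }
      }
      if (!matched) i <- i + 1L
    }
  }
  do.call(rbind, c(list(data.frame(sent_id = character(0),
                                   start_tok = integer(0),
                                   end_tok = integer(0),
                                   ids = character(0))), out))
}
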
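# CoNLL-U dependency parse I/O. Parses are consumed, never produced: the
# reader validates each sentence block (single root, acyclic head links)
# and, when given the corpus, checks that the parse tokens line up with the
# corpus tokenization. Heads use the CoNLL-U convention: token indices are
# 1-based and the root's head is 0.

#' Read dependency trees from a CoNLL-U file
#'
#' Sentence blocks must carry a `# sent_id = <id>` comment matching the
#' corpus sentence ids. Multiword-token ranges and empty nodes are skipped.
#' Each tree is validated: exactly one root, all head indices in range, no
#' cycles. With `corpus` supplied, the token count and surfaces of every
#' tree are checked against the corpus tokenization; any mismatch is an
#' error naming the offending `sent_id`.
#'
#' @param path CoNLL-U file.
#' @param corpus optional preprocessed `lit_corpus` to validate against.
#' @return a named list of `dep_tree` objects (names are sent_ids), each
#'   with fields `sent_id`, `form`, `upos`, `head`, `deprel`.
#' @export
read_conllu <- function(path, corpus = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  trees <- list()
  block <- character(0)
  sent_id <- NA_character_
  flush <- function() {
    if (!length(block)) return()
    if (is.na(sent_id)) stop("CoNLL-U block without a '# sent_id =' comment")
    tree <- .parse_conllu_block(block, sent_id)
    trees[[sent_id]] <<- tree
  }
  for (ln in c(lines, "")) {
    if (!nzchar(trimws(ln))) {
      flush()
      block <- character(0)
      sent_id <- NA_character_
    } else if (startsWith(ln, "#")) {
      m <- regmatches(ln, regexec("^#\\s*sent_id\\s*=\\s*(.+?)\\s*$", ln))[[1]]
      if (length(m) == 2L) sent_id <- m[2]
    } else {
      block <- c(block, ln)
    }
  }
  if (!length(trees)) stop("no sentences in CoNLL-U file: ", path)
  if (!is.null(corpus)) {
    for (tree in trees) .check_tree_alignment(tree, corpus)
  }
  trees
}

.parse_conllu_block <- function(block, sent_id) {
  fields <- strsplit(block, "\t", fixed = TRUE)
  keep <- vapply(fields, function(f) grepl("^[0-9]+$", f[1]), logical(1))
  fields <- fields[keep]
  if (!length(fields)) stop("empty CoNLL-U sentence: ", sent_id)
  if (any(vapply(fields, length, integer(1)) < 8L)) {
    stop("malformed CoNLL-U row (needs >= 8 tab-separated fields): ", sent_id)
  }
  form <- vapply(fields, `[[`, "", 2L)
  upos <- vapply(fields, `[[`, "", 4L)
  head <- as.integer(vapply(fields, `[[`, "", 7L))
  deprel <- vapply(fields, `[[`, "", 8L)
  dep_tree(sent_id, form, upos, head, deprel)
}

#' Construct and validate a dependency tree
#'
#' @param sent_id sentence identifier.
#' @param form token surfaces.
#' @param upos universal part-of-speech tags (may be `"_"`).
#' @param head 1-based head indices, 0 for the root.
#' @param deprel dependency relation labels.
#' @return an object of class `dep_tree`.
#' @export
dep_tree <- function(sent_id, form, upos, head, deprel) {
  n <- length(form)
  stopifnot(length(upos) == n, length(head) == n, length(deprel) == n, n > 0L)
  if (anyNA(head) || any(head < 0L) || any(head > n)) {
    stop("head index out of range in sentence ", sent_id)
  }
  roots <- which(head == 0L)
  if (length(roots) != 1L) {
    stop("dependency tree must have exactly one root (sentence ", sent_id,
         " has ", length(roots), ")")
  }
  # cycle check: from every node, following heads must reach the root
  # within n steps
  for (i in seq_len(n)) {
    j <- i
    for (step in seq_len(n)) {
      if (head[j] == 0L) break
      j <- head[j]
    }
    if (head[j] != 0L) stop("cycle in head links of sentence ", sent_id)
  }
  structure(list(sent_id = sent_id, form = form, upos = upos,
                 head = head, deprel = deprel, root = roots),
            class = "dep_tree")
}

#' @export
print.dep_tree <- function(x, ...) {
  cat(sprintf("<dep_tree> %s: %d tokens, root '%s'\n",
              x$sent_id, length(x$form), x$form[x$root]))
  invisible(x)
}

.check_tree_alignment <- function(tree, corpus) {
  doc_id <- sub(":s[0-9]+$", "", tree$sent_id)
  doc <- corpus[[doc_id]]
  sent <- NULL
  if (!is.null(doc)) {
    for (s in doc$sentences) if (s$sent_id == tree$sent_id) sent <- s
  }
  if (is.null(sent)) {
    stop("CoNLL-U sentence not found in corpus: ", tree$sent_id)
  }
  if (length(tree$form) != nrow(sent$tokens) ||
      !all(tree$form == sent$tokens$surface)) {
    stop("tokenization mismatch between CoNLL-U and corpus for sentence ",
         tree$sent_id)
  }
  invisible(TRUE)
}

#' Write dependency trees to a CoNLL-U file
#' @param trees named list of `dep_tree` objects.
#' @param path output file.
#' @export
write_conllu <- function(trees, path) {
  out <- character(0)
  for (tree in trees) {
    rows <- vapply(seq_along(tree$form), function(i) {
      paste(i, tree$form[i], "_", tree$upos[i], "_", "_",
            tree$head[i], tree$deprel[i], "_", "_", sep = "\t")
    }, character(1))
    out <- c(out, paste0("# sent_id = ", tree$sent_id), rows, "")
  }
  writeLines(out, path, useBytes = FALSE)
  invisible(path)
}
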
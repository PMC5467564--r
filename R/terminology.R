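# Dictionary-based entity annotation. Terminology rows map a surface term
# to a reference-database identifier and entity type; the matcher indexes
# every automatically generated minor variant of every term and annotates
# token sequences left-to-right, longest match first, without overlaps.
# Ambiguity (one surface, several identifiers) is preserved on the mention
# as a candidate list and resolved later (see the disambiguation module).

#' Validate terminology entries
#'
#' @param entries a data frame with columns `term`, `entity_id`,
#'   `entity_type`, `source`.
#' @return the entries as a tibble, invisibly validated.
#' @export
term_entries <- function(entries) {
  entries <- tibble::as_tibble(entries)
  need <- c("term", "entity_id", "entity_type", "source")
  if (!all(need %in% names(entries))) {
    stop("dictionary needs columns: ", paste(need, collapse = ", "))
  }
  if (!nrow(entries)) stop("empty dictionary: no entries")
  if (any(!nzchar(entries$term))) stop("empty term in dictionary")
  key <- paste(entries$term, entries$entity_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (term, entity_id) pair in dictionary: ",
         entries$term[duplicated(key)][1])
  }
  entries[, need]
}

#' Read a terminology dictionary from TSV
#' @param path TSV with columns `term`, `entity_id`, `entity_type`, `source`.
#' @return a validated entries tibble.
#' @export
read_dictionary <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character", check.names = FALSE)
  term_entries(tab)
}

#' Write a terminology dictionary to TSV
#' @param entries entries tibble.
#' @param path output file.
#' @export
write_dictionary <- function(entries, path) {
  utils::write.table(term_entries(entries), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Expand the minor variants of a term
#'
#' Term recognition tolerates small orthographic differences: hyphens
#' swapped for spaces and vice versa, hyphen deletion, and — for terms
#' longer than 3 characters — a case-folded form. Terms of up to 3
#' characters stay case-sensitive because short gene symbols are
#' case-informative. The returned set is closed: expanding any of its
#' members yields no new strings.
#'
#' @param term a non-empty term string.
#' @return character vector of variants (always includes `term` itself).
#' @export
expand_variants <- function(term) {
  stopifnot(is.character(term), length(term) == 1L, nzchar(term))
  fold <- nchar(term) > 3L
  out <- term
  repeat {
    new <- unique(c(
      out,
      gsub("-", " ", out, fixed = TRUE),
      gsub(" ", "-", out, fixed = TRUE),
      gsub("-", "", out, fixed = TRUE),
      if (fold) tolower(out)
    ))
    if (length(new) == length(out)) break
    out <- new
  }
  sort(out)
}

#' Compile a terminology dictionary into a matcher
#'
#' Every variant of every term is tokenized and indexed by its token
#' surface sequence. Variants of distinct entries may collide; the matcher
#' keeps all of them, so an ambiguous surface yields a mention listing all
#' candidate identifiers. Terms longer than 3 characters are matched
#' case-insensitively, shorter ones exactly.
#'
#' @param entries entries tibble (see [term_entries()]).
#' @return an object of class `term_matcher`.
#' @export
compile_dictionary <- function(entries) {
  entries <- term_entries(entries)
  cs <- new.env(parent = emptyenv(), hash = TRUE)
  ci <- new.env(parent = emptyenv(), hash = TRUE)
  max_len <- 1L
  add <- function(env, key, row) {
    assign(key, c(if (exists(key, envir = env, inherits = FALSE))
      get(key, envir = env), row), envir = env)
  }
  for (row in seq_len(nrow(entries))) {
    term <- entries$term[row]
    fold <- nchar(term) > 3L
    for (v in expand_variants(term)) {
      toks <- tokenize(v)
      if (!nrow(toks)) next
      key <- paste(toks$surface, collapse = " ")
      max_len <- max(max_len, nrow(toks))
      if (fold) add(ci, tolower(key), row) else add(cs, key, row)
    }
  }
  structure(list(entries = entries, cs = cs, ci = ci, max_len = max_len),
            class = "term_matcher")
}

#' @export
print.term_matcher <- function(x, ...) {
  cat(sprintf(
    "<term_matcher> %d entries, %d variant keys, max term length %d token(s)\n",
    nrow(x$entries), length(ls(x$cs)) + length(ls(x$ci)), x$max_len))
  invisible(x)
}

.matcher_lookup <- function(matcher, key) {
  rows <- integer(0)
  if (exists(key, envir = matcher$cs, inherits = FALSE)) {
    rows <- c(rows, get(key, envir = matcher$cs))
  }
  lkey <- tolower(key)
  if (exists(lkey, envir = matcher$ci, inherits = FALSE)) {
    rows <- c(rows, get(lkey, envir = matcher$ci))
  }
  unique(rows)
}

.empty_mentions <- function() {
  tibble::tibble(
    doc_id = character(0), sent_id = character(0),
    start_tok = integer(0), end_tok = integer(0),
    char_start = integer(0), char_end = integer(0),
    matched_surface = character(0), entity_type = character(0),
    candidate_ids = list(), resolved_id = character(0)
  )
}

#' Annotate a document with entity mentions
#'
#' Scans each sentence's token sequence left to right; at each position the
#' longest dictionary match wins and matching resumes after it, so mentions
#' never overlap ("oxyS promoter" beats "oxyS" where both are terms).
#' Matching is over whole token sequences, never inside tokens, so a term
#' "oxy" cannot fire inside the word "oxygen". Each mention carries every
#' candidate identifier for its surface; `resolved_id` is set immediately
#' when there is exactly one candidate and left `NA` otherwise.
#'
#' @param document a preprocessed `lit_document`.
#' @param matcher a compiled `term_matcher`.
#' @return a mentions tibble with columns `doc_id`, `sent_id`, `start_tok`,
#'   `end_tok` (1-based, half-open token span), `char_start`, `char_end`
#'   (0-based, half-open), `matched_surface`, `entity_type` (distinct types
#'   joined with `;` while ambiguous), `candidate_ids` (list column of
#'   sorted ids), `resolved_id`.
#' @export
annotate <- function(document, matcher) {
  stopifnot(inherits(matcher, "term_matcher"))
  out <- list()
  for (s in document$sentences) {
    toks <- s$tokens
    n <- nrow(toks)
    i <- 1L
    while (i <= n) {
      hit_len <- 0L
      hit_rows <- integer(0)
      for (len in seq(min(matcher$max_len, n - i + 1L), 1L)) {
        key <- paste(toks$surface[i:(i + len - 1L)], collapse = " ")
        rows <- .matcher_lookup(matcher, key)
        if (length(rows)) {
          hit_len <- len
          hit_rows <- rows
          break
        }
      }
      if (hit_len) {
        ids <- sort(unique(matcher$entries$entity_id[hit_rows]))
        types <- sort(unique(matcher$entries$entity_type[hit_rows]))
        cs0 <- toks$char_start[i]
        ce0 <- toks$char_end[i + hit_len - 1L]
        out[[length(out) + 1L]] <- tibble::tibble(
          doc_id = document$doc_id, sent_id = s$sent_id,
          start_tok = i, end_tok = i + hit_len,
          char_start = cs0, char_end = ce0,
          matched_surface = text_slice(document$text, cs0, ce0),
          entity_type = paste(types, collapse = ";"),
          candidate_ids = list(ids),
          resolved_id = if (length(ids) == 1L) ids else NA_character_
        )
        i <- i + hit_len
      } else {
        i <- i + 1L
      }
    }
  }
  if (!length(out)) return(.empty_mentions())
  dplyr::bind_rows(out)
}

#' Annotate every document of a corpus
#' @param corpus a preprocessed `lit_corpus`.
#' @inheritParams annotate
#' @return mentions tibble over all documents, in corpus order.
#' @export
annotate_corpus <- function(corpus, matcher) {
  dplyr::bind_rows(c(list(.empty_mentions()),
                     lapply(corpus, annotate, matcher = matcher)))
}

#' Write mentions to TSV
#'
#' `candidate_ids` are semicolon-joined; the remaining columns are written
#' as-is. [read_mentions()] restores the list column.
#'
#' @param mentions mentions tibble.
#' @param path output file.
#' @export
write_mentions <- function(mentions, path) {
  flat <- mentions
  flat$candidate_ids <- vapply(mentions$candidate_ids, paste,
                               character(1), collapse = ";")
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read mentions from TSV
#' @param path file written by [write_mentions()].
#' @return mentions tibble.
#' @export
read_mentions <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character", na.strings = "")
  tab$start_tok <- as.integer(tab$start_tok)
  tab$end_tok <- as.integer(tab$end_tok)
  tab$char_start <- as.integer(tab$char_start)
  tab$char_end <- as.integer(tab$char_end)
  tab <- tibble::as_tibble(tab)
  tab$candidate_ids <- lapply(strsplit(tab$candidate_ids, ";", fixed = TRUE),
                              sort)
  tab
}
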
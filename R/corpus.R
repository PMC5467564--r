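# Text data model. A corpus is a named list of documents; a document holds
# its raw text plus (after preprocessing) a list of sentences, each carrying
# a token table. Character offsets are 0-based and half-open so that the
# document text slice [char_start, char_end) reproduces a surface exactly;
# token positions inside a sentence are ordinary 1-based R indices.

#' Construct a document
#'
#' @param doc_id unique document identifier.
#' @param text the raw document text (preserved verbatim).
#' @return an object of class `lit_document` with empty `sentences`.
#' @export
lit_document <- function(doc_id, text) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L, nzchar(doc_id),
            is.character(text), length(text) == 1L)
  structure(
    list(doc_id = doc_id, text = text, sentences = list()),
    class = "lit_document"
  )
}

#' Bundle documents into a corpus
#'
#' @param documents list of `lit_document` objects with distinct ids.
#' @param corpus_id optional identifier recorded in downstream link graphs.
#' @return an object of class `lit_corpus` (a list of documents named by id).
#' @export
as_corpus <- function(documents, corpus_id = "corpus") {
  stopifnot(is.list(documents))
  ids <- vapply(documents, function(d) d$doc_id, character(1))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate doc_id: ", paste(unique(dup), collapse = ", "))
  }
  names(documents) <- ids
  structure(documents, class = "lit_corpus", corpus_id = corpus_id)
}

#' @export
print.lit_corpus <- function(x, ...) {
  ns <- sum(vapply(x, function(d) length(d$sentences), integer(1)))
  cat(sprintf("<lit_corpus> %d document(s), %d sentence(s)\n", length(x), ns))
  invisible(x)
}

#' @export
print.lit_document <- function(x, ...) {
  cat(sprintf("<lit_document> %s: %d chars, %d sentence(s)\n",
              x$doc_id, nchar(x$text), length(x$sentences)))
  invisible(x)
}

#' Slice document text by a 0-based half-open character span
#'
#' @param text document text.
#' @param char_start,char_end 0-based half-open span.
#' @return the substring covered by the span.
#' @export
text_slice <- function(text, char_start, char_end) {
  substr(text, char_start + 1L, char_end)
}

#' Read a corpus from disk
#'
#' Two layouts are supported: a directory of UTF-8 `.txt` files (one
#' document per file, `doc_id` = file name without extension), or a TSV
#' with columns `doc_id` and `text`. Text is preserved exactly as read;
#' sentences are not yet split (see [split_sentences()] /
#' [preprocess_corpus()]).
#'
#' @param path directory or TSV file path.
#' @param format `"txt-dir"` or `"tsv"`.
#' @return a `lit_corpus`.
#' @export
read_corpus <- function(path, format = c("txt-dir", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("path does not exist: ", path)
  if (format == "txt-dir") {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    if (!length(files)) stop("empty corpus: no .txt files under ", path)
    docs <- lapply(files, function(f) {
      txt <- readChar(f, file.info(f)$size, useBytes = FALSE)
      # strip a single trailing newline added by editors; inner text is kept
      txt <- sub("\n$", "", txt)
      lit_document(sub("\\.txt$", "", basename(f)), txt)
    })
  } else {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             quote = "", comment.char = "",
                             colClasses = "character", check.names = FALSE)
    if (!all(c("doc_id", "text") %in% names(tab))) {
      stop("tsv corpus must have columns doc_id and text")
    }
    if (!nrow(tab)) stop("empty corpus: no rows in ", path)
    docs <- lapply(seq_len(nrow(tab)), function(i) {
      lit_document(tab$doc_id[i], tab$text[i])
    })
  }
  as_corpus(docs)
}

#' Write a corpus as a doc_id/text TSV
#'
#' @param corpus a `lit_corpus`.
#' @param path output file.
#' @export
write_corpus_tsv <- function(corpus, path) {
  tab <- data.frame(
    doc_id = vapply(corpus, function(d) d$doc_id, character(1)),
    text = vapply(corpus, function(d) d$text, character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Abbreviations that suppress sentence splitting
#'
#' Periods ending these strings are not treated as sentence boundaries. Any
#' single capital letter followed by a period (a genus or name initial, as
#' in "E. coli") is always suppressed in addition to this list.
#'
#' @return character vector of abbreviations.
#' @export
default_abbreviations <- function() {
  c("e.g.", "i.e.", "cf.", "vs.", "et al.", "al.", "Fig.", "fig.",
    "Figs.", "Eq.", "no.", "No.", "ca.", "approx.", "Dr.", "St.", "sp.",
    "spp.", "subsp.", "str.")
}

#' Split a document into sentences
#'
#' Boundaries are placed at runs of sentence-final punctuation (`.`, `!`,
#' `?`, optionally followed by closing quotes/brackets) that are followed by
#' whitespace and an upper-case letter or digit. A period is not a boundary
#' when the preceding word is a known abbreviation or a single capital
#' letter (so "E. coli" never splits). Every non-whitespace character of
#' the document falls inside exactly one sentence span; leading/trailing
#' whitespace between sentences belongs to no sentence. Text without any
#' terminator yields a single sentence.
#'
#' @param document a `lit_document`.
#' @param abbreviations abbreviation stop-list, see [default_abbreviations()].
#' @return the document with `sentences` populated (tokens not yet filled).
#' @export
split_sentences <- function(document, abbreviations = default_abbreviations()) {
  text <- document$text
  stopifnot(nzchar(text))
  n <- nchar(text)

  m <- gregexpr("[.!?]+[\"')\\]]*(?=[ \t\r\n]+[A-Z0-9])", text, perl = TRUE)[[1]]
  cut_after <- integer(0) # 1-based index of last char of each sentence
  if (m[1] != -1L) {
    starts <- as.integer(m)
    ends <- starts + attr(m, "match.length") - 1L
    for (j in seq_along(ends)) {
      e <- ends[j]
      punct <- substr(text, starts[j], e)
      pre <- substr(text, max(1L, e - 24L), e)
      is_abbrev <- FALSE
      if (grepl(".", punct, fixed = TRUE)) {
        # single capital initial: "... E."
        if (grepl("(^|[^A-Za-z])[A-Z]\\.$", pre)) is_abbrev <- TRUE
        for (ab in abbreviations) {
          if (endsWith(pre, ab)) {
            before <- substr(pre, nchar(pre) - nchar(ab), nchar(pre) - nchar(ab))
            if (before == "" || grepl("[^A-Za-z]", before)) is_abbrev <- TRUE
          }
        }
      }
      if (!is_abbrev) cut_after <- c(cut_after, e)
    }
  }
  bounds <- c(0L, cut_after, n) # segment k covers (bounds[k], bounds[k+1]]
  sentences <- list()
  idx <- 0L
  for (k in seq_len(length(bounds) - 1L)) {
    seg_start <- bounds[k] + 1L
    seg_end <- bounds[k + 1L]
    if (seg_start > seg_end) next
    seg <- substr(text, seg_start, seg_end)
    first_nw <- regexpr("[^ \t\r\n]", seg)
    if (first_nw == -1L) next
    last_nw <- regexpr("[ \t\r\n]*$", seg) - 1L
    char_start <- seg_start + as.integer(first_nw) - 2L # to 0-based
    char_end <- seg_start + as.integer(last_nw) - 1L    # 0-based exclusive
    sentences[[length(sentences) + 1L]] <- list(
      sent_id = sprintf("%s:s%d", document$doc_id, idx),
      doc_id = document$doc_id,
      index = idx,
      char_start = char_start,
      char_end = char_end,
      text = text_slice(text, char_start, char_end),
      tokens = NULL
    )
    idx <- idx + 1L
  }
  document$sentences <- sentences
  document
}

#' Tokenize a stretch of text
#'
#' Tokens are maximal runs of alphanumeric characters (hyphens joining two
#' alphanumerics are kept inside the token, so "heat-shock" is one token)
#' or single punctuation marks. Offsets are document-absolute, 0-based,
#' half-open: `text_slice(document_text, char_start, char_end)` reproduces
#' each surface.
#'
#' @param text the sentence text.
#' @param offset the sentence's `char_start` within its document (0-based).
#' @return a tibble with columns `surface`, `char_start`, `char_end`.
#' @export
tokenize <- function(text, offset = 0L) {
  empty <- tibble::tibble(surface = character(0),
                          char_start = integer(0), char_end = integer(0))
  if (!nzchar(text)) return(empty)
  m <- gregexpr("[A-Za-z0-9]+(?:-[A-Za-z0-9]+)*|[^ \t\r\nA-Za-z0-9]",
                text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  tibble::tibble(
    surface = substring(text, starts, starts + lens - 1L),
    char_start = offset + starts - 1L,
    char_end = offset + starts + lens - 1L
  )
}

#' Preprocess a corpus
#'
#' Runs the full normalization cascade on every document: sentence
#' splitting, tokenization, stemming and coarse part-of-speech tagging.
#' Most downstream operations (annotation, filters, similarity, linking)
#' expect a preprocessed corpus.
#'
#' @param corpus a `lit_corpus`.
#' @param abbreviations abbreviation stop-list for sentence splitting.
#' @param tagger part-of-speech tagger, see [pos_tag()].
#' @return the corpus with sentences and annotated token tables populated.
#' @export
preprocess_corpus <- function(corpus, abbreviations = default_abbreviations(),
                              tagger = default_pos_tagger) {
  docs <- lapply(corpus, function(doc) preprocess_document(doc, abbreviations, tagger))
  as_corpus(docs, corpus_id = attr(corpus, "corpus_id"))
}

#' @rdname preprocess_corpus
#' @param document a `lit_document`.
#' @export
preprocess_document <- function(document, abbreviations = default_abbreviations(),
                                tagger = default_pos_tagger) {
  doc <- split_sentences(document, abbreviations)
  doc$sentences <- lapply(doc$sentences, function(s) {
    toks <- tokenize(s$text, offset = s$char_start)
    toks$stem <- if (nrow(toks)) stem(toks$surface) else character(0)
    s$tokens <- pos_tag(toks, tagger = tagger)
    s
  })
  doc
}

#' List every sentence of a corpus
#'
#' @param corpus a preprocessed `lit_corpus`.
#' @return a list of sentence records in corpus order.
#' @export
corpus_sentences <- function(corpus) {
  unlist(lapply(corpus, function(d) d$sentences), recursive = FALSE,
         use.names = FALSE)
}

#' Look up one sentence by id
#' @param corpus a preprocessed `lit_corpus`.
#' @param doc_id,sent_id sentence address.
#' @return the sentence record.
#' @export
get_sentence <- function(corpus, doc_id, sent_id) {
  doc <- corpus[[doc_id]]
  if (is.null(doc)) stop("unknown doc_id: ", doc_id)
  for (s in doc$sentences) if (s$sent_id == sent_id) return(s)
  stop("unknown sent_id: ", sent_id, " in document ", doc_id)
}
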
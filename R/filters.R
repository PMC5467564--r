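# Boolean sentence filters. A filter is a curator-written expression over
# per-sentence annotations — "type:TF AND lexicon:effect" selects sentences
# mentioning a transcription factor together with a regulatory-effect word,
# which is how a curator narrows hundreds of sentences down to the handful
# worth reading. Grammar (keywords case-insensitive, NOT > AND > OR, both
# binary operators left-associative):
#
#   expr    := or
#   or      := and (OR and)*
#   and     := not (AND not)*
#   not     := NOT not | primary
#   primary := '(' or ')' | atom
#   atom    := type:<TYPE> | lexicon:<name> | term:"<literal>"

.filter_tokenize <- function(expr) {
  pat <- paste0(
    '\\(|\\)|',
    'type:[A-Za-z0-9_;-]+|',
    'lexicon:[A-Za-z0-9_-]+|',
    'term:"[^"]*"|',
    '[A-Za-z]+'
  )
  m <- gregexpr(pat, expr, perl = TRUE)[[1]]
  if (m[1] == -1L) stop("filter syntax error at position 1: empty expression")
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  texts <- substring(expr, starts, starts + lens - 1L)
  # anything between tokens other than whitespace is a syntax error
  covered <- rep(FALSE, nchar(expr))
  for (i in seq_along(starts)) {
    covered[seq(starts[i], starts[i] + lens[i] - 1L)] <- TRUE
  }
  chars <- strsplit(expr, "", fixed = TRUE)[[1]]
  bad <- which(!covered & !grepl("^[ \t\r\n]$", chars))
  if (length(bad)) {
    stop("filter syntax error at position ", bad[1],
         ": unexpected character '", chars[bad[1]], "'")
  }
  list(text = texts, pos = starts)
}

.filter_atom <- function(tok) {
  if (startsWith(tok, "type:")) {
    list(op = "atom", kind = "type", value = sub("^type:", "", tok))
  } else if (startsWith(tok, "lexicon:")) {
    list(op = "atom", kind = "lexicon", value = sub("^lexicon:", "", tok))
  } else if (startsWith(tok, "term:")) {
    list(op = "atom", kind = "term",
         value = sub('^term:"(.*)"$', "\\1", tok))
  } else {
    NULL
  }
}

#' Parse a filter expression
#'
#' Parses the filter grammar into an expression tree. Keywords `AND`,
#' `OR`, `NOT` are case-insensitive; atom payloads are case-sensitive.
#' Precedence is `NOT` > `AND` > `OR`, so `"NOT a AND b"` reads as
#' `(NOT a) AND b`. Syntax errors report a character position. When
#' `lexicons` is supplied, every `lexicon:` atom must name one of them.
#'
#' @param expr filter expression string.
#' @param lexicons optional named list of `lit_lexicon` objects (or a
#'   character vector of known names) used to validate lexicon atoms.
#' @return an object of class `filter_expr`.
#' @export
parse_filter <- function(expr, lexicons = NULL) {
  stopifnot(is.character(expr), length(expr) == 1L)
  toks <- .filter_tokenize(expr)
  i <- 1L
  n <- length(toks$text)
  peek <- function() if (i <= n) toks$text[i] else NA_character_
  pos <- function() if (i <= n) toks$pos[i] else nchar(expr) + 1L
  advance <- function() i <<- i + 1L
  is_kw <- function(tok, kw) !is.na(tok) && toupper(tok) == kw

  parse_or <- function() {
    node <- parse_and()
    while (is_kw(peek(), "OR")) {
      advance()
      node <- list(op = "or", children = list(node, parse_and()))
    }
    node
  }
  parse_and <- function() {
    node <- parse_not()
    while (is_kw(peek(), "AND")) {
      advance()
      node <- list(op = "and", children = list(node, parse_not()))
    }
    node
  }
  parse_not <- function() {
    if (is_kw(peek(), "NOT")) {
      advance()
      return(list(op = "not", children = list(parse_not())))
    }
    parse_primary()
  }
  open_parens <- integer(0)
  parse_primary <- function() {
    tok <- peek()
    p <- pos()
    if (is.na(tok)) {
      if (length(open_parens)) {
        stop("filter syntax error at position ", tail(open_parens, 1),
             ": unclosed '('")
      }
      stop("filter syntax error at position ", p, ": unexpected end of expression")
    }
    if (tok == "(") {
      advance()
      open_parens <<- c(open_parens, p)
      node <- parse_or()
      if (!identical(peek(), ")")) {
        stop("filter syntax error at position ", p, ": unclosed '('")
      }
      open_parens <<- head(open_parens, -1L)
      advance()
      return(node)
    }
    atom <- .filter_atom(tok)
    if (is.null(atom)) {
      stop("filter syntax error at position ", p, ": expected an atom, got '",
           tok, "'")
    }
    advance()
    atom
  }

  tree <- parse_or()
  if (i <= n) {
    stop("filter syntax error at position ", pos(), ": trailing input '",
         peek(), "'")
  }
  if (!is.null(lexicons)) {
    known <- if (is.character(lexicons)) lexicons else names(lexicons)
    for (name in .filter_lexicon_names(tree)) {
      if (!name %in% known) stop("unknown lexicon in filter: ", name)
    }
  }
  structure(tree, class = "filter_expr")
}

.filter_lexicon_names <- function(node) {
  if (node$op == "atom") {
    if (node$kind == "lexicon") node$value else character(0)
  } else {
    unlist(lapply(node$children, .filter_lexicon_names))
  }
}

#' Print a filter expression canonically
#'
#' Produces a string that re-parses to the same tree (round-trip), with
#' parentheses only where precedence requires them.
#'
#' @param expr a `filter_expr`.
#' @return a single string.
#' @export
format_filter <- function(expr) {
  prec <- c(or = 1L, and = 2L, not = 3L, atom = 4L)
  fmt <- function(node) {
    p <- prec[[node$op]]
    wrap <- function(child) {
      s <- fmt(child)
      if (prec[[child$op]] < p) paste0("(", s, ")") else s
    }
    switch(node$op,
      atom = switch(node$kind,
        type = paste0("type:", node$value),
        lexicon = paste0("lexicon:", node$value),
        term = paste0('term:"', node$value, '"')
      ),
      not = paste0("NOT ", wrap(node$children[[1]])),
      and = paste(wrap(node$children[[1]]), "AND", wrap(node$children[[2]])),
      or = paste(wrap(node$children[[1]]), "OR", wrap(node$children[[2]]))
    )
  }
  fmt(expr)
}

#' @export
print.filter_expr <- function(x, ...) {
  cat("<filter_expr>", format_filter(x), "\n")
  invisible(x)
}

#' Evaluate a filter against one sentence
#'
#' Atoms see only this sentence: `type:T` is true when at least one
#' mention in the sentence has entity type `T` (an ambiguous mention
#' carrying several types satisfies each of them); `lexicon:name` is true
#' when at least one token matches the named lexicon (on stems or
#' surfaces, per the lexicon's `match_on`); `term:"s"` is true when the
#' literal string occurs in the sentence text. Internal nodes apply
#' ordinary boolean semantics.
#'
#' @param expr a `filter_expr` (or expression string, parsed on the fly).
#' @param sentence a preprocessed sentence record.
#' @param mentions mentions tibble (rows outside this sentence ignored).
#' @param lexicons named list of `lit_lexicon` objects.
#' @return `TRUE` or `FALSE`.
#' @export
eval_filter <- function(expr, sentence, mentions, lexicons = list()) {
  if (is.character(expr)) expr <- parse_filter(expr, lexicons)
  ms <- mentions[mentions$sent_id == sentence$sent_id, , drop = FALSE]
  sent_types <- unique(.split_types(ms$entity_type))
  ev <- function(node) {
    switch(node$op,
      atom = switch(node$kind,
        type = node$value %in% sent_types,
        lexicon = {
          lex <- lexicons[[node$value]]
          if (is.null(lex)) stop("unknown lexicon in filter: ", node$value)
          lexicon_hit(lex, sentence$tokens)
        },
        term = grepl(node$value, sentence$text, fixed = TRUE)
      ),
      not = !ev(node$children[[1]]),
      and = ev(node$children[[1]]) && ev(node$children[[2]]),
      or = ev(node$children[[1]]) || ev(node$children[[2]])
    )
  }
  ev(expr)
}

#' Select the sentences of a corpus satisfying a filter
#'
#' @param corpus a preprocessed `lit_corpus`.
#' @param expr a `filter_expr` or expression string.
#' @param mentions mentions tibble from [annotate_corpus()].
#' @param lexicons named list of `lit_lexicon` objects.
#' @return an object of class `sentence_selection`: a list with `selected`
#'   (tibble `doc_id`, `sent_id`, `text`, in corpus order), `n_total`,
#'   `n_selected` and `fraction` (share of all sentences selected).
#' @export
select_sentences <- function(corpus, expr, mentions, lexicons = list()) {
  if (is.character(expr)) expr <- parse_filter(expr, lexicons)
  sents <- corpus_sentences(corpus)
  hits <- vapply(sents, function(s) eval_filter(expr, s, mentions, lexicons),
                 logical(1))
  selected <- tibble::tibble(
    doc_id = vapply(sents, `[[`, "", "doc_id")[hits],
    sent_id = vapply(sents, `[[`, "", "sent_id")[hits],
    text = vapply(sents, `[[`, "", "text")[hits]
  )
  structure(
    list(selected = selected, n_total = length(sents),
         n_selected = sum(hits),
         fraction = if (length(sents)) sum(hits) / length(sents) else 0),
    class = "sentence_selection"
  )
}

#' @export
print.sentence_selection <- function(x, ...) {
  cat(sprintf("<sentence_selection> %d / %d sentences (fraction %.3f)\n",
              x$n_selected, x$n_total, x$fraction))
  invisible(x)
}
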
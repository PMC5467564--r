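# Keyword lexicons: small curator-maintained word collections (e.g. the
# family of regulatory-effect words "activates", "repression", ...) used by
# sentence filters and by relation trigger gating. A lexicon matches either
# token surfaces verbatim or token stems (the default, so one entry "activ"
# or "activates" covers the whole inflectional family).

#' Construct a keyword lexicon
#'
#' @param name lexicon name (referenced by filter atoms `lexicon:<name>`).
#' @param entries non-empty character vector of words or stems.
#' @param match_on `"stem"` (entries and tokens are compared after
#'   lower-casing and stemming) or `"surface"` (verbatim comparison).
#' @return an object of class `lit_lexicon`.
#' @export
lexicon <- function(name, entries, match_on = c("stem", "surface")) {
  match_on <- match.arg(match_on)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.character(entries), length(entries) > 0L, all(nzchar(entries)))
  keys <- if (match_on == "stem") unique(stem(tolower(entries))) else unique(entries)
  structure(
    list(name = name, entries = unique(entries), match_on = match_on, keys = keys),
    class = "lit_lexicon"
  )
}

#' @export
print.lit_lexicon <- function(x, ...) {
  cat(sprintf("<lit_lexicon> %s: %d entries, match_on=%s\n",
              x$name, length(x$entries), x$match_on))
  invisible(x)
}

#' Does a sentence hit a lexicon?
#'
#' @param lex a `lit_lexicon`.
#' @param tokens a token tibble (with `stem` when `match_on = "stem"`).
#' @return `TRUE` if at least one token matches.
#' @export
lexicon_hit <- function(lex, tokens) {
  if (!nrow(tokens)) return(FALSE)
  if (lex$match_on == "stem") any(tokens$stem %in% lex$keys)
  else any(tokens$surface %in% lex$keys)
}

#' Read a lexicon from a line-oriented text file
#'
#' One entry per line; blank lines and lines starting with `#` are skipped.
#'
#' @param path file path.
#' @inheritParams lexicon
#' @return a `lit_lexicon`.
#' @export
read_lexicon <- function(path, name = sub("\\.[^.]*$", "", basename(path)),
                         match_on = c("stem", "surface")) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lexicon(name, lines, match_on = match.arg(match_on))
}

#' Write a lexicon's entries to a line-oriented text file
#' @param lex a `lit_lexicon`.
#' @param path output file.
#' @export
write_lexicon <- function(lex, path) {
  writeLines(lex$entries, path, useBytes = FALSE)
  invisible(path)
}

#' The regulatory-effect word family
#'
#' Words expressing the effect of a transcription factor on its target
#' (activation, repression, or unspecific regulation), together with the
#' polarity class of each word. Used as the default trigger lexicon for
#' relation extraction and as the conventional `effect` lexicon in filters.
#'
#' @return a tibble with columns `term` and `polarity`.
#' @export
default_effect_lexicon <- function() {
  tibble::tibble(
    term = c(
      "activates", "activate", "activated", "activation", "activator",
      "induces", "induce", "induced", "induction",
      "stimulates", "stimulate", "stimulated", "stimulation",
      "enhances", "enhance", "enhanced", "enhancement",
      "represses", "repress", "repressed", "repression", "repressor",
      "inhibits", "inhibit", "inhibited", "inhibition",
      "silences", "silenced", "silencing",
      "regulates", "regulate", "regulated", "regulation",
      "upregulates", "upregulated", "upregulation",
      "downregulates", "downregulated", "downregulation",
      "controls", "controlled", "modulates", "modulated"
    ),
    polarity = c(
      rep("activation", 5),
      rep("activation", 4),
      rep("activation", 4),
      rep("activation", 4),
      rep("repression", 5),
      rep("repression", 4),
      rep("repression", 3),
      rep("regulation", 4),
      rep("activation", 3),
      rep("repression", 3),
      rep("regulation", 2), rep("regulation", 2)
    )
  )
}

#' Read an effect lexicon (term, polarity) from TSV
#' @param path TSV with columns `term` and `polarity`.
#' @return a tibble with columns `term` and `polarity`.
#' @export
read_effect_lexicon <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character")
  stopifnot(all(c("term", "polarity") %in% names(tab)))
  tibble::as_tibble(tab[, c("term", "polarity")])
}

#' Write an effect lexicon to TSV
#' @param effect_lexicon tibble with columns `term` and `polarity`.
#' @param path output file.
#' @export
write_effect_lexicon <- function(effect_lexicon, path) {
  utils::write.table(effect_lexicon, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# stem -> polarity map; on collisions the first polarity in table order wins
effect_stem_map <- function(effect_lexicon = default_effect_lexicon()) {
  stems <- stem(tolower(effect_lexicon$term))
  keep <- !duplicated(stems)
  stats::setNames(effect_lexicon$polarity[keep], stems[keep])
}

#' Convert an effect lexicon to a plain filter lexicon
#' @param effect_lexicon tibble with columns `term` and `polarity`.
#' @param name lexicon name, default `"effect"`.
#' @return a `lit_lexicon` matching on stems.
#' @export
as_effect_filter_lexicon <- function(effect_lexicon = default_effect_lexicon(),
                                     name = "effect") {
  lexicon(name, effect_lexicon$term, match_on = "stem")
}

#' A small English stop word list
#'
#' Function words with no topical content, used (optionally) when building
#' sentence vectors so that shared determiners and prepositions do not
#' inflate similarity between unrelated sentences. Vectorization defaults
#' to no stop word removal; pass this list explicitly where wanted.
#'
#' @return character vector of lower-case stop words.
#' @export
default_stopwords <- function() {
  c(.closed_class$other, .closed_class$verb,
    "then", "now", "also", "not", "thus", "there", "here", "such",
    "other", "more", "most", "many", "much", "few", "several", "same",
    "own", "very", "too", "just", "both")
}
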
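# Coarse part-of-speech tagging. The pipeline only consumes noun/verb
# distinctions (relation trigger gating, POS-aware normalization), so tags
# are restricted to a 5-label set: NOUN, VERB, ADJ, ADV, OTHER. The default
# tagger is a closed-class lexicon plus suffix rules; any vectorized
# function (surface, stem) -> tag can be dropped in instead.

.pos_labels <- c("NOUN", "VERB", "ADJ", "ADV", "OTHER")

.closed_class <- local({
  det <- c("the", "a", "an", "this", "that", "these", "those", "each",
           "every", "some", "any", "no", "all", "both", "its", "their",
           "his", "her", "our", "your", "my")
  prep <- c("of", "in", "on", "at", "by", "for", "with", "from", "to",
            "into", "onto", "across", "during", "against", "between",
            "under", "over", "within", "without", "through", "via",
            "among", "upon", "about", "as", "like")
  conj <- c("and", "or", "but", "nor", "so", "yet", "if", "than",
            "because", "while", "although", "whereas", "when", "where",
            "which", "who", "whose", "whom")
  pron <- c("it", "he", "she", "they", "we", "you", "i", "them", "him",
            "us", "me", "itself", "themselves")
  other <- c(det, prep, conj, pron)
  verb <- c("is", "are", "was", "were", "be", "been", "being", "am",
            "has", "have", "had", "having", "do", "does", "did", "done",
            "can", "could", "will", "would", "may", "might", "shall",
            "should", "must")
  adv <- c("then", "now", "also", "not", "very", "often", "thus",
           "however", "therefore", "moreover", "furthermore", "here",
           "there", "only", "even", "still", "already", "again",
           "together", "well", "further", "strongly", "highly")
  list(other = other, verb = verb, adv = adv)
})

# stems of verbs common in regulatory-genomics prose; a token whose stem is
# here (and that escaped the noun/adjective suffix rules) is tagged VERB
.verb_stems <- c(
  "induc", "activ", "repress", "regul", "upregul", "downregul", "inhibit",
  "express", "encod", "bind", "bound", "transcrib", "suppress", "stimul",
  "enhanc", "reduc", "increas", "decreas", "promot", "mediat", "requir",
  "produc", "respond", "protect", "control", "affect", "modul", "interact",
  "grow", "divid", "occur", "show", "suggest", "indic", "reveal", "assist",
  "involv", "contain", "includ", "depend", "lead", "result", "caus",
  "prevent", "confer", "block", "trigger", "detect", "observ", "identifi"
)

#' Default rule-based part-of-speech tagger
#'
#' Assigns one of five coarse tags per token: closed-class function words
#' map to OTHER/VERB/ADV from fixed lists; `-ly` gives ADV; nominal
#' suffixes (`-tion`, `-ment`, `-ness`, `-ity`, `-ance/-ence`, `-ism`,
#' `-ase`, ...) give NOUN; adjectival suffixes (`-ous`, `-ive`, `-able`,
#' `-al`, `-ic`, ...) give ADJ; tokens whose stem matches a list of verbs
#' common in regulatory-genomics prose give VERB; mixed-case or digit-bearing
#' symbols (gene/protein names such as "OxyR", "katG") give NOUN; a plain
#' plural falls back to NOUN; everything else is OTHER.
#'
#' @param surface,stems character vectors of equal length.
#' @return character vector of tags.
#' @export
default_pos_tagger <- function(surface, stems) {
  n <- length(surface)
  out <- rep("OTHER", n)
  if (!n) return(out)
  lower <- tolower(surface)
  alpha <- grepl("^[A-Za-z][A-Za-z-]*$", surface)

  out[lower %in% .closed_class$other] <- "OTHER"
  done <- lower %in% unlist(.closed_class)
  out[lower %in% .closed_class$verb] <- "VERB"
  out[lower %in% .closed_class$adv] <- "ADV"

  todo <- alpha & !done
  rule <- function(pattern) todo & grepl(pattern, lower, perl = TRUE)

  hit <- rule("[a-z]ly$")
  out[hit] <- "ADV"; todo <- todo & !hit
  hit <- rule("(tion|sion|ment|ness|ity|ance|ence|ism|ist|ase|ome|osis)s?$")
  out[hit] <- "NOUN"; todo <- todo & !hit
  hit <- rule("(ous|ive|able|ible|ful|less|ic|ical|ary|al)$")
  out[hit] <- "ADJ"; todo <- todo & !hit
  hit <- todo & stems %in% .verb_stems
  out[hit] <- "VERB"; todo <- todo & !hit
  # gene/protein-style symbols: internal capitals or digits
  hit <- todo & grepl("^[A-Za-z].*[A-Z0-9]", surface) & grepl("[A-Za-z]", surface)
  out[hit] <- "NOUN"; todo <- todo & !hit
  # residual plain plurals are most often nouns
  hit <- rule("[a-z]{3,}s$")
  out[hit] <- "NOUN"
  out
}

#' Tag tokens with coarse part-of-speech labels
#'
#' @param tokens a token tibble with `surface` (and, for the default
#'   tagger, `stem`) columns.
#' @param tagger a vectorized function `(surface, stems) -> tags`; tags
#'   must come from `NOUN`, `VERB`, `ADJ`, `ADV`, `OTHER`.
#' @return the token tibble with a `pos` column.
#' @export
pos_tag <- function(tokens, tagger = default_pos_tagger) {
  stems <- if ("stem" %in% names(tokens)) tokens$stem else stem_or_empty(tokens$surface)
  tags <- tagger(tokens$surface, stems)
  if (nrow(tokens) && !all(tags %in% .pos_labels)) {
    stop("tagger produced labels outside the coarse set: ",
         paste(setdiff(unique(tags), .pos_labels), collapse = ", "))
  }
  tokens$pos <- tags
  tokens
}

stem_or_empty <- function(x) if (length(x)) stem(x) else character(0)
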
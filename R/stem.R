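# Porter suffix-stripping stemmer (the classic 1980 rule cascade).
# Implemented here because downstream components (sentence vectors, lexicon
# matching, disambiguation features) need a deterministic normalizer with no
# external model. Operates on lower-cased ASCII words; tokens containing
# non-letters are only lower-cased.

.vowels <- c("a", "e", "i", "o", "u")

# consonant/vowel flags for a letter vector; "y" is a vowel when preceded by
# a consonant, a consonant otherwise (including word-initially)
.cons_flags <- function(letters) {
  n <- length(letters)
  flags <- logical(n)
  for (i in seq_len(n)) {
    ch <- letters[i]
    if (ch %in% .vowels) {
      flags[i] <- FALSE
    } else if (ch == "y") {
      flags[i] <- if (i == 1L) TRUE else !flags[i - 1L]
    } else {
      flags[i] <- TRUE
    }
  }
  flags
}

# the measure m: number of vowel->consonant transitions in [C](VC)^m[V]
.measure <- function(stem) {
  if (!nzchar(stem)) return(0L)
  f <- .cons_flags(strsplit(stem, "", fixed = TRUE)[[1]])
  sum(f[-1] & !f[-length(f)])
}

.has_vowel <- function(stem) {
  if (!nzchar(stem)) return(FALSE)
  any(!.cons_flags(strsplit(stem, "", fixed = TRUE)[[1]]))
}

.ends_double_cons <- function(stem) {
  n <- nchar(stem)
  if (n < 2L) return(FALSE)
  a <- substr(stem, n - 1L, n - 1L)
  b <- substr(stem, n, n)
  if (a != b) return(FALSE)
  f <- .cons_flags(strsplit(stem, "", fixed = TRUE)[[1]])
  f[n]
}

# *o: stem ends consonant-vowel-consonant where the final consonant is not
# w, x or y
.ends_cvc <- function(stem) {
  n <- nchar(stem)
  if (n < 3L) return(FALSE)
  f <- .cons_flags(strsplit(stem, "", fixed = TRUE)[[1]])
  last <- substr(stem, n, n)
  f[n] && !f[n - 1L] && f[n - 2L] && !(last %in% c("w", "x", "y"))
}

.ends_with <- function(w, suf) {
  nw <- nchar(w)
  ns <- nchar(suf)
  nw >= ns && substr(w, nw - ns + 1L, nw) == suf
}

.chop <- function(w, k) substr(w, 1L, nchar(w) - k)

# rule table steps: find the LONGEST matching suffix, then test the measure
# condition on the residual stem; no fall-through to shorter suffixes
.rule_step <- function(w, rules, min_m) {
  ord <- order(-nchar(names(rules)))
  for (i in ord) {
    suf <- names(rules)[i]
    if (.ends_with(w, suf)) {
      stem <- .chop(w, nchar(suf))
      if (.measure(stem) > min_m) {
        return(paste0(stem, rules[[i]]))
      }
      return(w)
    }
  }
  w
}

.step2_rules <- c(
  ational = "ate", tional = "tion", enci = "ence", anci = "ance",
  izer = "ize", abli = "able", alli = "al", entli = "ent", eli = "e",
  ousli = "ous", ization = "ize", ation = "ate", ator = "ate",
  alism = "al", iveness = "ive", fulness = "ful", ousness = "ous",
  aliti = "al", iviti = "ive", biliti = "ble"
)

.step3_rules <- c(
  icate = "ic", ative = "", alize = "al", iciti = "ic",
  ical = "ic", ful = "", ness = ""
)

.step4_suffixes <- c(
  "al", "ance", "ence", "er", "ic", "able", "ible", "ant", "ement",
  "ment", "ent", "ion", "ou", "ism", "ate", "iti", "ous", "ive", "ize"
)

.porter_one <- function(w) {
  if (nchar(w) <= 2L) return(w)

  # step 1a
  if (.ends_with(w, "sses")) {
    w <- .chop(w, 2L)
  } else if (.ends_with(w, "ies")) {
    w <- paste0(.chop(w, 3L), "i")
  } else if (!.ends_with(w, "ss") && .ends_with(w, "s")) {
    w <- .chop(w, 1L)
  }

  # step 1b
  if (.ends_with(w, "eed")) {
    if (.measure(.chop(w, 3L)) > 0L) w <- .chop(w, 1L)
  } else {
    fired <- FALSE
    if (.ends_with(w, "ed") && .has_vowel(.chop(w, 2L))) {
      w <- .chop(w, 2L)
      fired <- TRUE
    } else if (.ends_with(w, "ing") && .has_vowel(.chop(w, 3L))) {
      w <- .chop(w, 3L)
      fired <- TRUE
    }
    if (fired) {
      if (.ends_with(w, "at") || .ends_with(w, "bl") || .ends_with(w, "iz")) {
        w <- paste0(w, "e")
      } else if (.ends_double_cons(w) &&
                 !(substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z"))) {
        w <- .chop(w, 1L)
      } else if (.measure(w) == 1L && .ends_cvc(w)) {
        w <- paste0(w, "e")
      }
    }
  }

  # step 1c
  if (.ends_with(w, "y") && .has_vowel(.chop(w, 1L))) {
    w <- paste0(.chop(w, 1L), "i")
  }

  # steps 2 and 3
  w <- .rule_step(w, as.list(.step2_rules), 0L)
  w <- .rule_step(w, as.list(.step3_rules), 0L)

  # step 4: drop the longest matching suffix when m > 1; "ion" additionally
  # requires the stem to end in s or t
  ord <- order(-nchar(.step4_suffixes))
  for (i in ord) {
    suf <- .step4_suffixes[i]
    if (.ends_with(w, suf)) {
      stem <- .chop(w, nchar(suf))
      ok <- .measure(stem) > 1L
      if (suf == "ion") {
        last <- substr(stem, nchar(stem), nchar(stem))
        ok <- ok && last %in% c("s", "t")
      }
      if (ok) w <- stem
      break
    }
  }

  # step 5a
  if (.ends_with(w, "e")) {
    stem <- .chop(w, 1L)
    m <- .measure(stem)
    if (m > 1L || (m == 1L && !.ends_cvc(stem))) w <- stem
  }

  # step 5b
  if (.measure(w) > 1L && .ends_double_cons(w) && .ends_with(w, "l")) {
    w <- .chop(w, 1L)
  }

  w
}

#' Stem words with the Porter algorithm
#'
#' Reduces inflected English words to a common stem so that, for example,
#' "activates", "activated" and "activation" all collapse to `"activ"`.
#' This is the normalization used throughout the package: for sentence
#' vectors (it lowers the dimensionality of the bag-of-words space by
#' collapsing words sharing a lexeme), for lexicon matching, and for
#' disambiguation context features.
#'
#' Output is always lower-cased. Tokens containing characters other than
#' ASCII letters (digits, hyphens, punctuation) are returned lower-cased but
#' otherwise untouched, since the suffix rules are defined for plain words
#' only. The rule cascade is applied repeatedly until the word stops
#' changing, so the function is deterministic and idempotent
#' (`stem(stem(w)) == stem(w)`) — a property the downstream normalization
#' keys rely on, and which a single pass of the cascade does not guarantee
#' (a single pass maps "agreed" to "agre", and "agre" to "agr"; the
#' fixpoint is "agr"). For almost all words the first pass is already
#' stable and the output equals the classic single-pass stem.
#'
#' @param words character vector of words.
#' @return character vector of stems, same length as `words`.
#' @examples
#' stem(c("activation", "activates", "induces", "oxyR"))
#' @export
stem <- function(words) {
  if (length(words) == 0L) return(character(0))
  stopifnot(is.character(words), all(nzchar(words)))
  lw <- tolower(words)
  pure <- grepl("^[a-z]+$", lw)
  out <- lw
  if (any(pure)) {
    uniq <- unique(lw[pure])
    stems <- vapply(uniq, function(w) {
      repeat {
        nxt <- .porter_one(w)
        if (nxt == w) return(w)
        w <- nxt
      }
    }, character(1), USE.NAMES = TRUE)
    out[pure] <- unname(stems[lw[pure]])
  }
  out
}
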
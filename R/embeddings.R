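# Dense word vectors in the whitespace-separated text format used by
# pre-trained embedding distributions: optionally a "vocab_size dim" header
# line, then one "word f1 ... fd" row per word.

#' Construct a word-vector table
#' @param mat numeric matrix, one row per word, rownames = words.
#' @return an object of class `word_vectors`.
#' @export
word_vectors <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat), ncol(mat) > 0,
            !is.null(rownames(mat)))
  structure(list(d = ncol(mat), vectors = mat), class = "word_vectors")
}

#' @export
print.word_vectors <- function(x, ...) {
  cat(sprintf("<word_vectors> %d words, dimension %d\n",
              nrow(x$vectors), x$d))
  invisible(x)
}

#' Read word vectors from text
#'
#' Accepts an optional first line `"<vocab_size> <d>"`; every remaining
#' line is a word followed by `d` whitespace-separated floats. Rows whose
#' dimension disagrees raise an error at load time.
#'
#' @param path vector file.
#' @return a `word_vectors` object.
#' @export
read_word_vectors <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty word-vector file: ", path)
  first <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  if (length(first) == 2L && !anyNA(suppressWarnings(as.numeric(first)))) {
    lines <- lines[-1]
  }
  parts <- strsplit(trimws(lines), "[ \t]+")
  words <- vapply(parts, `[[`, "", 1L)
  d <- length(parts[[1]]) - 1L
  if (d < 1L) stop("word-vector rows need at least one value")
  bad <- which(vapply(parts, length, integer(1)) != d + 1L)
  if (length(bad)) {
    stop("dimension mismatch in word-vector file at data row ", bad[1],
         " (word '", words[bad[1]], "')")
  }
  mat <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(d)))
  if (anyNA(mat)) stop("non-numeric value in word-vector file: ", path)
  rownames(mat) <- words
  word_vectors(mat)
}

#' Write word vectors to text (with a header line)
#' @param vectors a `word_vectors` object.
#' @param path output file.
#' @export
write_word_vectors <- function(vectors, path) {
  mat <- vectors$vectors
  rows <- vapply(seq_len(nrow(mat)), function(i) {
    paste(rownames(mat)[i],
          paste(formatC(mat[i, ], format = "g", digits = 8), collapse = " "))
  }, character(1))
  writeLines(c(paste(nrow(mat), ncol(mat)), rows), path, useBytes = FALSE)
  invisible(path)
}

#' Embedding similarity between two words
#'
#' Cosine of the two dense vectors, clamped from \[-1, 1\] to \[0, 1\] via
#' `max(0, cos)`: a negative cosine carries no similarity signal here.
#' A word missing from the vocabulary yields 0 with attribute `oov = TRUE`.
#'
#' @param vectors a `word_vectors` object.
#' @param w1,w2 words.
#' @return similarity in \[0, 1\] with an `oov` attribute.
#' @export
embedding_word_sim <- function(vectors, w1, w2) {
  mat <- vectors$vectors
  if (!(w1 %in% rownames(mat)) || !(w2 %in% rownames(mat))) {
    return(structure(0, oov = TRUE))
  }
  a <- mat[w1, ]
  b <- mat[w2, ]
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(structure(0, oov = FALSE))
  structure(max(0, sum(a * b) / (na * nb)), oov = FALSE)
}
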
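test_that("sentence vectors count normalized content words", {
  cfg <- sim_config()
  v <- vectorize("Activated OxyR then induces transcription", cfg)
  expect_identical(v, c(activ = 1L, induc = 1L, oxyr = 1L, then = 1L,
                        transcript = 1L))
  expect_length(vectorize("", cfg), 0L)
  expect_length(vectorize(", . ; 123", cfg), 0L) # nothing alphabetic

  # counts equal a brute-force tally
  withr::with_seed(19, {
    for (trial in 1:20) {
      text <- random_sentence_text()
      v <- vectorize(text, cfg)
      words <- stem(tolower(unlist(strsplit(text, " ", fixed = TRUE))))
      tally <- table(words)
      expect_identical(v[order(names(v))],
                       stats::setNames(as.integer(tally), names(tally)))
    }
  })

  # stop words and stemming are honored
  cfg2 <- sim_config(stopwords = c("the", "of"), stemming = FALSE)
  v2 <- vectorize("The genes of the genes", cfg2)
  expect_identical(v2, c(genes = 2L))
})

test_that("cosine matches hand values and a dot-product oracle", {
  expect_equal(cosine(c(a = 2L, b = 1L), c(a = 2L, b = 1L)), 1)
  expect_equal(cosine(c(a = 1L), c(b = 1L)), 0)
  expect_equal(cosine(c(a = 1L, b = 1L), c(a = 1L, c = 1L)), 0.5)
  expect_equal(cosine(stats::setNames(integer(0), character(0)), c(a = 1L)), 0)
  withr::with_seed(29, {
    for (trial in 1:300) {
      v1 <- random_sparse_vector()
      v2 <- random_sparse_vector()
      expect_equal(cosine(v1, v2), oracle_cosine(v1, v2), tolerance = 1e-12)
      expect_equal(cosine(v1, v2), cosine(v2, v1))
      expect_gte(cosine(v1, v2), 0)
      expect_lte(cosine(v1, v2), 1 + 1e-12)
    }
  })
})

lin_fixture <- function() {
  concepts <- tibble::tibble(
    concept = c("root", "Z", "W", "X", "Y"),
    parent = c("", "root", "root", "Z", "Z"),
    freq = c(0, 0, 50, 25, 25))
  word_map <- tibble::tibble(
    word = c("wx", "wy", "wz", "ww"),
    concept = c("X", "Y", "Z", "W"))
  taxonomy(concepts, word_map)
}

test_that("Lin similarity reproduces the closed-form fixture", {
  tax <- lin_fixture()
  expect_equal(information_content(tax, "root"), 0)
  expect_equal(information_content(tax, "Z"), log(2), tolerance = 1e-12)
  expect_equal(information_content(tax, "X"), log(4), tolerance = 1e-12)
  # p(X) = p(Y) = 0.25 under LCS Z with p(Z) = 0.5:
  # 2 log 2 / (log 4 + log 4) = 0.5
  expect_equal(as.numeric(lin_similarity(tax, "wx", "wy")), 0.5,
               tolerance = 1e-12)
  expect_equal(as.numeric(lin_similarity(tax, "wx", "wx")), 1)
  # LCS at the root scores zero
  expect_equal(as.numeric(lin_similarity(tax, "wx", "ww")), 0)
  oov <- lin_similarity(tax, "wx", "absent")
  expect_equal(as.numeric(oov), 0)
  expect_true(attr(oov, "oov"))
  # IC never decreases from root to leaf
  expect_true(information_content(tax, "root") <=
                information_content(tax, "Z"))
  expect_true(information_content(tax, "Z") <=
                information_content(tax, "X"))
})

test_that("Lin similarity increases with the information content of the subsumer", {
  # chain taxonomies: same leaf ICs, deeper (higher-IC) subsumer
  build <- function(subsumer_freq) {
    taxonomy(
      tibble::tibble(
        concept = c("root", "mid", "other", "X", "Y"),
        parent = c("", "root", "root", "mid", "mid"),
        freq = c(0, subsumer_freq, 400 - subsumer_freq - 50 - 50, 50, 50)),
      tibble::tibble(word = c("wx", "wy"), concept = c("X", "Y")))
  }
  sims <- vapply(c(200, 100, 0), function(f) {
    as.numeric(lin_similarity(build(f), "wx", "wy"))
  }, numeric(1))
  # lowering mid's own mass raises IC(mid) while IC(X), IC(Y) fixed
  expect_true(all(diff(sims) > 0))
})

test_that("embedding similarity clamps negative cosines and flags OOV", {
  mat <- rbind(a = c(1, 0), b = c(0, 1), c = c(-1, 0), d = c(2, 0))
  vecs <- word_vectors(mat)
  expect_equal(as.numeric(embedding_word_sim(vecs, "a", "a")), 1)
  expect_equal(as.numeric(embedding_word_sim(vecs, "a", "b")), 0)
  expect_equal(as.numeric(embedding_word_sim(vecs, "a", "c")), 0) # clamped
  expect_equal(as.numeric(embedding_word_sim(vecs, "a", "d")), 1)
  oov <- embedding_word_sim(vecs, "a", "zz")
  expect_equal(as.numeric(oov), 0)
  expect_true(attr(oov, "oov"))
})

test_that("word vector files round-trip and reject ragged rows", {
  mat <- matrix(rnorm(12), nrow = 3,
                dimnames = list(c("wa", "wb", "wc"), NULL))
  p <- withr::local_tempfile(fileext = ".txt")
  write_word_vectors(word_vectors(mat), p)
  back <- read_word_vectors(p)
  expect_equal(back$d, 4L)
  expect_equal(back$vectors, mat, tolerance = 1e-6)

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("wa 1 2 3", "wb 1 2"), bad)
  expect_error(read_word_vectors(bad), "dimension mismatch.*wb")
})

test_that("aligned word scores average directional best matches", {
  sims <- c("a1 b1" = 0.8, "a1 b2" = 0.2, "a2 b1" = 0.1, "a2 b2" = 0.4)
  fn <- function(x, y) {
    key <- paste(sort(c(x, y)), collapse = " ")
    if (key %in% names(sims)) sims[[key]] else 0
  }
  # both directions give (0.8 + 0.4) / 2 = 0.6
  expect_equal(aligned_word_score(c("a1", "a2"), c("b1", "b2"), fn), 0.6)
  expect_equal(aligned_word_score(c("w", "v"), c("w", "v"), fn), 1) # identity
  expect_equal(aligned_word_score(character(0), c("b1"), fn), 0)
  expect_equal(aligned_word_score(c("a1"), c("zz"), function(x, y) 0), 0)
})

test_that("combined similarity is a weighted mean scaled to 0-5", {
  cfg <- sim_config()
  s <- toy_sentence("OxyR induces katG expression")
  expect_equal(combined_similarity(s, s, cfg)$scaled, 5)

  # weight reduction: single enabled metric equals 5 * cosine
  t1 <- "OxyR induces katG"
  t2 <- "OxyR represses oxyS"
  sc <- combined_similarity(t1, t2, cfg)
  expect_equal(sc$scaled,
               5 * cosine(vectorize(t1, cfg), vectorize(t2, cfg)))

  # identical sentences hit 5 under any weighting, including metrics
  # that need resources
  tax <- lin_fixture()
  vecs <- word_vectors(rbind(wx = c(1, 0), wy = c(0, 1)))
  cfg3 <- sim_config(weights = c(vsm = 1, taxonomy = 1, embedding = 1),
                     taxonomy = tax, vectors = vecs)
  expect_equal(combined_similarity("wx wy novel", "wx wy novel", cfg3)$scaled, 5)
  breakdown <- combined_similarity("wx", "wy", cfg3)
  expect_length(breakdown$metrics, 3L)
  expect_equal(breakdown$combined,
               sum(breakdown$metrics) / 3, tolerance = 1e-12)

  expect_error(sim_config(weights = c(vsm = 0, taxonomy = 0, embedding = 0)),
               "all metric weights are zero")
  expect_error(sim_config(weights = c(vsm = 1, taxonomy = 1)), "taxonomy")
})

test_that("stemming collapses inflection into higher VSM similarity", {
  with_stem <- sim_config(stemming = TRUE)
  without <- sim_config(stemming = FALSE)
  t1 <- "X activates Y"
  t2 <- "activation of Y by X"
  expect_gt(combined_similarity(t1, t2, with_stem)$metrics[["vsm"]],
            combined_similarity(t1, t2, without)$metrics[["vsm"]])
})

test_that("topical sentences outscore an off-topic distractor", {
  cfg <- sim_config(stopwords = default_stopwords())
  a <- paste("The oxidized form of OxyR is a transcriptional activator of a",
             "multitude of genes that assist in protecting the cell from",
             "oxidative damage.")
  b <- paste("Activated OxyR then induces transcription of a set of",
             "antioxidant genes, including katG, ahpCF and oxyS.")
  distractor <- "The orchestra rehearsed a symphony before the winter concert."
  expect_gt(combined_similarity(a, b, cfg)$scaled,
            combined_similarity(a, distractor, cfg)$scaled)
})

test_that("similarity is bounded and symmetric on random pairs", {
  cfg <- sim_config()
  withr::with_seed(37, {
    for (trial in 1:200) {
      t1 <- random_sentence_text()
      t2 <- random_sentence_text()
      s12 <- combined_similarity(t1, t2, cfg)
      s21 <- combined_similarity(t2, t1, cfg)
      expect_equal(s12$scaled, s21$scaled, tolerance = 1e-12)
      expect_gte(s12$scaled, 0)
      expect_lte(s12$scaled, 5 + 1e-9)
      expect_true(all(s12$metrics >= 0 & s12$metrics <= 1 + 1e-12))
    }
  })
})

test_that("pearson matches closed-form cases and rejects degenerate input", {
  xs <- c(0.5, 1.5, 4)
  expect_equal(pearson(xs, 2 * xs + 1), 1)
  expect_equal(pearson(xs, -xs), -1)
  expect_equal(pearson(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(pearson(c(1, 2), c(1, 2, 3)), "unequal")
  expect_error(pearson(numeric(0), numeric(0)), "at least 2")
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("the evaluation harness recovers known correlations", {
  cfg <- sim_config()
  pairs <- gen_gold_pairs(fixture_spec(seed = 11, noise_sigma = 0,
                                       n_gold_pairs = 60))
  self <- evaluate_sts(pairs, cfg)
  expect_equal(self$pearson_r, 1)
  expect_equal(self$n, 60L)

  inverted <- pairs
  inverted$gold <- 5 - vapply(seq_len(nrow(pairs)), function(i) {
    combined_similarity(pairs$text1[i], pairs$text2[i], cfg)$scaled
  }, numeric(1))
  expect_equal(evaluate_sts(inverted, cfg)$pearson_r, -1)

  out <- withr::local_tempfile(fileext = ".tsv")
  rep <- evaluate_sts(pairs[1:10, ], cfg, out_tsv = out)
  tab <- utils::read.delim(out)
  expect_equal(nrow(tab), 10L)
  expect_equal(tab$system, rep$scores$system, tolerance = 1e-9)
})
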
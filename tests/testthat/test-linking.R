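# small corpora for linking tests
linking_corpus <- function(seed, n_docs = 2, sentences_per_doc = 3) {
  gen_corpus(fixture_spec(seed = seed, n_docs = n_docs,
                          sentences_per_doc = sentences_per_doc))$corpus
}

oxyr_world <- function() {
  corpus <- preprocess_corpus(read_corpus(extdata("oxyr_linking_corpus.tsv"),
                                          "tsv"))
  cfg_sim <- sim_config(stopwords = default_stopwords())
  sents <- corpus_sentences(corpus)
  ids <- vapply(sents, `[[`, "", "doc_id")
  scores <- c()
  topical <- c()
  for (i in seq_len(length(sents) - 1L)) {
    for (j in seq(i + 1L, length(sents))) {
      scores <- c(scores, combined_similarity(sents[[i]], sents[[j]],
                                              cfg_sim)$scaled)
      topical <- c(topical, grepl("^ox", ids[i]) && grepl("^ox", ids[j]))
    }
  }
  # threshold derived from the fixture's own score distribution
  threshold <- (min(scores[topical]) + max(c(scores[!topical], 0))) / 2
  list(corpus = corpus, sim = cfg_sim, threshold = threshold,
       scores = scores, topical = topical)
}

test_that("topical sentences link mutually and distractors stay unlinked", {
  w <- oxyr_world()
  expect_gt(min(w$scores[w$topical]), max(w$scores[!w$topical]))
  graph <- build_links(w$corpus, link_config(threshold = w$threshold,
                                             top_k = 10, sim = w$sim))
  expect_equal(nrow(graph$links), 3L) # the three topical pairs
  expect_setequal(paste(graph$links$doc_a, graph$links$doc_b),
                  c("ox1 ox2", "ox1 ox3", "ox2 ox3"))
  expect_true(all(graph$links$cross_document))
  nb <- neighbors(graph, "ox1", "ox1:s0")
  expect_equal(nb$cross_document$doc_id, c("ox2", "ox3")) # ranked by score
  expect_equal(nrow(nb$same_document), 0L)
})

test_that("degenerate corpora produce empty graphs, not errors", {
  single <- preprocess_corpus(as_corpus(list(lit_document("d1", "only one."))))
  g <- build_links(single, link_config(threshold = 0, top_k = 3))
  expect_equal(nrow(g$links), 0L)
  expect_error(build_links(structure(list(), class = "lit_corpus"),
                           link_config()), "empty corpus")
  un <- neighbors(g, "d1", "d1:s0")
  expect_equal(nrow(un$same_document), 0L)
  expect_equal(nrow(un$cross_document), 0L)
  expect_error(neighbors(g, "d1", "d1:s9"), "unknown sentence")
})

test_that("the graph equals an exhaustive pairwise recomputation", {
  cfg <- link_config(threshold = 1.0, top_k = 50,
                     sim = sim_config(stopwords = default_stopwords()))
  corpus <- linking_corpus(seed = 14, n_docs = 5, sentences_per_doc = 6)
  graph <- build_links(corpus, cfg)
  sents <- corpus_sentences(corpus)
  # independent double loop over sentence pairs
  want <- list()
  for (i in seq_len(length(sents) - 1L)) {
    for (j in seq(i + 1L, length(sents))) {
      s <- combined_similarity(sents[[i]], sents[[j]], cfg$sim)$scaled
      if (s >= cfg$threshold) {
        a <- c(sents[[i]]$doc_id, sents[[i]]$sent_id)
        b <- c(sents[[j]]$doc_id, sents[[j]]$sent_id)
        if (paste(a, collapse = "\r") > paste(b, collapse = "\r")) {
          tmp <- a; a <- b; b <- tmp
        }
        want[[length(want) + 1L]] <- data.frame(
          doc_a = a[1], sent_a = a[2], doc_b = b[1], sent_b = b[2],
          score = s, stringsAsFactors = FALSE)
      }
    }
  }
  want <- do.call(rbind, want)
  want <- want[order(want$doc_a, want$sent_a, want$doc_b, want$sent_b), ]
  expect_equal(nrow(graph$candidates), nrow(want))
  expect_equal(graph$candidates$score, want$score, tolerance = 1e-12)
  expect_equal(graph$candidates$sent_a, want$sent_a)
  expect_equal(graph$candidates$sent_b, want$sent_b)
  # top_k = 50 keeps everything here
  expect_equal(nrow(graph$links), nrow(graph$candidates))
})

test_that("incremental addition equals a batch rebuild", {
  cfg <- link_config(threshold = 1.0, top_k = 3,
                     sim = sim_config(stopwords = default_stopwords()))
  for (seed in c(21, 22, 23, 24, 25)) {
    full <- linking_corpus(seed = seed, n_docs = 3, sentences_per_doc = 4)
    base <- as_corpus(full[1:2], corpus_id = "synthetic")
    g_inc <- add_document(build_links(base, cfg), base, full[[3]], cfg)
    g_batch <- build_links(as_corpus(full[1:3], corpus_id = "synthetic"), cfg)
    expect_equal(g_inc$links, g_batch$links)
    expect_equal(g_inc$candidates, g_batch$candidates)
    expect_equal(g_inc$sentences, g_batch$sentences)
  }
  # degenerate additions
  corpus <- linking_corpus(seed = 26)
  g <- build_links(corpus, cfg)
  expect_error(add_document(g, corpus, corpus[[1]], cfg), "duplicate doc_id")
  empty_doc <- preprocess_document(lit_document("fresh", " "))
  g2 <- add_document(g, corpus, empty_doc, cfg)
  expect_equal(g2$links, g$links)
})

test_that("graph symmetry and threshold monotonicity hold", {
  corpus <- linking_corpus(seed = 27, n_docs = 3, sentences_per_doc = 4)
  sim <- sim_config(stopwords = default_stopwords())
  g1 <- build_links(corpus, link_config(threshold = 0.5, top_k = 4, sim = sim))
  # symmetry: y in neighbors(x) <=> x in neighbors(y)
  for (k in seq_len(min(nrow(g1$links), 20L))) {
    a <- c(g1$links$doc_a[k], g1$links$sent_a[k])
    b <- c(g1$links$doc_b[k], g1$links$sent_b[k])
    nb_a <- neighbors(g1, a[1], a[2])
    nb_b <- neighbors(g1, b[1], b[2])
    all_a <- rbind(nb_a$same_document, nb_a$cross_document)
    all_b <- rbind(nb_b$same_document, nb_b$cross_document)
    expect_true(any(all_a$doc_id == b[1] & all_a$sent_id == b[2]))
    expect_true(any(all_b$doc_id == a[1] & all_b$sent_id == a[2]))
  }
  # raising the threshold never adds links
  thresholds <- c(0.5, 1.5, 2.5, 3.5, 4.5)
  sizes <- vapply(thresholds, function(th) {
    nrow(build_links(corpus, link_config(threshold = th, top_k = 4,
                                         sim = sim))$links)
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
  keys <- lapply(thresholds, function(th) {
    g <- build_links(corpus, link_config(threshold = th, top_k = 100,
                                         sim = sim))
    paste(g$links$doc_a, g$links$sent_a, g$links$doc_b, g$links$sent_b)
  })
  for (k in seq_len(length(keys) - 1L)) {
    expect_true(all(keys[[k + 1L]] %in% keys[[k]]))
  }
})

test_that("neighbor ranking agrees with re-sorting the raw link list", {
  corpus <- linking_corpus(seed = 28, n_docs = 4, sentences_per_doc = 4)
  g <- build_links(corpus, link_config(threshold = 0.5, top_k = 5,
                                       sim = sim_config()))
  target <- c(g$links$doc_a[1], g$links$sent_a[1])
  nb <- neighbors(g, target[1], target[2])
  combined <- rbind(nb$same_document, nb$cross_document)
  # scores must be the sorted multiset of this sentence's link scores
  mine <- g$links$score[(g$links$doc_a == target[1] &
                           g$links$sent_a == target[2]) |
                          (g$links$doc_b == target[1] &
                             g$links$sent_b == target[2])]
  expect_equal(sort(combined$score, decreasing = TRUE),
               sort(mine, decreasing = TRUE))
  expect_true(!is.unsorted(rev(nb$cross_document$score)))
})

test_that("link graphs survive a JSON round trip", {
  corpus <- linking_corpus(seed = 30)
  cfg <- link_config(threshold = 1, top_k = 3,
                     sim = sim_config(stopwords = c("the", "of")))
  g <- build_links(corpus, cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_link_graph(g, path)
  back <- read_link_graph(path)
  expect_equal(back$links$score, g$links$score, tolerance = 1e-12)
  expect_equal(back$links$doc_a, g$links$doc_a)
  expect_equal(back$config$threshold, cfg$threshold)
  expect_equal(back$config$top_k, cfg$top_k)
  expect_equal(back$config$sim$stopwords, c("the", "of"))
  expect_equal(back$sentences, g$sentences)
  # a reloaded graph can still be updated incrementally
  extra <- preprocess_document(lit_document("zzz", "totally unrelated words."))
  g2 <- add_document(back, corpus, extra, back$config)
  expect_equal(nrow(g2$sentences), nrow(g$sentences) + 1L)
})
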
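# A compact two-document world used by several cases: the surface "abcX"
# is ambiguous between a TF sense (E-TF) and a gene sense (E-GENE); each
# training document uses one sense amid sense-specific context words.
toy_disambig_world <- function() {
  dict <- tibble::tibble(
    term = c("abcX", "abcX"),
    entity_id = c("E-GENE", "E-TF"),
    entity_type = c("GENE", "TF"),
    source = "db")
  docs <- list(
    lit_document("train1", "the abcX protein senses peroxide stress"),
    lit_document("train2", "the abcX operon encodes transport machinery")
  )
  corpus <- preprocess_corpus(as_corpus(docs))
  links <- tibble::tibble(doc_id = c("train1", "train2"),
                          entity_id = c("E-TF", "E-GENE"))
  list(corpus = corpus, dict = dict, links = links,
       matcher = compile_dictionary(dict))
}

test_that("feature bags contain window stems and co-mention types", {
  dict <- tibble::tibble(
    term = c("OxyR", "katG"),
    entity_id = c("TF-OXYR", "G-KATG"),
    entity_type = c("TF", "GENE"), source = "db")
  doc <- preprocess_document(lit_document(
    "d1", "Activated OxyR then induces transcription of katG. Other genes respond."))
  mentions <- annotate(doc, compile_dictionary(dict))
  oxyr <- mentions[mentions$matched_surface == "OxyR", ]
  feats <- extract_features(oxyr, doc$sentences[[1]], mentions, window = 5L)
  expect_true(all(c("w:induc", "w:transcript", "w:activ", "st:GENE") %in% feats))
  expect_false(any(feats == "w:oxyr")) # mention tokens excluded

  # a mention alone in a one-word document has an empty bag
  dict1 <- tibble::tibble(term = "solo", entity_id = "E", entity_type = "X",
                          source = "db")
  doc1 <- preprocess_document(lit_document("one", "solo"))
  m1 <- annotate(doc1, compile_dictionary(dict1))
  expect_length(extract_features(m1, doc1$sentences[[1]], m1), 0L)

  # renaming the document does not change the features
  doc_b <- doc
  doc_b$doc_id <- "renamed"
  doc_b$sentences <- lapply(doc_b$sentences, function(s) {
    s$doc_id <- "renamed"
    s
  })
  mentions_b <- mentions
  mentions_b$doc_id <- "renamed"
  feats_b <- extract_features(mentions_b[mentions_b$matched_surface == "OxyR", ],
                              doc_b$sentences[[1]], mentions_b, window = 5L)
  expect_identical(sort(feats), sort(feats_b))
})

test_that("the posterior matches a hand-computed naive Bayes calculation", {
  world <- toy_disambig_world()
  model <- train_distant(world$corpus, world$links, world$matcher, alpha = 1)

  # test mention in a fresh sentence sharing one TF-context word
  doc <- preprocess_document(lit_document("test1", "the abcX factor senses light"))
  mentions <- annotate(doc, world$matcher)
  feats <- extract_features(mentions, doc$sentences[[1]], mentions)
  res <- disambiguate(feats, mentions$candidate_ids[[1]], model)

  # by hand: one instance per class; the training bags are the window
  # stems around abcX. Priors 1/2 each. With Laplace alpha = 1 and
  # vocabulary V, P(f | class) = (count + 1) / (total + V).
  bag_tf <- c("w:the", "w:protein", "w:sens", "w:peroxid", "w:stress")
  bag_gene <- c("w:the", "w:operon", "w:encod", "w:transport", "w:machineri")
  vocab <- sort(unique(c(bag_tf, bag_gene)))
  test_bag <- intersect(c("w:the", "w:factor", "w:sens", "w:light"), vocab)
  loglik <- function(bag) {
    sum(vapply(test_bag, function(f) {
      log((sum(bag == f) + 1) / (length(bag) + length(vocab)))
    }, numeric(1))) + log(0.5)
  }
  lp <- c(`E-GENE` = loglik(bag_gene), `E-TF` = loglik(bag_tf))
  post <- exp(lp - max(lp))
  post <- post / sum(post)
  expect_equal(unname(res$posterior[c("E-GENE", "E-TF")]), unname(post),
               tolerance = 1e-12)
  expect_equal(res$entity_id, "E-TF") # "sens" is TF-context evidence
  expect_gt(res$score, 0.5)
  expect_equal(sum(res$posterior), 1)
})

test_that("training validates its inputs", {
  world <- toy_disambig_world()
  bad_links <- tibble::tibble(doc_id = "ghost", entity_id = "E-TF")
  expect_error(train_distant(world$corpus, bad_links, world$matcher),
               "absent doc_id.*ghost")
  no_hit <- tibble::tibble(doc_id = "train1", entity_id = "UNRELATED")
  expect_error(train_distant(world$corpus, no_hit, world$matcher),
               "zero training instances")
  expect_error(train_distant(world$corpus, world$links, world$matcher,
                             alpha = 0), "alpha")
})

test_that("disambiguation handles bypass, symmetry ties and unseen candidates", {
  world <- toy_disambig_world()
  model <- train_distant(world$corpus, world$links, world$matcher)

  single <- disambiguate(c("w:x"), "ONLY-ID", model)
  expect_equal(single$entity_id, "ONLY-ID")
  expect_equal(single$score, 1)

  # symmetric evidence: empty feature bag, equal priors -> tie broken
  # towards the lexicographically smaller id
  tie <- disambiguate(character(0), c("E-TF", "E-GENE"), model)
  expect_equal(unname(tie$posterior), c(0.5, 0.5))
  expect_equal(tie$entity_id, "E-GENE")

  unseen <- disambiguate(c("w:x"), c("Z2", "Z1"), model)
  expect_true(unseen$low_confidence)
  expect_equal(unseen$entity_id, "Z1")
  expect_equal(unname(unseen$posterior), c(0.5, 0.5))
})

test_that("separable synthetic contexts give high held-out accuracy", {
  fx <- gen_ambiguous_links(fixture_spec(seed = 7, n_docs = 50))
  res <- heldout_accuracy(fx)
  expect_gte(res$accuracy, 0.9)
  expect_gt(res$n_heldout_mentions, 10L)
})

test_that("models serialize deterministically and reload with identical predictions", {
  world <- toy_disambig_world()
  m1 <- train_distant(world$corpus, world$links, world$matcher)
  m2 <- train_distant(world$corpus, world$links, world$matcher)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_model(m1, p1)
  write_model(m2, p2)
  expect_identical(readLines(p1), readLines(p2))

  m3 <- read_model(p1)
  feats <- c("w:sens", "w:stress", "w:light")
  r_orig <- disambiguate(feats, c("E-GENE", "E-TF"), m1)
  r_load <- disambiguate(feats, c("E-GENE", "E-TF"), m3)
  expect_identical(r_orig$posterior, r_load$posterior)
  expect_identical(r_orig$entity_id, r_load$entity_id)
})
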
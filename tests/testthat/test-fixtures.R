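test_that("fixture generation is deterministic under the seed", {
  spec <- fixture_spec(seed = 13, n_docs = 4)
  g1 <- gen_corpus(spec)
  g2 <- gen_corpus(spec)
  expect_identical(vapply(g1$corpus, `[[`, "", "text"),
                   vapply(g2$corpus, `[[`, "", "text"))
  expect_identical(g1$dictionary, g2$dictionary)
  expect_identical(g1$mentions, g2$mentions)

  g3 <- gen_corpus(fixture_spec(seed = 14, n_docs = 4))
  expect_false(identical(vapply(g1$corpus, `[[`, "", "text"),
                         vapply(g3$corpus, `[[`, "", "text")))

  tv1 <- gen_taxonomy_and_vectors(spec)
  tv2 <- gen_taxonomy_and_vectors(spec)
  expect_identical(tv1$vectors$vectors, tv2$vectors$vectors)

  p1 <- gen_gold_pairs(spec)
  p2 <- gen_gold_pairs(spec)
  expect_identical(p1, p2)
})

test_that("annotation recovers exactly the planted mentions", {
  gen <- gen_corpus(fixture_spec(seed = 5))
  mentions <- annotate_corpus(gen$corpus, compile_dictionary(gen$dictionary))
  expect_equal(nrow(mentions), nrow(gen$mentions))
  expect_equal(mentions$doc_id, gen$mentions$doc_id)
  expect_equal(mentions$sent_id, gen$mentions$sent_id)
  expect_equal(mentions$char_start, gen$mentions$char_start)
  expect_equal(mentions$char_end, gen$mentions$char_end)
  expect_equal(mentions$matched_surface, gen$mentions$surface)
  expect_equal(mentions$resolved_id, gen$mentions$entity_id)
  expect_equal(mentions$entity_type, gen$mentions$entity_type)
})

test_that("same-topic sentences are more similar than cross-topic ones", {
  gen <- gen_corpus(fixture_spec(seed = 16, n_docs = 9))
  cfg <- sim_config(stopwords = default_stopwords())
  sents <- corpus_sentences(gen$corpus)
  vecs <- lapply(sents, vectorize, config = cfg)
  topic <- gen$topics$topic
  within <- c()
  across <- c()
  withr::with_seed(1, {
    idx <- sample(seq_along(sents), 40L)
    for (i in idx) {
      for (j in sample(seq_along(sents), 10L)) {
        if (i == j) next
        s <- cosine(vecs[[i]], vecs[[j]])
        if (topic[i] == topic[j]) within <- c(within, s)
        else across <- c(across, s)
      }
    }
  })
  expect_gt(mean(within), mean(across))
})

test_that("ambiguity fixtures are consistent and rate 0 disables training", {
  fx <- gen_ambiguous_links(fixture_spec(seed = 7, n_docs = 20))
  # links cover the training split only, and agree with planted senses
  expect_true(all(fx$links$doc_id %in% setdiff(unique(fx$senses$doc_id),
                                               fx$heldout$doc_id)))
  audit <- merge(fx$links, fx$senses, by = "doc_id")
  expect_true(all(audit$entity_id.x == audit$entity_id.y))
  # every ambiguous surface carries both senses in the dictionary
  amb_terms <- table(fx$dictionary$term)
  expect_true(any(amb_terms == 2L))

  fx0 <- gen_ambiguous_links(fixture_spec(seed = 7, n_docs = 10,
                                          ambiguity_rate = 0))
  expect_equal(nrow(fx0$links), 0L)
  expect_error(
    train_distant(fx0$corpus, fx0$links,
                  compile_dictionary(fx0$dictionary)),
    "zero training instances")
})

test_that("generated taxonomies and vectors satisfy their design anchors", {
  spec <- fixture_spec(seed = 20)
  tv <- gen_taxonomy_and_vectors(spec)
  expect_equal(information_content(tv$taxonomy, "c_root"), 0)
  expect_equal(as.numeric(lin_similarity(tv$taxonomy, "leftmark", "rightmark")),
               0.5, tolerance = 1e-12)
  expect_equal(tv$vectors$d, spec$dim)
  expect_equal(ncol(tv$vectors$vectors), 50L)

  # within-topic embedding cosine exceeds cross-topic; topic membership
  # comes from the taxonomy word map
  wm <- tv$taxonomy$word_map
  within <- c()
  across <- c()
  for (t1 in c("c_topic1", "c_topic2")) {
    w1 <- wm$word[wm$concept == t1][1:5]
    w2 <- wm$word[wm$concept == "c_topic3"][1:5]
    for (a in w1) {
      for (b in w1) {
        if (a != b) {
          within <- c(within, as.numeric(embedding_word_sim(tv$vectors, a, b)))
        }
      }
      for (b in w2) {
        across <- c(across, as.numeric(embedding_word_sim(tv$vectors, a, b)))
      }
    }
  }
  expect_gt(mean(within), mean(across))
})

test_that("gold pairs respect the clamp and the noise model", {
  pairs <- gen_gold_pairs(fixture_spec(seed = 11, noise_sigma = 0.3,
                                       n_gold_pairs = 200))
  expect_equal(nrow(pairs), 200L)
  expect_true(all(pairs$gold >= 0 & pairs$gold <= 5))
  r <- evaluate_sts(pairs, sim_config())$pearson_r
  expect_gte(r, 0.9)

  exact <- gen_gold_pairs(fixture_spec(seed = 11, noise_sigma = 0,
                                       n_gold_pairs = 50))
  expect_equal(evaluate_sts(exact, sim_config())$pearson_r, 1)
})

test_that("every generator round-trips through its external file format", {
  spec <- fixture_spec(seed = 3, n_docs = 3)
  gen <- gen_corpus(spec)
  dir <- withr::local_tempdir()

  # corpus TSV
  cp <- file.path(dir, "corpus.tsv")
  write_corpus_tsv(gen$corpus, cp)
  corpus2 <- read_corpus(cp, "tsv")
  expect_identical(vapply(corpus2, `[[`, "", "text"),
                   vapply(gen$corpus, `[[`, "", "text"))

  # dictionary TSV
  dp <- file.path(dir, "dict.tsv")
  write_dictionary(gen$dictionary, dp)
  expect_equal(read_dictionary(dp), gen$dictionary)

  # reference links TSV
  fx <- gen_ambiguous_links(fixture_spec(seed = 7, n_docs = 10))
  lp <- file.path(dir, "links.tsv")
  write_reference_links(fx$links, lp)
  expect_equal(read_reference_links(lp), fx$links)

  # keyword lexicon (line-oriented)
  lex <- lexicon("effect", c("activates", "represses"))
  xp <- file.path(dir, "effect.txt")
  write_lexicon(lex, xp)
  lex2 <- read_lexicon(xp, "effect")
  expect_identical(lex2$keys, lex$keys)

  # effect lexicon TSV
  ep <- file.path(dir, "effect.tsv")
  write_effect_lexicon(default_effect_lexicon(), ep)
  expect_equal(read_effect_lexicon(ep), default_effect_lexicon())

  # taxonomy + word map TSV
  tv <- gen_taxonomy_and_vectors(spec)
  tp <- file.path(dir, "concepts.tsv")
  wp <- file.path(dir, "words.tsv")
  write_taxonomy(tv$taxonomy, tp, wp)
  tax2 <- read_taxonomy(tp, wp)
  expect_equal(tax2$ic[order(names(tax2$ic))],
               tv$taxonomy$ic[order(names(tv$taxonomy$ic))],
               tolerance = 1e-12)

  # word vectors text
  vp <- file.path(dir, "vectors.txt")
  write_word_vectors(tv$vectors, vp)
  v2 <- read_word_vectors(vp)
  expect_equal(v2$vectors, tv$vectors$vectors, tolerance = 1e-6)

  # gold pairs TSV
  gp <- file.path(dir, "gold.tsv")
  pairs <- gen_gold_pairs(spec)
  write_gold_pairs(pairs, gp)
  expect_equal(read_gold_pairs(gp), pairs, tolerance = 1e-9)

  # dependency parses CoNLL-U
  trees <- gen_conllu(gen)
  pp <- file.path(dir, "parses.conllu")
  write_conllu(trees, pp)
  trees2 <- read_conllu(pp, gen$corpus)
  expect_equal(names(trees2), names(trees))
  expect_identical(trees2[[1]]$head, trees[[1]]$head)
})
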
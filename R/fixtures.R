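# Seeded synthetic fixtures. Every external input the pipeline consumes —
# corpora, terminology, reference links, dependency parses, taxonomies,
# word vectors, gold similarity pairs — can be generated deterministically
# from a small specification, so the whole system is testable with no
# downloads. Fixture sentences are template-generated ("The <TF> protein
# <effect-verb> transcription of the <gene> gene ...") rather than natural
# text: downstream components consume only lexical and statistical
# structure, and templates keep the ground truth (planted mention offsets,
# topic labels, sense labels) exactly computable.

#' Fixture specification
#'
#' @param seed integer RNG seed; the same spec always produces
#'   byte-identical fixtures.
#' @param n_docs number of documents.
#' @param sentences_per_doc sentences per document.
#' @param n_topics number of topics; documents are assigned round-robin.
#' @param words_per_topic topic-specific vocabulary size.
#' @param shared_words words shared by all topic vocabularies (topical
#'   overlap).
#' @param n_tf,n_genes entities per type, spread over topics.
#' @param interaction_rate fraction of sentences planting a TF-effect-gene
#'   statement (the rest are topical filler).
#' @param ambiguity_rate rate of ambiguous surfaces for
#'   [gen_ambiguous_links()]; 0 disables ambiguity (and yields no links).
#' @param train_fraction fraction of documents whose reference links are
#'   released for distant training; the rest are held out.
#' @param noise_sigma Gaussian noise added to gold similarity scores.
#' @param n_gold_pairs number of gold pairs generated.
#' @param dim word-vector dimensionality (default 50).
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_docs = 10L, sentences_per_doc = 8L,
                         n_topics = 3L, words_per_topic = 24L,
                         shared_words = 4L, n_tf = 6L, n_genes = 12L,
                         interaction_rate = 0.5, ambiguity_rate = 0.3,
                         train_fraction = 0.8, noise_sigma = 0.3,
                         n_gold_pairs = 200L, dim = 50L) {
  spec <- list(seed = as.integer(seed), n_docs = as.integer(n_docs),
               sentences_per_doc = as.integer(sentences_per_doc),
               n_topics = as.integer(n_topics),
               words_per_topic = as.integer(words_per_topic),
               shared_words = as.integer(shared_words),
               n_tf = as.integer(n_tf), n_genes = as.integer(n_genes),
               interaction_rate = interaction_rate,
               ambiguity_rate = ambiguity_rate,
               train_fraction = train_fraction,
               noise_sigma = noise_sigma,
               n_gold_pairs = as.integer(n_gold_pairs),
               dim = as.integer(dim))
  stopifnot(spec$n_docs >= 1L, spec$sentences_per_doc >= 1L,
            spec$n_topics >= 1L, spec$words_per_topic >= 4L,
            spec$n_tf >= 1L, spec$n_genes >= 1L,
            spec$interaction_rate >= 0, spec$interaction_rate <= 1,
            spec$ambiguity_rate >= 0, spec$ambiguity_rate <= 1,
            spec$train_fraction > 0, spec$train_fraction < 1,
            spec$noise_sigma >= 0, spec$dim >= 1L)
  structure(spec, class = "fixture_spec")
}

.syllables <- c("ba", "be", "bo", "da", "de", "do", "fa", "fe", "fo",
                "ga", "ge", "go", "ka", "ke", "ko", "la", "le", "lo",
                "ma", "me", "mo", "na", "ne", "no", "pa", "pe", "po",
                "ra", "re", "ro", "sa", "se", "so", "ta", "te", "to",
                "va", "ve", "vo", "za", "ze", "zo")

# n distinct pseudo-words (lower-case, >= 6 chars), avoiding `used`
.make_words <- function(n, used = character(0)) {
  out <- character(0)
  while (length(out) < n) {
    w <- paste(sample(.syllables, 3L, replace = TRUE), collapse = "")
    if (!(w %in% out) && !(w %in% used)) out <- c(out, w)
  }
  out
}

# entity name generators; lower-cased names stay distinct from all words
.make_tf_names <- function(n, used) {
  out <- character(0)
  while (length(out) < n) {
    w <- paste0(sample(LETTERS, 1L),
                paste(sample(letters, 2L, replace = TRUE), collapse = ""),
                sample(LETTERS, 1L))
    if (!(tolower(w) %in% used) && !(tolower(w) %in% tolower(out))) {
      out <- c(out, w)
    }
  }
  out
}

.make_gene_names <- function(n, used) {
  out <- character(0)
  while (length(out) < n) {
    w <- paste0(paste(sample(letters, 3L, replace = TRUE), collapse = ""),
                sample(LETTERS, 1L))
    if (!(tolower(w) %in% used) && !(tolower(w) %in% tolower(out))) {
      out <- c(out, w)
    }
  }
  out
}

.effect_verbs <- c("activates", "represses", "induces", "regulates",
                   "upregulates", "downregulates", "stimulates", "inhibits")
.filler_verbs <- c("involves", "concerns", "comprises", "follows", "shows")

# shared lexical material; must be the FIRST draws under the spec seed so
# that corpus, taxonomy and vector generators see the same vocabulary
.gen_lexical <- function(spec) {
  shared <- .make_words(spec$shared_words)
  topic_words <- list()
  used <- shared
  for (t in seq_len(spec$n_topics)) {
    tw <- .make_words(spec$words_per_topic, used)
    used <- c(used, tw)
    topic_words[[t]] <- tw
  }
  tf_names <- .make_tf_names(spec$n_tf, used)
  gene_names <- .make_gene_names(spec$n_genes, c(used, tolower(tf_names)))
  list(shared = shared, topic_words = topic_words,
       tf_names = tf_names, gene_names = gene_names)
}

# assemble a sentence from a word vector; entity_rows marks which word
# positions are planted entities. Returns text plus 0-based word offsets.
.assemble_sentence <- function(words) {
  starts <- cumsum(c(0L, nchar(words) + 1L))[seq_along(words)]
  list(text = paste0(paste(words, collapse = " "), "."),
       starts = starts, ends = starts + nchar(words))
}

#' Generate a topical corpus with planted entity mentions
#'
#' Documents are assigned to topics round-robin; each sentence is either a
#' planted regulatory statement ("The `<TF>` protein `<effect-verb>`
#' transcription of the `<gene>` gene under `<topic words>` conditions.")
#' or topical filler built from the topic's vocabulary. The returned
#' ground truth records every planted mention with exact character
#' offsets, and the per-sentence topic labels.
#'
#' @param spec a `fixture_spec`.
#' @return a list with `corpus` (preprocessed `lit_corpus`), `dictionary`
#'   (entries tibble), `mentions` (planted ground truth: `doc_id`,
#'   `sent_id`, `char_start`, `char_end`, `surface`, `entity_id`,
#'   `entity_type`), `topics` (tibble `doc_id`, `sent_id`, `topic`) and
#'   `effect_lexicon`.
#' @export
gen_corpus <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, {
    lex <- .gen_lexical(spec)
    tf_topic <- rep_len(seq_len(spec$n_topics), spec$n_tf)
    gene_topic <- rep_len(seq_len(spec$n_topics), spec$n_genes)
    tf_ids <- sprintf("TF%03d", seq_len(spec$n_tf))
    gene_ids <- sprintf("GENE%03d", seq_len(spec$n_genes))

    docs <- list()
    mention_rows <- list()
    topic_rows <- list()
    for (d in seq_len(spec$n_docs)) {
      doc_id <- sprintf("doc%03d", d)
      topic <- (d - 1L) %% spec$n_topics + 1L
      vocab <- c(lex$topic_words[[topic]], lex$shared)
      tfs <- which(tf_topic == topic)
      genes <- which(gene_topic == topic)
      sent_texts <- character(spec$sentences_per_doc)
      offset <- 0L
      for (k in seq_len(spec$sentences_per_doc)) {
        sent_id <- sprintf("%s:s%d", doc_id, k - 1L)
        interaction <- length(tfs) && length(genes) &&
          stats::runif(1) < spec$interaction_rate
        if (interaction) {
          tf <- tfs[sample.int(length(tfs), 1L)]
          gene <- genes[sample.int(length(genes), 1L)]
          ws <- sample(vocab, 2L)
          words <- c("The", lex$tf_names[tf], "protein",
                     sample(.effect_verbs, 1L), "transcription", "of",
                     "the", lex$gene_names[gene], "gene", "under",
                     ws[1], ws[2], "conditions")
          asm <- .assemble_sentence(words)
          for (pos in c(2L, 8L)) {
            ent_tf <- pos == 2L
            mention_rows[[length(mention_rows) + 1L]] <- tibble::tibble(
              doc_id = doc_id, sent_id = sent_id,
              char_start = offset + asm$starts[pos],
              char_end = offset + asm$ends[pos],
              surface = words[pos],
              entity_id = if (ent_tf) tf_ids[tf] else gene_ids[gene],
              entity_type = if (ent_tf) "TF" else "GENE"
            )
          }
        } else {
          ws <- sample(vocab, 5L)
          words <- c("The", ws[1], ws[2], "response",
                     sample(.filler_verbs, 1L), ws[3], "and", ws[4],
                     ws[5], "processes")
          asm <- .assemble_sentence(words)
        }
        sent_texts[k] <- asm$text
        topic_rows[[length(topic_rows) + 1L]] <- tibble::tibble(
          doc_id = doc_id, sent_id = sent_id, topic = topic)
        offset <- offset + nchar(asm$text) + 1L
      }
      docs[[d]] <- lit_document(doc_id, paste(sent_texts, collapse = " "))
    }

    dictionary <- term_entries(tibble::tibble(
      term = c(lex$tf_names, lex$gene_names),
      entity_id = c(tf_ids, gene_ids),
      entity_type = c(rep("TF", spec$n_tf), rep("GENE", spec$n_genes)),
      source = "synthetic"
    ))
    list(
      corpus = preprocess_corpus(as_corpus(docs, corpus_id = "synthetic")),
      dictionary = dictionary,
      mentions = dplyr::bind_rows(mention_rows),
      topics = dplyr::bind_rows(topic_rows),
      effect_lexicon = default_effect_lexicon()
    )
  })
}

#' Generate flat dependency parses for a generated corpus
#'
#' Produces one tree per sentence of a [gen_corpus()] corpus: the main
#' verb (the planted effect verb or the filler verb) is the root and every
#' other token attaches to it. Simplistic, but structurally valid, and the
#' lowest common ancestor of any planted TF/gene pair is the effect verb —
#' exactly the configuration relation extraction looks for.
#'
#' @param gen result of [gen_corpus()].
#' @return named list of `dep_tree` objects keyed by sent_id.
#' @export
gen_conllu <- function(gen) {
  verbs <- c(.effect_verbs, .filler_verbs)
  trees <- list()
  for (s in corpus_sentences(gen$corpus)) {
    form <- s$tokens$surface
    root <- which(form %in% verbs)
    root <- if (length(root)) root[1] else 1L
    head <- rep(root, length(form))
    head[root] <- 0L
    upos <- rep("NOUN", length(form))
    upos[!grepl("[A-Za-z0-9]", form)] <- "PUNCT"
    upos[root] <- if (form[root] %in% verbs) "VERB" else upos[root]
    deprel <- rep("dep", length(form))
    deprel[root] <- "root"
    trees[[s$sent_id]] <- dep_tree(s$sent_id, form, upos, head, deprel)
  }
  trees
}

#' Generate a distant-supervision disambiguation fixture
#'
#' Builds a corpus in which a small set of surfaces is ambiguous between
#' two identifiers (a TF sense and a GENE sense) whose context
#' vocabularies are disjoint; every document uses one sense consistently.
#' Reference links are released only for the training split of documents;
#' the held-out documents' true senses are returned separately so
#' resolution accuracy can be measured.
#'
#' @param spec a `fixture_spec` with `ambiguity_rate > 0` (an ambiguity
#'   rate of 0 yields no ambiguous surfaces and therefore no links).
#' @return a list with `corpus`, `dictionary`, `links` (training split
#'   only), `heldout` (tibble `doc_id`, `surface`, `entity_id` with the
#'   true sense of each held-out document) and `senses` (the full
#'   assignment, for auditing).
#' @export
gen_ambiguous_links <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, {
    n_surfaces <- if (spec$ambiguity_rate > 0) 2L else 0L
    used <- character(0)
    surfaces <- character(0)
    context <- list() # context[[surface]][[sense]] = word vector
    if (n_surfaces > 0) {
      surfaces <- .make_gene_names(n_surfaces, used)
      used <- tolower(surfaces)
      for (s in surfaces) {
        w1 <- .make_words(12L, used)
        used <- c(used, w1)
        w2 <- .make_words(12L, used)
        used <- c(used, w2)
        context[[s]] <- list(w1, w2)
      }
    }
    filler <- .make_words(20L, used)

    sense_ids <- function(surface) {
      c(sprintf("TF-%s", toupper(surface)), sprintf("GENE-%s", toupper(surface)))
    }
    docs <- list()
    sense_rows <- list()
    for (d in seq_len(spec$n_docs)) {
      doc_id <- sprintf("amb%03d", d)
      sent_texts <- character(spec$sentences_per_doc)
      if (n_surfaces > 0) {
        surface <- surfaces[(d - 1L) %% n_surfaces + 1L]
        sense <- sample.int(2L, 1L)
        ids <- sense_ids(surface)
        sense_rows[[length(sense_rows) + 1L]] <- tibble::tibble(
          doc_id = doc_id, surface = surface, entity_id = ids[sense])
        ctx <- context[[surface]][[sense]]
        for (k in seq_len(spec$sentences_per_doc)) {
          ws <- sample(ctx, 4L)
          sent_texts[k] <- .assemble_sentence(
            c("The", surface, "element", "concerns", ws[1], ws[2],
              "and", ws[3], ws[4], "signals"))$text
        }
      } else {
        for (k in seq_len(spec$sentences_per_doc)) {
          ws <- sample(filler, 4L)
          sent_texts[k] <- .assemble_sentence(
            c("The", ws[1], ws[2], "response", "concerns", ws[3],
              ws[4], "signals"))$text
        }
      }
      docs[[d]] <- lit_document(doc_id, paste(sent_texts, collapse = " "))
    }
    senses <- dplyr::bind_rows(c(
      list(tibble::tibble(doc_id = character(0), surface = character(0),
                          entity_id = character(0))),
      sense_rows))

    dict_rows <- list(tibble::tibble(
      term = filler[1], entity_id = "FILLER001", entity_type = "OTHER",
      source = "synthetic"))
    for (s in surfaces) {
      ids <- sense_ids(s)
      dict_rows[[length(dict_rows) + 1L]] <- tibble::tibble(
        term = c(s, s), entity_id = ids, entity_type = c("TF", "GENE"),
        source = "synthetic")
    }
    dictionary <- term_entries(dplyr::bind_rows(dict_rows))

    n_train <- max(1L, min(spec$n_docs - 1L,
                           ceiling(spec$train_fraction * spec$n_docs)))
    train_docs <- sprintf("amb%03d", seq_len(n_train))
    links <- senses[senses$doc_id %in% train_docs,
                    c("doc_id", "entity_id"), drop = FALSE]
    heldout <- senses[!(senses$doc_id %in% train_docs), , drop = FALSE]
    list(
      corpus = preprocess_corpus(as_corpus(docs, corpus_id = "ambiguous")),
      dictionary = dictionary,
      links = reference_links(links),
      heldout = heldout,
      senses = senses
    )
  })
}

#' Measure held-out disambiguation accuracy on a generated fixture
#'
#' Trains [train_distant()] on the fixture's training links and resolves
#' every ambiguous mention of the held-out documents.
#'
#' @param fixture result of [gen_ambiguous_links()].
#' @param alpha,window passed to [train_distant()].
#' @return a list with `accuracy`, `n_heldout_mentions` and the `model`.
#' @export
heldout_accuracy <- function(fixture, alpha = 1, window = 5L) {
  model <- train_distant(fixture$corpus, fixture$links,
                         compile_dictionary(fixture$dictionary),
                         alpha = alpha, window = window)
  mentions <- annotate_corpus(fixture$corpus,
                              compile_dictionary(fixture$dictionary))
  held_docs <- unique(fixture$heldout$doc_id)
  amb <- mentions[mentions$doc_id %in% held_docs &
                    lengths(mentions$candidate_ids) > 1L, , drop = FALSE]
  if (!nrow(amb)) stop("no held-out ambiguous mentions")
  resolved <- resolve_mentions(fixture$corpus, amb, model)
  truth <- stats::setNames(
    fixture$heldout$entity_id,
    paste(fixture$heldout$doc_id, fixture$heldout$surface, sep = "\r"))
  key <- paste(resolved$doc_id, resolved$matched_surface, sep = "\r")
  ok <- resolved$resolved_id == truth[key]
  list(accuracy = mean(ok), n_heldout_mentions = nrow(amb), model = model)
}

#' Generate a taxonomy and word vectors matching the corpus vocabulary
#'
#' The taxonomy is a small single-rooted tree with a designed frequency
#' assignment: below the root sit an upper concept (cumulative probability
#' 0.5) with two child branches of cumulative probability 0.25 each, and
#' an unrelated sibling absorbing the remaining mass — so the Lin
#' similarity between the two branch markers is exactly
#' `2 log 2 / (log 4 + log 4) = 0.5`, a closed-form anchor for tests.
#' Topic vocabularies (stemmed, as the similarity engine sees them) hang
#' under the two branches. Word vectors place same-topic words around a
#' common direction so that within-topic cosine exceeds cross-topic
#' cosine.
#'
#' @param spec a `fixture_spec`.
#' @return list with `taxonomy` (a `lit_taxonomy`) and `vectors`
#'   (a `word_vectors` of dimension `spec$dim`).
#' @export
gen_taxonomy_and_vectors <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, {
    lex <- .gen_lexical(spec)
    stems <- lapply(lex$topic_words, stem)

    left <- seq_len(ceiling(spec$n_topics / 2))
    right <- setdiff(seq_len(spec$n_topics), left)
    topic_concept <- sprintf("c_topic%d", seq_len(spec$n_topics))
    side_freq <- function(side) {
      if (length(side)) rep(100 / length(side), length(side)) else numeric(0)
    }
    concepts <- tibble::tibble(
      concept = c("c_root", "c_upper", "c_other", "c_left", "c_right",
                  topic_concept),
      parent = c("", "c_root", "c_root", "c_upper", "c_upper",
                 ifelse(seq_len(spec$n_topics) %in% left, "c_left", "c_right")),
      freq = c(0, 0, 200,
               if (length(left)) 0 else 100,
               if (length(right)) 0 else 100,
               rep(0, spec$n_topics))
    )
    concepts$freq[concepts$concept %in% topic_concept[left]] <- side_freq(left)
    concepts$freq[concepts$concept %in% topic_concept[right]] <- side_freq(right)

    word_map <- dplyr::bind_rows(
      tibble::tibble(word = c("leftmark", "rightmark"),
                     concept = c("c_left", "c_right")),
      dplyr::bind_rows(lapply(seq_len(spec$n_topics), function(t) {
        tibble::tibble(word = unique(stems[[t]]), concept = topic_concept[t])
      }))
    )
    tax <- taxonomy(concepts, word_map)

    vocab <- unique(c(unlist(stems), "leftmark", "rightmark"))
    mat <- matrix(0, nrow = length(vocab), ncol = spec$dim,
                  dimnames = list(vocab, NULL))
    normalize <- function(v) v / sqrt(sum(v^2))
    centers <- lapply(seq_len(spec$n_topics), function(t) {
      normalize(stats::rnorm(spec$dim))
    })
    for (t in seq_len(spec$n_topics)) {
      for (w in unique(stems[[t]])) {
        mat[w, ] <- normalize(centers[[t]] + 0.35 * stats::rnorm(spec$dim))
      }
    }
    for (w in c("leftmark", "rightmark")) {
      mat[w, ] <- normalize(stats::rnorm(spec$dim))
    }
    list(taxonomy = tax, vectors = word_vectors(mat))
  })
}

#' Generate gold-scored sentence pairs
#'
#' Pairs are drawn from a [gen_corpus()] corpus in a fixed mix — identical
#' sentences, same-topic pairs, cross-topic pairs — and the gold score is
#' the engine's own scaled score plus Gaussian noise, clamped to \[0, 5\].
#' With `noise_sigma = 0` the engine therefore evaluates against itself at
#' Pearson r = 1.
#'
#' @param spec a `fixture_spec`.
#' @param config `sim_config` used by the default scorer.
#' @param scorer optional function `(text1, text2) -> scaled score`.
#' @return tibble with columns `text1`, `text2`, `gold`.
#' @export
gen_gold_pairs <- function(spec, config = sim_config(), scorer = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  gen <- gen_corpus(spec)
  texts <- vapply(corpus_sentences(gen$corpus), `[[`, "", "text")
  topics <- gen$topics$topic
  if (is.null(scorer)) {
    scorer <- function(t1, t2) combined_similarity(t1, t2, config)$scaled
  }
  withr::with_seed(spec$seed + 1L, {
    n <- spec$n_gold_pairs
    kind <- rep_len(c("same", "within", "cross"), n)
    i1 <- integer(n)
    i2 <- integer(n)
    for (k in seq_len(n)) {
      if (kind[k] == "same") {
        i1[k] <- i2[k] <- sample.int(length(texts), 1L)
      } else if (kind[k] == "within" && spec$n_topics >= 1L) {
        t <- sample.int(spec$n_topics, 1L)
        pool <- which(topics == t)
        if (length(pool) < 2L) {
          i1[k] <- i2[k] <- pool[1]
        } else {
          pick <- pool[sample.int(length(pool), 2L)]
          i1[k] <- pick[1]; i2[k] <- pick[2]
        }
      } else {
        t <- sample.int(spec$n_topics, 1L)
        pool1 <- which(topics == t)
        pool2 <- which(topics != t)
        if (!length(pool2)) pool2 <- pool1
        i1[k] <- pool1[sample.int(length(pool1), 1L)]
        i2[k] <- pool2[sample.int(length(pool2), 1L)]
      }
    }
    system <- vapply(seq_len(n), function(k) scorer(texts[i1[k]], texts[i2[k]]),
                     numeric(1))
    gold <- pmin(5, pmax(0, system + stats::rnorm(n, 0, spec$noise_sigma)))
    tibble::tibble(text1 = texts[i1], text2 = texts[i2], gold = gold)
  })
}
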
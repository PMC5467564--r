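---
title: "Methods: assisted literature curation with litcurate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assisted literature curation with litcurate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litcurate)
```

## The problem

Databases of transcriptional regulation are filled by expert curators who
read primary articles and transcribe facts — which transcription factor
(TF) regulates which gene or transcription unit (TU), with what effect,
under which growth condition. Only a small fraction of the sentences in an
article carry such facts, so most reading time is spent locating rather
than transcribing. `litcurate` implements the text-mining machinery that
shrinks the search: entities are pre-annotated from a terminology
dictionary, sentences can be selected with boolean filters over those
annotations, dependency parses propose candidate TF–gene interactions, and
a sentence-similarity engine links topically related sentences across the
whole article collection so a curator can follow one idea through many
papers instead of reading each paper linearly.

Every component is deterministic, testable offline, and exercised against
seeded synthetic fixtures that plant known ground truth.

## Linguistic normalization

Documents enter as plain text (a directory of `.txt` files or a
`doc_id`/`text` TSV) and pass through `preprocess_corpus()`:

* **Sentence splitting** cuts at sentence-final punctuation followed by
  whitespace and an upper-case letter, with an abbreviation stop-list and
  a single-capital-initial rule so that "E. coli" never splits. Character
  spans are 0-based and half-open; every non-whitespace character belongs
  to exactly one sentence, which the suite checks as an invariant.
* **Tokenization** keeps maximal alphanumeric runs (with internal
  hyphens, so "heat-shock" is one token) and single punctuation marks,
  with document-absolute offsets that re-slice to the surface exactly.
* **Stemming** uses the classic Porter suffix-stripping cascade,
  implemented in the package. One deliberate deviation: the cascade is
  iterated to a fixpoint, because downstream components use stems as
  dictionary keys and need `stem(stem(w)) == stem(w)`. A single pass does
  not guarantee that (it maps "agreed" to "agre" and "agre" to "agr");
  for almost all words the first pass is already stable.
* **POS tagging** assigns a deliberately coarse five-label set
  (NOUN/VERB/ADJ/ADV/OTHER) — only the noun/verb distinction is consumed
  downstream (relation trigger gating). The default tagger is a
  closed-class lexicon plus suffix rules, chosen so the package needs no
  statistical model and stays runnable offline; `pos_tag()` accepts any
  drop-in replacement function for users with a real tagger.

## Terminology annotation

A dictionary row maps a term to a reference-database identifier and
entity type. `expand_variants()` closes each term under small orthographic
edits — hyphen/space swaps and hyphen deletion — and adds a case-folded
form for terms longer than 3 characters; shorter terms stay
case-sensitive because short gene symbols (fur vs Fur) are
case-informative. Plural `-s` stripping is deliberately *not* a default
variant rule; it can be layered on by adding explicit dictionary rows.

`annotate()` matches token sequences (never substrings, so a term "oxy"
cannot fire inside "oxygen") left-to-right with the longest match winning
and no overlaps — the standard dictionary-NER convention, chosen for
determinism. Ambiguity is preserved, not resolved: a mention carries every
candidate identifier, and `resolved_id` is set immediately only when
there is exactly one.

## Distant-supervision disambiguation

Many surfaces map to several identifiers. Rather than requiring an
annotated corpus, training labels come from the reference database
itself: if the database links article *B* to entity *A*, a mention in *B*
whose candidate set contains *A* is assumed to denote *A*. Mentions whose
candidates intersect the document's linked set in two or more identifiers
are skipped as training instances — keeping the distant-labeling
assumption clean — and the assumption's residual noise is accepted as
small relative to corpus size.

The classifier is multinomial naive Bayes with Laplace smoothing
(`alpha`, default 1) over bag-of-context features: stems in a ±5-token
window (configurable), entity types co-mentioned in the sentence, and
entity types present elsewhere in the document. Naive Bayes was chosen
because it is implementable from scratch, exactly reproducible, and fits
bag-of-features evidence; the suite pins its posterior to a hand-computed
value on a two-document corpus. Prediction restricts the posterior to the
mention's candidates; exact ties break towards the lexicographically
smaller identifier, and candidates never seen in training yield a
uniform-score result flagged `low_confidence`. Models serialize to
versioned JSON with fully sorted contents, so identical inputs give
byte-identical files.

## Relation candidates from dependency parses

Parses are consumed from CoNLL-U, never produced — parser training is out
of scope, and `read_conllu()` validates each tree (single root, acyclic)
against the corpus tokenization. The extraction rule: for an ordered pair
of a TF-type mention and a GENE/TU-type mention, find the lowest common
ancestor of their head tokens — the uppermost node where the two
syntactic paths meet. That token is the candidate trigger. Two design
choices fill gaps the rule itself leaves open:

* the mention head is the **last token** of its span (English noun
  phrases are right-headed);
* the trigger gate passes if the LCA token is **tagged VERB or its stem
  is in the effect lexicon** — the lexicon clause admits nominalizations
  ("the activation of *x* by *y*"), which a verb-only gate would miss.

Polarity is the lexicon class of the trigger stem (activation /
repression / regulation), `"unspecified"` for verbs outside the lexicon.
Agent/target roles are assigned by entity type (TF is always the agent);
role assignment from dependency labels is noted as future work.

## Boolean sentence filters

A filter is a curator-written boolean expression over per-sentence
annotations, e.g. `type:TF AND lexicon:effect` — at least one TF mention
and at least one regulatory-effect word. The grammar supports AND/OR/NOT
with the usual precedence (NOT > AND > OR, binary operators
left-associative), parentheses, case-insensitive keywords, and atoms
`type:<TYPE>`, `lexicon:<name>`, `term:"<literal>"`. Lexicon atoms match
on stems by default so one entry covers an inflectional family
("activates", "activation", …); this is a documented choice — literal
word-list matching is available per lexicon via `match_on = "surface"`.
Filter scope is the sentence, and `select_sentences()` reports the
selected fraction, the quantity a curator watches to judge a filter's
selectivity.

## Sentence similarity

The engine is a weighted combination of up to three metrics, each in
[0, 1]:

* **vsm** — a sentence is the frequency vector of its normalized content
  words (punctuation dropped, optional stop words removed, lower-cased,
  stemmed); similarity is the cosine of two such vectors. Cosine is
  scale-invariant, so raw counts need no prior normalization.
* **taxonomy** — Lin word similarity,
  \(2\,\mathrm{IC}(\mathrm{lcs})/(\mathrm{IC}(c_1)+\mathrm{IC}(c_2))\),
  with \(\mathrm{IC}(c) = -\log p(c)\) from cumulative concept
  frequencies; for ambiguous words the score is maximized over sense
  pairs (documented choice), and the lowest common subsumer in a DAG is
  the shared ancestor of maximal IC.
* **embedding** — cosine of dense word vectors, clamped by
  \(\max(0, \cos)\): a negative cosine carries no similarity signal for
  this use, and mapping \((\cos+1)/2\) would make antipodal words look
  half-similar.

Word-level metrics are lifted to sentences by symmetrized greedy
alignment: each content word takes its best match in the other sentence,
the matches are averaged, and the two directions are averaged — a
standard semantic-textual-similarity baseline that is \(O(nm)\) and
deterministic. Identical normalized words always count as a perfect
match, independent of resource coverage, which guarantees that identical
sentences score the maximum under any configuration.

Enabled metrics combine as a weighted arithmetic mean (equal weights by
default — the simplest auditable choice, fully configurable) and scale by
5 to the 0–5 scale used in community sentence-similarity evaluations,
where 5 means the sentences convey the same meaning and 0 means they are
unrelated. Stemming defaults on; stop-word removal defaults off and is
supplied explicitly where wanted (`default_stopwords()`). The planned
syntactic metrics are represented only by the POS-aware normalization
hooks; they are extension points, not implemented claims.

`evaluate_sts()` scores gold-standard pairs and reports the Pearson
correlation between system and gold scores, the conventional figure of
merit for this task.

## Cross-document linking

`build_links()` scores every sentence pair of a corpus — an exhaustive
\(O(n^2)\) offline pass, acceptable at the scale of a curation corpus and
run when a publication is integrated — and keeps pairs at or above a
scaled-score threshold, additionally capping each sentence at its `top_k`
strongest links. Defaults (threshold 3.5 of 5, `top_k` 10) bound graph
size on dense topical corpora; both are recorded in the graph snapshot.
The cap is *mutual*: a link survives if it makes the cut for at least one
endpoint, which preserves the symmetry invariant (y among x's neighbors
iff x among y's). The graph stores its above-threshold candidate set, so
`add_document()` can score only the new pairs and re-apply the cap,
provably reproducing a from-scratch rebuild — the suite checks equality
over 100 random trials. Links are stored once per unordered pair in
lexicographic order; `neighbors()` returns same-document and
cross-document partitions ranked by score.

## Synthetic fixtures: what they do and do not show

`gen_corpus()` and its siblings generate every input format the pipeline
reads, deterministically under a seed. Sentences are template-generated
("The `<TF>` protein `<effect-verb>` transcription of the `<gene>` gene
under `<topic words>` conditions.") rather than natural text: downstream
components consume only lexical and statistical structure, and templates
keep ground truth exactly computable — planted mention offsets, topic
labels, sense labels. Key designed properties:

* topic vocabularies are disjoint apart from a small shared pool, so
  same-topic sentences have higher cosine than cross-topic ones;
* ambiguous surfaces get two senses with disjoint context vocabularies,
  making distant supervision separable by construction (held-out
  resolution accuracy ≥ 0.9 at 50 documents, 2 senses);
* the generated taxonomy embeds a closed-form anchor — sibling branches
  of probability 0.25 under a subsumer of probability 0.5 give Lin
  similarity exactly 0.5;
* gold similarity scores are the engine's own score plus Gaussian noise
  (σ configurable, 0.3 by default), clamped to [0, 5] — a simple noise
  model standing in for inter-annotator variation.

What passing these tests shows: the machinery is correct — offsets,
matching, posteriors, graph algebra, metric identities. What it does not
show: performance on real biomedical prose, whose synonymy, anaphora and
syntactic complexity the templates deliberately lack; fixture accuracies
are upper bounds set by construction, not performance claims. Evaluating
against real curated corpora and real lexical resources (the taxonomy and
vector interfaces accept them unchanged) is the intended next step.

## Numerical and operational choices

* All randomness flows through explicit seeds (`fixture_spec(seed = )`,
  `withr::with_seed`); identical inputs give identical outputs
  everywhere, including byte-identical serialized models.
* Ties break lexicographically (disambiguation candidates, link
  ordering); empty inputs have defined results (empty vectors have
  cosine 0; a one-sentence corpus yields an empty graph) rather than
  errors, while genuinely malformed inputs (duplicate ids, cyclic
  parses, ragged vector files, zero-variance correlation input) raise
  informative errors.
* The test and evaluation problem sizes — corpora of 10–50 documents,
  200 gold pairs, 1000-case property loops — were chosen as the smallest
  sizes at which the checked properties are non-trivial; everything runs
  in a few minutes on one core.

## Limitations

Dictionary matching cannot find entities absent from the terminology;
there is no fuzzy matching, abbreviation detection or coreference.
Relation extraction proposes candidates, not curated facts — polarity
comes from a lexicon lookup and negation/speculation scope is not
analyzed. The similarity engine is bag-of-words at heart; word order and
syntax contribute nothing yet. These boundaries mirror the package's
role: it narrows what a curator reads, it does not replace the curator.
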
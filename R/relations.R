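# Relation candidate extraction from dependency parses. The guiding idea:
# when a sentence mentions a transcription factor and a regulated gene, the
# word expressing the interaction (the trigger, e.g. "induces") sits at the
# uppermost node shared by the syntactic paths from the root to the two
# arguments — their lowest common ancestor. A candidate is emitted for
# every (TF, gene/TU) mention pair whose LCA token looks like a trigger:
# either tagged VERB or carrying a stem from the effect lexicon (which also
# admits nominalizations such as "activation of X by Y").

#' Path from a token to the root
#' @param tree a `dep_tree`.
#' @param index 1-based token index.
#' @return integer vector of token indices from `index` up to the root.
#' @export
root_path <- function(tree, index) {
  n <- length(tree$head)
  stopifnot(index >= 1L, index <= n)
  path <- index
  i <- index
  while (tree$head[i] != 0L) {
    i <- tree$head[i]
    path <- c(path, i)
  }
  path
}

#' Lowest common ancestor of two tokens
#'
#' Returns the deepest node lying on both root-paths: the uppermost node at
#' the intersection of the syntactic paths leading to the two arguments.
#' Symmetric in its arguments; `lca_trigger(tree, i, i)` is `i`; the root
#' is always a common ancestor, so a result always exists.
#'
#' @param tree a `dep_tree`.
#' @param index_a,index_b 1-based token indices.
#' @return the 1-based index of the LCA token.
#' @export
lca_trigger <- function(tree, index_a, index_b) {
  pa <- root_path(tree, index_a)
  pb <- root_path(tree, index_b)
  for (i in pb) {
    if (i %in% pa) return(i)
  }
  tree$root # unreachable: the root terminates every path
}

.empty_relations <- function() {
  tibble::tibble(
    doc_id = character(0), sent_id = character(0),
    agent_id = character(0), target_id = character(0),
    agent_surface = character(0), target_surface = character(0),
    trigger_index = integer(0), trigger_surface = character(0),
    trigger_stem = character(0), polarity = character(0)
  )
}

.mention_entity_id <- function(mentions, i) {
  id <- mentions$resolved_id[i]
  if (!is.na(id)) id else paste(mentions$candidate_ids[[i]], collapse = ";")
}

#' Extract relation candidates from one parsed sentence
#'
#' For every ordered pair of an agent-type mention (default `TF`) and a
#' target-type mention (default `GENE`/`TU`) in the sentence, the LCA of
#' the two mention head tokens (head = last token of the span, English
#' noun phrases being right-headed) is computed. A candidate is emitted
#' iff that token is tagged VERB (in the parse, falling back to the
#' sentence's coarse tags) or its stem is in the effect lexicon; polarity
#' is the lexicon class of the trigger stem, `"unspecified"` when the
#' trigger is a verb outside the lexicon.
#'
#' @param sentence a preprocessed sentence record.
#' @param tree the aligned `dep_tree`.
#' @param mentions mentions tibble (any rows not in this sentence are
#'   ignored).
#' @param effect_lexicon tibble with columns `term`, `polarity`
#'   (see [default_effect_lexicon()]).
#' @param agent_types,target_types entity types acting as agent / target.
#' @return a relations tibble: `doc_id`, `sent_id`, `agent_id`,
#'   `target_id`, `agent_surface`, `target_surface`, `trigger_index`,
#'   `trigger_surface`, `trigger_stem`, `polarity`.
#' @export
extract_relations <- function(sentence, tree, mentions,
                              effect_lexicon = default_effect_lexicon(),
                              agent_types = "TF",
                              target_types = c("GENE", "TU")) {
  ms <- mentions[mentions$sent_id == sentence$sent_id, , drop = FALSE]
  if (!nrow(ms)) return(.empty_relations())
  if (length(tree$form) != nrow(sentence$tokens)) {
    stop("dependency tree not aligned with sentence ", sentence$sent_id)
  }
  types <- lapply(ms$entity_type, .split_types)
  is_agent <- vapply(types, function(t) any(t %in% agent_types), logical(1))
  is_target <- vapply(types, function(t) any(t %in% target_types), logical(1))
  if (!any(is_agent) || !any(is_target)) return(.empty_relations())

  effect_map <- effect_stem_map(effect_lexicon)
  out <- list()
  for (a in which(is_agent)) {
    for (b in which(is_target)) {
      if (a == b) next
      head_a <- ms$end_tok[a] - 1L
      head_b <- ms$end_tok[b] - 1L
      lca <- lca_trigger(tree, head_a, head_b)
      stem_lca <- sentence$tokens$stem[lca]
      is_verb <- identical(tree$upos[lca], "VERB") ||
        (tree$upos[lca] %in% c("_", "") &&
           identical(sentence$tokens$pos[lca], "VERB"))
      in_lexicon <- stem_lca %in% names(effect_map)
      if (!is_verb && !in_lexicon) next
      out[[length(out) + 1L]] <- tibble::tibble(
        doc_id = sentence$doc_id, sent_id = sentence$sent_id,
        agent_id = .mention_entity_id(ms, a),
        target_id = .mention_entity_id(ms, b),
        agent_surface = ms$matched_surface[a],
        target_surface = ms$matched_surface[b],
        trigger_index = lca,
        trigger_surface = tree$form[lca],
        trigger_stem = stem_lca,
        polarity = if (in_lexicon) unname(effect_map[[stem_lca]]) else "unspecified"
      )
    }
  }
  if (!length(out)) return(.empty_relations())
  dplyr::bind_rows(out)
}

#' Extract relation candidates for a whole corpus
#'
#' @param corpus a preprocessed `lit_corpus`.
#' @param trees named list of `dep_tree` (from [read_conllu()]); sentences
#'   without a parse are skipped.
#' @param mentions mentions tibble from [annotate_corpus()].
#' @inheritParams extract_relations
#' @return relations tibble over all parsed sentences, in corpus order.
#' @export
extract_relations_corpus <- function(corpus, trees, mentions,
                                     effect_lexicon = default_effect_lexicon(),
                                     agent_types = "TF",
                                     target_types = c("GENE", "TU")) {
  out <- list(.empty_relations())
  for (s in corpus_sentences(corpus)) {
    tree <- trees[[s$sent_id]]
    if (is.null(tree)) next
    out[[length(out) + 1L]] <-
      extract_relations(s, tree, mentions, effect_lexicon,
                        agent_types, target_types)
  }
  dplyr::bind_rows(out)
}

#' Write relation candidates to TSV
#' @param relations relations tibble.
#' @param path output file.
#' @export
write_relations <- function(relations, path) {
  utils::write.table(relations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
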
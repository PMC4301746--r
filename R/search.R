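#' Search a record corpus with query assistance and neural ranking
#'
#' Runs the full retrieval pipeline: the query is tokenized and expanded
#' with synonyms, candidate hits are retrieved (any record containing at
#' least one group member), per-hit 11-dimensional relevance features are
#' extracted, and hits are ordered either by the neural ranker (when a
#' network is supplied) or by the TF-IDF baseline. Each result carries its
#' score, feature vector, a text excerpt around the matches, and (when a
#' mapping table is supplied) evidence-sorted annotation links.
#'
#' @param index A `bio_index`.
#' @param query Free-text query string.
#' @param synonyms Optional `synonym_table`.
#' @param config A `feature_config`.
#' @param network Optional `ranker_network`; if `NULL`, TF-IDF scores are
#'   used for ordering.
#' @param mappings Optional mapping table from [load_mappings()].
#' @param db Optional source-database filter (only records of this
#'   database are returned).
#' @param use_synonyms Apply synonym expansion (default `TRUE`).
#' @param top Maximum number of results (default 20).
#' @param snippet_radius Token radius of result excerpts.
#' @return A list with `results` (data frame in the export schema:
#'   `rank`, `record_id`, `source_db`, `score`, 11 feature columns,
#'   `excerpt`, `links`), `expected_hits` (AND-of-OR estimate),
#'   `suggestions` (named list of spelling suggestions for
#'   out-of-vocabulary terms) and `query_spec`.
#' @export
search_records <- function(index, query, synonyms = NULL,
                           config = feature_config(), network = NULL,
                           mappings = NULL, db = NULL, use_synonyms = TRUE,
                           top = 20L, snippet_radius = 8L) {
  tokens <- tokenize(query)
  spec <- expand_synonyms(tokens, if (use_synonyms) synonyms else NULL,
                          raw = query)

  suggestions <- list()
  if (length(index$df)) {
    for (tok in unique(tokens)) {
      if (!tok %in% names(index$df)) {
        sug <- correct_spelling(tok, index)
        if (length(sug)) suggestions[[tok]] <- sug
      }
    }
  }

  # candidate hits: any record containing >= 1 member of >= 1 group
  cand <- unique(unlist(lapply(spec$groups, function(g)
    unlist(lapply(g$members, function(m)
      records_with_member(index, m$tokens))))))
  if (!is.null(db))
    cand <- cand[vapply(cand, function(id)
      identical(index$records[[id]]$source_db, db), logical(1))]

  empty_results <- cbind(
    data.frame(rank = integer(0), record_id = character(0),
               source_db = character(0), score = numeric(0),
               stringsAsFactors = FALSE),
    as.data.frame(matrix(numeric(0), 0, 11,
                         dimnames = list(NULL, FEATURE_NAMES))),
    data.frame(excerpt = character(0), links = character(0),
               stringsAsFactors = FALSE))

  if (length(cand) == 0L)
    return(list(results = empty_results,
                expected_hits = estimate_hits(spec, index),
                suggestions = suggestions, query_spec = spec))

  cand <- sort(cand)
  ctxs <- lapply(cand, function(id) hit_context(spec, id, index))
  names(ctxs) <- cand
  feats <- t(vapply(cand, function(id)
    extract_features(spec, index$records[[id]], ctxs[[id]], index, config),
    numeric(11)))

  if (!is.null(network)) {
    scores <- predict_relevance(network, feats)
  } else {
    qt <- unique(unlist(lapply(spec$groups, function(g)
      unlist(lapply(g$members, `[[`, "tokens")))))
    ranked <- tfidf_rank(qt, index)
    scores <- ranked$score[match(cand, ranked$record_id)]
    scores[is.na(scores)] <- 0
  }

  ord <- order(-scores, cand)
  keep <- ord[seq_len(min(top, length(ord)))]

  rows <- lapply(seq_along(keep), function(pos) {
    i <- keep[pos]
    id <- cand[i]
    rec <- index$records[[id]]
    ctx <- ctxs[[id]]
    if (is.null(ctx$attribute)) {
      snip <- make_snippet(character(0))
    } else {
      snip <- make_snippet(index$tokens[[id]][[ctx$attribute]],
                           sort(unique(unlist(ctx$group_positions))),
                           radius = snippet_radius)
    }
    links <- if (is.null(mappings)) ""
             else format_links(resolve_links(id, mappings, index))
    cbind(data.frame(rank = pos, record_id = id, source_db = rec$source_db,
                     score = scores[i], stringsAsFactors = FALSE),
          as.data.frame(as.list(feats[i, ])),
          data.frame(excerpt = snip$text, links = links,
                     stringsAsFactors = FALSE))
  })
  results <- do.call(rbind, rows)
  rownames(results) <- NULL

  list(results = results, expected_hits = estimate_hits(spec, index),
       suggestions = suggestions, query_spec = spec)
}
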
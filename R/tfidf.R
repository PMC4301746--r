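#' Rank records by TF-IDF cosine similarity (vector-space baseline)
#'
#' Documents and queries are weighted vectors in a vector space model where
#' each distinct index term is a dimension. Document weights are
#' `w(t,d) = tf(t,d) * (1 + ln(N/df(t)))`; query weights are 1 per distinct
#' term; relevance is the cosine between the two vectors. Records with
#' score 0 are omitted. This is the classical lexical baseline the neural
#' ranker is compared against.
#'
#' @param query_terms Character vector of query tokens (see [tokenize()]).
#' @param index A `bio_index`.
#' @return A data frame with columns `record_id`, `score`, sorted by
#'   descending score, ties broken by ascending `record_id`.
#' @export
tfidf_rank <- function(query_terms, index) {
  query_terms <- unique(query_terms)
  query_terms <- query_terms[query_terms %in% names(index$df)]
  empty <- data.frame(record_id = character(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(query_terms) == 0L || index$N == 0L) return(empty)

  scores <- new.env(parent = emptyenv())
  for (t in query_terms) {
    idf <- 1 + log(index$N / unname(index$df[t]))
    for (id in unique(index$inv[[t]])) {
      prev <- if (is.null(scores[[id]])) 0 else scores[[id]]
      scores[[id]] <- prev + unname(index$tf[[id]][t]) * idf
    }
  }
  ids <- ls(scores)
  if (length(ids) == 0L) return(empty)
  dot <- vapply(ids, function(id) scores[[id]], numeric(1))
  cosine <- dot / (index$doc_norm[ids] * sqrt(length(query_terms)))
  keep <- cosine > 0
  out <- data.frame(record_id = ids[keep], score = unname(cosine[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$record_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Estimate the number of expected results for an expanded query
#'
#' Counts records that contain, for every query term group, at least one
#' group member (AND across groups, OR within a group). Multi-word synonym
#' members match as contiguous token sequences.
#'
#' @param query_spec A `query_spec` from [expand_synonyms()] / [parse_query()].
#' @param index A `bio_index`.
#' @return Non-negative integer count.
#' @export
estimate_hits <- function(query_spec, index) {
  stopifnot(inherits(query_spec, "query_spec"))
  if (length(query_spec$groups) == 0L) return(0L)
  sets <- lapply(query_spec$groups, function(g) {
    ids <- unlist(lapply(g$members, function(m)
      records_with_member(index, m$tokens)))
    unique(ids)
  })
  length(Reduce(intersect, sets))
}

# Cosine similarity between two records' TF-IDF vectors.
record_cosine <- function(index, id_a, id_b) {
  wa <- tfidf_weights(index, id_a)
  wb <- tfidf_weights(index, id_b)
  shared <- intersect(names(wa), names(wb))
  if (length(shared) == 0L) return(0)
  na <- index$doc_norm[[id_a]]
  nb <- index$doc_norm[[id_b]]
  if (na == 0 || nb == 0) return(0)
  min(1, sum(wa[shared] * wb[shared]) / (na * nb))
}

#' Suggest related entries by document similarity
#'
#' Returns the `k` records most similar to a given record under TF-IDF
#' cosine similarity, excluding the record itself.
#'
#' @param record_id Identifier of a record present in the index.
#' @param index A `bio_index`.
#' @param k Maximum number of suggestions (>= 1).
#' @return A data frame with columns `record_id`, `similarity`, descending,
#'   ties broken by ascending `record_id`.
#' @export
suggest_related <- function(record_id, index, k = 5L) {
  if (!record_id %in% names(index$records))
    stop("unknown record_id: ", record_id)
  stopifnot(k >= 1L)
  others <- setdiff(index$record_ids, record_id)
  sim <- vapply(others, function(id) record_cosine(index, record_id, id),
                numeric(1))
  ord <- order(-sim, others)
  out <- data.frame(record_id = others[ord], similarity = unname(sim[ord]),
                    stringsAsFactors = FALSE)
  out <- out[seq_len(min(k, nrow(out))), , drop = FALSE]
  rownames(out) <- NULL
  out
}
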
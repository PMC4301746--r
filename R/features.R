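#' Names and order of the 11 relevance features
#'
#' The first nine features encode, in order: the attribute a hit was found
#' in, the source database, query-term frequency, term co-occurrence
#' (closeness and order), good/bad keyword context, organism agreement,
#' sequence length, the portion of the attribute covered by the query, and
#' whether the hit came only from synonym expansion. Two additional
#' standard IR signals — query coverage and mean inverse document
#' frequency — complete the 11-dimensional input of the neural ranker.
#'
#' @format Character vector of length 11.
#' @export
FEATURE_NAMES <- c(
  "attribute_weight", "database_weight", "term_frequency", "cooccurrence",
  "keyword_context", "organism_match", "sequence_length_norm",
  "text_position_coverage", "synonym_origin", "query_coverage", "idf_weight"
)

#' Configuration of the relevance feature extractor
#'
#' @param attribute_weights Named numeric in `[0,1]`: prior weight of each
#'   attribute name (unmapped attributes get 0.5).
#' @param database_weights Named numeric in `[0,1]`: prior weight of each
#'   source database (unmapped databases get 0.5).
#' @param good_keywords,bad_keywords Tokens whose presence near a query
#'   match raises / lowers the keyword-context feature.
#' @param keyword_window Window half-width in tokens for keyword context
#'   (default 5, must be >= 1).
#' @param length_cap Sequence length (residues/bases) mapping to feature
#'   value 1 on the log10 scale (default 100000, must be >= 1).
#' @param taxonomy Named list: canonical organism -> character vector of
#'   alias tokens (lowercase) used to detect organisms in queries and in
#'   record organism labels.
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(attribute_weights = numeric(0),
                           database_weights = numeric(0),
                           good_keywords = character(0),
                           bad_keywords = character(0),
                           keyword_window = 5L,
                           length_cap = 100000L,
                           taxonomy = default_taxonomy()) {
  aw <- unlist(attribute_weights)
  dw <- unlist(database_weights)
  if (length(aw) && (any(aw < 0) || any(aw > 1)))
    stop("attribute_weights must lie in [0,1]")
  if (length(dw) && (any(dw < 0) || any(dw > 1)))
    stop("database_weights must lie in [0,1]")
  if (keyword_window < 1L) stop("keyword_window must be >= 1")
  if (length_cap < 1L) stop("length_cap must be >= 1")
  structure(
    list(attribute_weights = aw, database_weights = dw,
         good_keywords = tolower(good_keywords),
         bad_keywords = tolower(bad_keywords),
         keyword_window = as.integer(keyword_window),
         length_cap = as.numeric(length_cap),
         taxonomy = lapply(taxonomy, tolower)),
    class = "feature_config"
  )
}

#' Built-in plant taxonomy alias list
#'
#' Canonical organisms with the alias tokens under which they appear in
#' queries and record organism labels (common names, genus, species,
#' well-known cultivar/subspecies epithets).
#'
#' @return Named list: canonical organism -> alias tokens.
#' @export
default_taxonomy <- function() {
  list(
    "Hordeum vulgare"      = c("barley", "hordeum", "vulgare", "morex",
                               "spontaneum"),
    "Arabidopsis thaliana" = c("arabidopsis", "thaliana"),
    "Oryza sativa"         = c("rice", "oryza", "sativa"),
    "Zea mays"             = c("maize", "zea", "mays")
  )
}

#' Read a feature configuration from YAML or JSON
#'
#' @param path Path to a YAML (`.yml`/`.yaml`) or JSON file whose keys
#'   mirror the arguments of [feature_config()].
#' @return A `feature_config`.
#' @export
read_feature_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  args <- obj[intersect(names(obj), names(formals(feature_config)))]
  do.call(feature_config, args)
}

#' Term co-occurrence score: closeness and order of matched terms
#'
#' With a single matched term the score is 1. With `m >= 2` matched terms,
#' the minimal token window containing at least one occurrence of each term
#' is located; the base score is `m / span` (span in tokens, inclusive),
#' multiplied by 0.8 when no minimal window presents the terms in query
#' order. The result is clamped to `[0,1]`.
#'
#' @param position_lists List (in query order) of 0-based position vectors,
#'   one per matched term; every vector must be non-empty.
#' @return A real in `[0,1]`.
#' @export
proximity_score <- function(position_lists) {
  m <- length(position_lists)
  if (m == 0L || any(lengths(position_lists) == 0L))
    stop("proximity_score() requires at least one matched term with positions")
  if (m == 1L) return(1)

  all_pos <- sort(unique(unlist(position_lists)))
  best_span <- Inf
  windows <- list()
  for (lo in all_pos) {
    # smallest hi >= lo such that [lo, hi] covers every term
    his <- vapply(position_lists, function(p) {
      p <- p[p >= lo]
      if (length(p) == 0L) NA_real_ else min(p)
    }, numeric(1))
    if (anyNA(his)) next
    hi <- max(his)
    span <- hi - lo + 1
    if (span < best_span) {
      best_span <- span
      windows <- list(c(lo, hi))
    } else if (span == best_span) {
      windows[[length(windows) + 1L]] <- c(lo, hi)
    }
  }
  if (!is.finite(best_span)) stop("no covering window found")

  in_order <- any(vapply(windows, function(w) {
    cur <- w[1] - 1
    for (p in position_lists) {
      p <- p[p > cur & p <= w[2]]
      if (length(p) == 0L) return(FALSE)
      cur <- min(p)
    }
    TRUE
  }, logical(1)))

  score <- m / best_span
  if (!in_order) score <- score * 0.8
  min(max(score, 0), 1)
}

#' Keyword context score: good/bad keywords near query matches
#'
#' `p = 1` if any good keyword occurs within `keyword_window` tokens of any
#' matched position, else 0; `n` likewise for bad keywords. The score is
#' `(1 + p - n) / 2`, i.e. one of 0, 0.5, 1, with 0.5 neutral.
#'
#' @param matched_positions 0-based positions of query matches in the
#'   attribute.
#' @param attr_tokens Token vector of the attribute.
#' @param config A `feature_config`.
#' @return One of 0, 0.5, 1.
#' @export
keyword_context_score <- function(matched_positions, attr_tokens, config) {
  near <- function(keywords) {
    if (length(keywords) == 0L || length(matched_positions) == 0L) return(0)
    kw_pos <- which(attr_tokens %in% keywords) - 1L
    if (length(kw_pos) == 0L) return(0)
    hit <- any(vapply(kw_pos, function(k)
      any(abs(k - matched_positions) <= config$keyword_window), logical(1)))
    as.numeric(hit)
  }
  (1 + near(config$good_keywords) - near(config$bad_keywords)) / 2
}

#' Locate a query's matches inside one record
#'
#' Finds, per query term group, every occurrence of every group member in
#' every attribute, selects the best-matching attribute (most matched
#' groups; ties by most matched positions, then attribute order), and
#' records per-group matched positions within it together with the origin
#' of the matching members.
#'
#' @param query_spec A `query_spec`.
#' @param record_id A record present in the index.
#' @param index A `bio_index`.
#' @return An object of class `hit_context`.
#' @export
hit_context <- function(query_spec, record_id, index) {
  if (!record_id %in% names(index$records))
    stop("unknown record_id: ", record_id)
  attrs <- names(index$tokens[[record_id]])
  # per attribute, per group: matched positions and origins
  per_attr <- lapply(attrs, function(a) {
    tk <- index$tokens[[record_id]][[a]]
    lapply(query_spec$groups, function(g) {
      pos <- integer(0)
      origins <- character(0)
      for (m in g$members) {
        starts <- phrase_starts(tk, m$tokens)
        if (length(starts)) {
          covered <- unique(unlist(lapply(starts, function(s)
            s + seq_along(m$tokens) - 1L)))
          pos <- union(pos, covered)
          origins <- c(origins, m$origin)
        }
      }
      list(positions = sort(pos), origins = unique(origins))
    })
  })
  names(per_attr) <- attrs

  n_groups_matched <- vapply(per_attr, function(gs)
    sum(vapply(gs, function(g) length(g$positions) > 0L, logical(1))),
    integer(1))
  n_pos <- vapply(per_attr, function(gs)
    length(unique(unlist(lapply(gs, `[[`, "positions")))), integer(1))

  if (length(attrs) == 0L || all(n_groups_matched == 0L)) {
    best <- NULL
  } else {
    ord <- order(-n_groups_matched, -n_pos, seq_along(attrs))
    best <- attrs[ord[1]]
  }

  # groups matched anywhere in the record (for query coverage / origins)
  group_matched_anywhere <- vapply(seq_along(query_spec$groups), function(i)
    any(vapply(per_attr, function(gs) length(gs[[i]]$positions) > 0L,
               logical(1))), logical(1))
  group_origins <- lapply(seq_along(query_spec$groups), function(i)
    unique(unlist(lapply(per_attr, function(gs) gs[[i]]$origins))))

  structure(
    list(record_id = record_id,
         attribute = best,
         group_positions = if (is.null(best)) NULL
                           else lapply(per_attr[[best]], `[[`, "positions"),
         group_matched = group_matched_anywhere,
         group_origins = group_origins),
    class = "hit_context"
  )
}

#' Extract the 11-dimensional relevance feature vector of a hit
#'
#' Every component lies in `[0,1]`; see [FEATURE_NAMES] for the fixed
#' component order. Categorical features (attribute, database, organism)
#' are scalar-encoded via configuration lookups with 0.5 as the neutral /
#' unknown value.
#'
#' @param query_spec A `query_spec`.
#' @param rec The hit `bio_record`.
#' @param ctx A `hit_context` for this query and record.
#' @param index The `bio_index` containing the record.
#' @param config A `feature_config`.
#' @return Named numeric vector of length 11.
#' @export
extract_features <- function(query_spec, rec, ctx, index,
                             config = feature_config()) {
  if (!inherits(ctx, "hit_context") || !identical(ctx$record_id, rec$record_id))
    stop("hit_context does not belong to record '", rec$record_id, "'")
  n_groups <- length(query_spec$groups)
  if (!is.null(ctx$group_matched) && length(ctx$group_matched) != n_groups)
    stop("hit_context is inconsistent with the query (group count mismatch)")

  lookup <- function(map, key) {
    if (is.null(key) || is.null(map) || !key %in% names(map)) 0.5
    else unname(map[[key]])
  }

  attribute_weight <- lookup(config$attribute_weights, ctx$attribute)
  database_weight <- lookup(config$database_weights, rec$source_db)

  # distinct single tokens over all group members (exact and synonym)
  query_tokens <- unique(unlist(lapply(query_spec$groups, function(g)
    unlist(lapply(g$members, `[[`, "tokens")))))
  doc_len <- unname(index$doc_len[[rec$record_id]])
  counts <- index$tf[[rec$record_id]]
  occ <- sum(counts[intersect(query_tokens, names(counts))])
  term_frequency <- if (doc_len > 0) min(1, occ / doc_len) else 0

  matched_pos_lists <- if (is.null(ctx$attribute)) list()
                       else Filter(length, ctx$group_positions)
  cooccurrence <- if (length(matched_pos_lists) == 0L) 0
                  else proximity_score(matched_pos_lists)

  if (is.null(ctx$attribute)) {
    keyword_context <- 0.5
    text_position_coverage <- 0
  } else {
    attr_tokens <- index$tokens[[rec$record_id]][[ctx$attribute]]
    all_matched <- sort(unique(unlist(ctx$group_positions)))
    keyword_context <- keyword_context_score(all_matched, attr_tokens, config)
    text_position_coverage <- if (length(attr_tokens) == 0L) 0
                              else length(all_matched) / length(attr_tokens)
  }

  organism_match <- organism_agreement(query_tokens, rec$organism,
                                       config$taxonomy)

  sequence_length_norm <- if (is.null(rec$sequence_length)) 0
    else min(1, log10(1 + rec$sequence_length) / log10(1 + config$length_cap))

  matched_origins <- unlist(ctx$group_origins[ctx$group_matched])
  synonym_origin <- as.numeric("exact" %in% matched_origins)

  query_coverage <- if (n_groups == 0L) 0 else mean(ctx$group_matched)

  matched_terms <- intersect(query_tokens, names(counts))
  idf_weight <- if (index$N <= 1L || length(matched_terms) == 0L) 0
    else mean(log(index$N / unname(index$df[matched_terms])) / log(index$N))

  out <- c(attribute_weight, database_weight, term_frequency, cooccurrence,
           keyword_context, organism_match, sequence_length_norm,
           text_position_coverage, synonym_origin, query_coverage, idf_weight)
  names(out) <- FEATURE_NAMES
  out
}

# Organism agreement between the query and a record label:
# 1   both sides name an organism and they agree,
# 0   both sides name organisms but different ones,
# 0.5 either side is silent.
organism_agreement <- function(query_tokens, organism, taxonomy) {
  orgs_of <- function(tokens) {
    names(taxonomy)[vapply(taxonomy, function(alias)
      any(tokens %in% alias), logical(1))]
  }
  q_orgs <- orgs_of(tolower(query_tokens))
  r_orgs <- if (is.null(organism)) character(0)
            else orgs_of(tokenize(organism))
  if (length(q_orgs) == 0L || length(r_orgs) == 0L) return(0.5)
  as.numeric(length(intersect(q_orgs, r_orgs)) > 0L)
}
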
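#' Build a positional inverted index over a record corpus
#'
#' Every attribute of every record is tokenized independently with
#' [tokenize()], so per-attribute token positions remain addressable. The
#' index keeps, per term, its document frequency (number of records
#' containing it) and collection frequency (total occurrences), plus the
#' per-record term-count tables and TF-IDF document norms used by the
#' vector-space baseline ranker.
#'
#' @param records List of `bio_record` objects with unique identifiers.
#' @return An object of class `bio_index`.
#' @export
build_index <- function(records) {
  ids <- vapply(records, function(r) r$record_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate record_id: ", ids[duplicated(ids)][1])
  names(records) <- ids

  tokens <- lapply(records, function(r) lapply(r$attributes, tokenize))
  doc_terms <- lapply(tokens, function(attrs) unlist(attrs, use.names = FALSE))
  tf <- lapply(doc_terms, function(t) {
    if (length(t) == 0L) return(integer(0))
    tab <- table(t)
    stats::setNames(as.integer(tab), names(tab))
  })
  doc_len <- vapply(doc_terms, length, integer(1))

  all_terms <- unlist(lapply(tf, names), use.names = FALSE)
  n_terms_per_doc <- vapply(tf, length, integer(1))
  if (length(all_terms)) {
    df_tab <- table(all_terms)
    df <- stats::setNames(as.integer(df_tab), names(df_tab))
    cf_raw <- tapply(unlist(tf, use.names = FALSE), all_terms, sum)
    cf <- stats::setNames(as.integer(cf_raw), names(cf_raw))
    inv <- split(rep(ids, n_terms_per_doc), all_terms)
  } else {
    df <- stats::setNames(integer(0), character(0))
    cf <- df
    inv <- list()
  }

  idx <- structure(
    list(records = records, tokens = tokens, tf = tf, doc_len = doc_len,
         df = df, cf = cf, inv = inv, N = length(records),
         record_ids = sort(ids)),
    class = "bio_index"
  )
  idx$doc_norm <- vapply(ids, function(id) {
    w <- tfidf_weights(idx, id)
    sqrt(sum(w * w))
  }, numeric(1))
  idx
}

#' @export
print.bio_index <- function(x, ...) {
  cat("<bio_index>", x$N, "records,", length(x$df), "terms,",
      sum(x$doc_len), "tokens\n")
  invisible(x)
}

# TF-IDF weight vector of one record: w(t,d) = tf(t,d) * (1 + ln(N/df(t))).
tfidf_weights <- function(index, record_id) {
  counts <- index$tf[[record_id]]
  if (length(counts) == 0L) return(stats::setNames(numeric(0), character(0)))
  idf <- 1 + log(index$N / index$df[names(counts)])
  stats::setNames(as.numeric(counts) * as.numeric(idf), names(counts))
}

#' Document frequency of a term
#'
#' @param index A `bio_index`.
#' @param term A single token.
#' @return Number of records containing the term (0 if unseen).
#' @export
term_df <- function(index, term) {
  v <- unname(index$df[term])
  if (is.na(v)) 0L else as.integer(v)
}

#' Positional postings of a term
#'
#' @param index A `bio_index`.
#' @param term A single token.
#' @return A data frame with columns `record_id`, `attribute`, and a
#'   list-column `positions` of strictly ascending 0-based token offsets;
#'   zero rows if the term is absent.
#' @export
postings <- function(index, term) {
  hits <- list()
  for (id in sort(unique(index$inv[[term]]))) {
    for (a in names(index$tokens[[id]])) {
      pos <- which(index$tokens[[id]][[a]] == term) - 1L
      if (length(pos))
        hits[[length(hits) + 1L]] <-
          list(record_id = id, attribute = a, positions = pos)
    }
  }
  data.frame(
    record_id = vapply(hits, `[[`, character(1), "record_id"),
    attribute = vapply(hits, `[[`, character(1), "attribute"),
    positions = I(lapply(hits, `[[`, "positions")),
    stringsAsFactors = FALSE
  )
}

# 0-based start positions of a contiguous token sequence within an attribute.
phrase_starts <- function(attr_tokens, phrase_tokens) {
  k <- length(phrase_tokens)
  n <- length(attr_tokens)
  if (k == 0L || n < k) return(integer(0))
  starts <- which(attr_tokens == phrase_tokens[1])
  if (k > 1L)
    starts <- starts[vapply(starts, function(s) {
      s + k - 1L <= n && all(attr_tokens[s:(s + k - 1L)] == phrase_tokens)
    }, logical(1))]
  starts - 1L
}

# Record ids containing a group member (token or phrase) anywhere.
records_with_member <- function(index, member_tokens) {
  if (length(member_tokens) == 1L)
    return(sort(unique(index$inv[[member_tokens]])))
  cand <- lapply(member_tokens, function(t) unique(index$inv[[t]]))
  cand <- Reduce(intersect, cand)
  if (is.null(cand) || length(cand) == 0L) return(character(0))
  sort(cand[vapply(cand, function(id) {
    any(vapply(index$tokens[[id]],
               function(tk) length(phrase_starts(tk, member_tokens)) > 0L,
               logical(1)))
  }, logical(1))])
}

#' Persist an index to a directory
#'
#' The on-disk layout is private but versioned: the corpus is written as
#' JSON-lines and re-indexed on load, which keeps the format small and
#' guarantees that load(save(x)) equals rebuilding from the same records.
#'
#' @param index A `bio_index`.
#' @param dir Directory path (created if needed).
#' @export
save_index <- function(index, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- list(format = "bioranker-index", version = 1L, N = index$N)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE),
             file.path(dir, "index.json"))
  write_records(index$records, file.path(dir, "records.jsonl"))
  invisible(dir)
}

#' Load an index saved by [save_index()]
#'
#' @param dir Directory written by [save_index()].
#' @return A `bio_index`.
#' @export
load_index <- function(dir) {
  meta_path <- file.path(dir, "index.json")
  if (!file.exists(meta_path)) stop("not an index directory: ", dir)
  meta <- jsonlite::fromJSON(meta_path)
  if (!identical(meta$format, "bioranker-index"))
    stop("unrecognized index format in ", dir)
  if (meta$version > 1L) stop("index version ", meta$version, " not supported")
  build_index(read_records(file.path(dir, "records.jsonl")))
}
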
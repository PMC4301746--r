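#' Load the 20-query benchmark
#'
#' Twenty trait-centred information-retrieval use cases expressed as
#' keyword queries, spanning trait, biological-entity, taxonomy,
#' affiliation, metabolic-function and regulatory-function query classes.
#' Shipped with the package as a TSV fixture.
#'
#' @param path Optional alternative fixture path (defaults to the shipped
#'   benchmark).
#' @return A data frame with columns `query_class`, `subquery_class`,
#'   `query` (20 rows).
#' @export
load_benchmark <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "benchmark_queries.tsv",
                        package = "bioranker")
  if (!nzchar(path) || !file.exists(path))
    stop("benchmark fixture not found")
  bm <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          encoding = "UTF-8")
  need <- c("query_class", "subquery_class", "query")
  if (!identical(names(bm), need))
    stop("benchmark fixture is corrupt: expected columns ",
         paste(need, collapse = ", "))
  if (any(!nzchar(bm$query_class) | !nzchar(bm$subquery_class) |
          !nzchar(bm$query)))
    stop("benchmark fixture is corrupt: empty fields")
  bm
}

#' Sample result elements for relevance judgment
#'
#' Per query, draws up to `quota` records uniformly without replacement
#' from that query's result list, with a seeded generator so the judgment
#' sample is reproducible.
#'
#' @param results_per_query Named list: query string -> character vector of
#'   result record ids (ranked or not; sampling is uniform).
#' @param quota Maximum records judged per query (default 20).
#' @param seed Integer RNG seed.
#' @return A data frame with columns `query`, `record_id`.
#' @export
sample_for_judgment <- function(results_per_query, quota = 20L, seed = 1L) {
  stopifnot(quota >= 1L)
  if (length(results_per_query) == 0L)
    return(data.frame(query = character(0), record_id = character(0),
                      stringsAsFactors = FALSE))
  with_seed(seed, {
    out <- lapply(names(results_per_query), function(q) {
      ids <- results_per_query[[q]]
      if (length(ids) == 0L)
        return(data.frame(query = character(0), record_id = character(0),
                          stringsAsFactors = FALSE))
      take <- min(quota, length(ids))
      data.frame(query = q, record_id = sample(ids, take, replace = FALSE),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
}

#' Write / read graded judgments as TSV
#'
#' Columns: query, record_id, label; no header. Persisting judgments lets
#' the same judgment set be re-used across rankers.
#'
#' @param judgments Data frame with `query`, `record_id`, `label`.
#' @param path File path.
#' @export
write_judgments <- function(judgments, path) {
  bad <- setdiff(unique(judgments$label), RELEVANCE_LABELS)
  if (length(bad)) stop("unknown relevance label: ", bad[1])
  writeLines(paste(judgments$query, judgments$record_id, judgments$label,
                   sep = "\t"), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_judgments
#' @export
read_judgments <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3L))
    stop("judgment file must have 3 tab-separated columns")
  out <- data.frame(
    query = vapply(parts, `[[`, character(1), 1),
    record_id = vapply(parts, `[[`, character(1), 2),
    label = vapply(parts, `[[`, character(1), 3),
    stringsAsFactors = FALSE
  )
  bad <- setdiff(unique(out$label), RELEVANCE_LABELS)
  if (length(bad)) stop("unknown relevance label: ", bad[1])
  out
}

#' Per-class score distributions of judged results
#'
#' For each ranker and each of the five relevance classes, computes the
#' five-number summary (min, q1, median, q3, max; quartiles as type-7
#' sample quantiles) of the scores the ranker assigned to the judged
#' items of that class. Classes with no judgments are marked empty rather
#' than zero.
#'
#' @param judgments Data frame with `query`, `record_id`, `label`.
#' @param scores Named list: ranker name -> data frame with `query`,
#'   `record_id`, `score` covering every judged pair.
#' @return An `eval_report`: list with `summaries` (data frame: ranker,
#'   label, n, min, q1, median, q3, max) and the judged score table.
#' @export
score_distributions <- function(judgments, scores) {
  judged <- judgments
  for (ranker in names(scores)) {
    sc <- scores[[ranker]]
    key_j <- paste(judged$query, judged$record_id, sep = "\r")
    key_s <- paste(sc$query, sc$record_id, sep = "\r")
    pos <- match(key_j, key_s)
    if (anyNA(pos)) {
      miss <- which(is.na(pos))[1]
      stop("no '", ranker, "' score for judged pair (",
           judged$query[miss], ", ", judged$record_id[miss], ")")
    }
    judged[[ranker]] <- sc$score[pos]
  }
  rows <- list()
  for (ranker in names(scores)) {
    for (lab in RELEVANCE_LABELS) {
      x <- judged[[ranker]][judged$label == lab]
      if (length(x) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          ranker = ranker, label = lab, n = 0L, min = NA_real_,
          q1 = NA_real_, median = NA_real_, q3 = NA_real_, max = NA_real_,
          stringsAsFactors = FALSE)
      } else {
        q <- unname(stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), type = 7))
        rows[[length(rows) + 1L]] <- data.frame(
          ranker = ranker, label = lab, n = length(x), min = q[1],
          q1 = q[2], median = q[3], q3 = q[4], max = q[5],
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(summaries = do.call(rbind, rows), judged = judged),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  print(x$summaries, digits = 3)
  if (!is.null(x$auc)) {
    cat("separation AUC (no relevance vs rest):\n")
    for (r in names(x$auc)) cat("  ", r, ": ", round(x$auc[[r]], 4), "\n",
                                sep = "")
  }
  invisible(x)
}

#' Mann-Whitney separation AUC: relevant vs non-relevant
#'
#' The probability that a uniformly random item judged in any class above
#' "no relevance" outscores a uniformly random "no relevance" item, with
#' ties counted one half. 0.5 means no separation, 1 perfect separation.
#'
#' @param judgments Data frame with `query`, `record_id`, `label`; must
#'   contain at least one "no relevance" judgment and one judgment in the
#'   other classes.
#' @param scores Numeric vector of ranker scores aligned with the rows of
#'   `judgments`.
#' @return A real in `[0,1]`.
#' @export
separation_auc <- function(judgments, scores) {
  if (length(scores) != nrow(judgments))
    stop("scores must align with judgments")
  neg <- scores[judgments$label == RELEVANCE_LABELS[1]]
  pos <- scores[judgments$label != RELEVANCE_LABELS[1]]
  if (length(neg) == 0L) stop("no 'no relevance' judgments")
  if (length(pos) == 0L) stop("no relevant-side judgments")
  r <- rank(c(pos, neg))  # mean ranks give ties weight 1/2
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Run the full graded-relevance evaluation protocol
#'
#' The class-separation experiment comparing the neural ranker with the
#' TF-IDF vector-space baseline on a corpus with known graded labels:
#'
#' 1. index the corpus and run every benchmark query through the TF-IDF
#'    ranker to obtain each query's hit list;
#' 2. sample up to `quota` labelled results per query for judgment
#'    (seeded, without replacement);
#' 3. split the judged items into training and held-out halves, train the
#'    neural ranker on the training half (features + equally spaced class
#'    targets), and score the held-out half with both rankers;
#' 4. report per-class five-number score summaries and the Mann-Whitney
#'    no-relevance-vs-rest separation AUC for each ranker.
#'
#' @param records List of `bio_record`s.
#' @param gold Data frame of gold judgments (`query`, `record_id`, `label`).
#' @param queries Character vector of query strings (default: the shipped
#'   benchmark queries).
#' @param config A `feature_config`.
#' @param quota Judgments sampled per query (default 20).
#' @param seed Integer seed driving sampling, the train/test split and
#'   network initialization.
#' @param learning_rate,epochs Training configuration (see
#'   [train_network()]).
#' @param train_fraction Fraction of judged items used for training
#'   (default 0.5).
#' @return An `eval_report` with `summaries`, `auc` (named list per
#'   ranker), `judged` (held-out scored items) and `n_judged`.
#' @export
evaluate_rankers <- function(records, gold,
                             queries = load_benchmark()$query,
                             config = feature_config(),
                             quota = 20L, seed = 1L,
                             learning_rate = 0.5, epochs = 1500L,
                             train_fraction = 0.5) {
  index <- build_index(records)

  # hit lists restricted to gold-labelled records: the synthetic expert can
  # only judge records whose true class is known for that query
  results <- list()
  tfidf_scores <- list()
  for (q in queries) {
    ranked <- tfidf_rank(unique(tokenize(q)), index)
    labelled <- gold$record_id[gold$query == q]
    ranked <- ranked[ranked$record_id %in% labelled, , drop = FALSE]
    results[[q]] <- ranked$record_id
    tfidf_scores[[q]] <- ranked
  }

  pairs <- sample_for_judgment(results, quota = quota, seed = seed)
  key_g <- paste(gold$query, gold$record_id, sep = "\r")
  key_p <- paste(pairs$query, pairs$record_id, sep = "\r")
  pairs$label <- gold$label[match(key_p, key_g)]

  # features + scores for every judged pair
  feats <- matrix(NA_real_, nrow(pairs), 11,
                  dimnames = list(NULL, FEATURE_NAMES))
  tf_sc <- numeric(nrow(pairs))
  for (q in unique(pairs$query)) {
    spec <- parse_query(q)
    rows <- which(pairs$query == q)
    sc <- tfidf_scores[[q]]
    for (i in rows) {
      id <- pairs$record_id[i]
      ctx <- hit_context(spec, id, index)
      feats[i, ] <- extract_features(spec, index$records[[id]], ctx, index,
                                     config)
      tf_sc[i] <- sc$score[match(id, sc$record_id)]
    }
  }

  n <- nrow(pairs)
  train_idx <- with_seed(seed + 1L,
                         sample(n, size = max(1L, round(train_fraction * n))))
  test_idx <- setdiff(seq_len(n), train_idx)
  if (length(test_idx) == 0L) stop("train_fraction leaves no held-out items")

  network <- init_network(seed + 2L)
  network <- train_network(network, feats[train_idx, , drop = FALSE],
                           label_to_target(pairs$label[train_idx]),
                           learning_rate = learning_rate, epochs = epochs)

  held <- pairs[test_idx, , drop = FALSE]
  neural <- data.frame(query = held$query, record_id = held$record_id,
                       score = predict_relevance(
                         network, feats[test_idx, , drop = FALSE]),
                       stringsAsFactors = FALSE)
  tfidf <- data.frame(query = held$query, record_id = held$record_id,
                      score = tf_sc[test_idx], stringsAsFactors = FALSE)

  report <- score_distributions(held, list(neural = neural, tfidf = tfidf))
  report$auc <- list(
    neural = separation_auc(held, neural$score),
    tfidf = separation_auc(held, tfidf$score)
  )
  report$n_judged <- n
  report$n_held_out <- length(test_idx)
  report$network <- network
  report
}

#' Write an evaluation report as JSON and flat CSV
#'
#' @param report An `eval_report` from [evaluate_rankers()] or
#'   [score_distributions()].
#' @param json_path,csv_path Output paths (either may be `NULL` to skip).
#' @export
write_eval_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    doc <- list(summaries = report$summaries)
    if (!is.null(report$auc)) doc$auc <- report$auc
    if (!is.null(report$n_judged)) doc$n_judged <- report$n_judged
    writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                dataframe = "rows", na = "null"),
               json_path)
  }
  if (!is.null(csv_path))
    utils::write.csv(report$summaries, csv_path, row.names = FALSE,
                     na = "")
  invisible(report)
}
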
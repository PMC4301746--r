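test_that("the benchmark fixture holds the 20 keyword queries", {
  bm <- load_benchmark()
  expect_equal(nrow(bm), 20L)
  expect_true(all(nzchar(bm$query)))
  expect_equal(bm$query[bm$subquery_class == "Cultivar name"],
               "Barley Morex")
  expect_true(any(bm$query_class == "Trait" &
                  bm$subquery_class == "Stress response" &
                  bm$query == "Salt stress"))
  expect_true(any(bm$query_class == "Biological entity" &
                  bm$subquery_class == "Gene name/ID" &
                  bm$query == "WUS Arabidopsis"))
  expect_true(any(bm$query_class == "Metabolic function" &
                  bm$subquery_class == "Catalytic process" &
                  bm$query == "Sucrose synthase"))
  # corrupt fixtures are rejected
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("wrong\theader", "x\ty"), bad)
  expect_error(load_benchmark(bad), "corrupt")
})

test_that("judgment sampling is deterministic, distinct, and quota-bound", {
  results <- list("query one" = sprintf("r%03d", 1:100),
                  "query two" = sprintf("s%03d", 1:5),
                  "query three" = character(0))
  s1 <- sample_for_judgment(results, quota = 20L, seed = 5L)
  s2 <- sample_for_judgment(results, quota = 20L, seed = 5L)
  expect_identical(s1, s2)
  expect_equal(sum(s1$query == "query one"), 20L)
  expect_equal(sum(s1$query == "query two"), 5L)    # min(quota, available)
  expect_equal(sum(s1$query == "query three"), 0L)
  expect_false(anyDuplicated(s1[s1$query == "query one", "record_id"]) > 0)
  expect_false(identical(s1$record_id,
                         sample_for_judgment(results, 20L, 6L)$record_id))
  # full quota arithmetic
  many <- stats::setNames(rep(list(sprintf("r%03d", 1:50)), 20),
                          paste("q", 1:20))
  expect_equal(nrow(sample_for_judgment(many, quota = 20L, seed = 1L)),
               400L)
})

test_that("judgments round-trip through TSV and validate labels", {
  j <- data.frame(query = c("q1", "q2"), record_id = c("r1", "r2"),
                  label = c("fully agree", "no relevance"),
                  stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_judgments(j, path)
  expect_equal(read_judgments(path), j)
  j$label[1] <- "sort of"
  expect_error(write_judgments(j, path), "sort of")
})

make_judged <- function(labels, scores) {
  n <- length(labels)
  list(judgments = data.frame(query = rep("q", n),
                              record_id = sprintf("r%02d", seq_len(n)),
                              label = labels, stringsAsFactors = FALSE),
       scores = data.frame(query = rep("q", n),
                           record_id = sprintf("r%02d", seq_len(n)),
                           score = scores, stringsAsFactors = FALSE))
}

test_that("score distributions give five-number summaries per class", {
  # constant scores collapse every summary to the constant
  jd <- make_judged(rep(RELEVANCE_LABELS, each = 2), rep(0.3, 10))
  rep1 <- score_distributions(jd$judgments, list(r = jd$scores))
  expect_true(all(rep1$summaries$n == 2L))
  for (col in c("min", "q1", "median", "q3", "max"))
    expect_true(all(rep1$summaries[[col]] == 0.3))

  # single class median
  jd2 <- make_judged(rep("undecided", 3), c(0.1, 0.2, 0.3))
  rep2 <- score_distributions(jd2$judgments, list(r = jd2$scores))
  row <- rep2$summaries[rep2$summaries$label == "undecided", ]
  expect_equal(row$median, 0.2)
  # absent classes are marked empty, not zero
  empty_rows <- rep2$summaries[rep2$summaries$label != "undecided", ]
  expect_true(all(empty_rows$n == 0L))
  expect_true(all(is.na(empty_rows$median)))

  # randomized inputs match an order-statistics oracle
  set.seed(21)
  labels <- sample(RELEVANCE_LABELS, 60, replace = TRUE)
  scores <- runif(60)
  jd3 <- make_judged(labels, scores)
  rep3 <- score_distributions(jd3$judgments, list(r = jd3$scores))
  for (lab in unique(labels)) {
    want <- brute_fivenum(scores[labels == lab])
    row <- rep3$summaries[rep3$summaries$label == lab, ]
    expect_equal(unlist(row[c("min", "q1", "median", "q3", "max")]),
                 want, tolerance = 1e-12, ignore_attr = TRUE)
  }

  # a judged pair without a score is an error naming the pair
  expect_error(
    score_distributions(jd2$judgments,
                        list(r = jd2$scores[-2, , drop = FALSE])),
    "r02")
})

test_that("separation AUC equals the brute-force pairwise probability", {
  lab6 <- c(rep("no relevance", 3), rep("fully agree", 3))
  # perfect separation
  jd <- make_judged(lab6, c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9))
  expect_equal(separation_auc(jd$judgments, jd$scores$score), 1.0)
  # identical scores everywhere: all ties
  jd2 <- make_judged(lab6, rep(0.5, 6))
  expect_equal(separation_auc(jd2$judgments, jd2$scores$score), 0.5)
  # mixed 3-vs-3 equals enumerating all 9 pairs
  sc <- c(0.4, 0.9, 0.2, 0.5, 0.9, 0.1)
  jd3 <- make_judged(lab6, sc)
  expect_equal(separation_auc(jd3$judgments, jd3$scores$score),
               brute_auc(pos = sc[4:6], neg = sc[1:3]))
  # randomized agreement with the enumeration oracle
  set.seed(13)
  for (i in 1:10) {
    labs <- sample(RELEVANCE_LABELS, 30, replace = TRUE)
    if (!any(labs == "no relevance") || all(labs == "no relevance")) next
    s <- round(runif(30), 2)  # rounding forces ties
    jd4 <- make_judged(labs, s)
    expect_equal(separation_auc(jd4$judgments, jd4$scores$score),
                 brute_auc(s[labs != "no relevance"],
                           s[labs == "no relevance"]))
  }
  # one side empty is an error
  jd5 <- make_judged(rep("fully agree", 3), c(0.1, 0.2, 0.3))
  expect_error(separation_auc(jd5$judgments, jd5$scores$score),
               "no relevance")
})

test_that("the full protocol is seeded and end-to-end deterministic", {
  spec <- corpus_spec(n_records = 240L, seed = 17L)
  corpus <- generate_corpus(spec)
  cfg <- synthetic_feature_config(spec)
  r1 <- evaluate_rankers(corpus$records, corpus$gold, config = cfg,
                         quota = 5L, seed = 2L, epochs = 200L)
  r2 <- evaluate_rankers(corpus$records, corpus$gold, config = cfg,
                         quota = 5L, seed = 2L, epochs = 200L)
  expect_identical(r1$summaries, r2$summaries)
  expect_identical(r1$auc, r2$auc)
  expect_equal(r1$n_judged, 100L)  # 20 queries x quota 5
  # report files are written and byte-identical across reruns
  j1 <- withr::local_tempfile(fileext = ".json")
  j2 <- withr::local_tempfile(fileext = ".json")
  c1 <- withr::local_tempfile(fileext = ".csv")
  write_eval_report(r1, json_path = j1, csv_path = c1)
  write_eval_report(r2, json_path = j2)
  expect_identical(readLines(j1), readLines(j2))
  expect_true(file.exists(c1))
})
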
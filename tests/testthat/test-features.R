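# index whose single record has one attribute with the given tokens
one_attr_index <- function(tokens, ...) {
  build_index(list(record("r1", "db",
                          list(description = paste(tokens, collapse = " ")),
                          ...)))
}

test_that("proximity scoring rewards tight, in-order term windows", {
  # single matched term anywhere
  expect_equal(proximity_score(list(c(0L))), 1.0)
  expect_equal(proximity_score(list(c(5L, 17L))), 1.0)
  # [sucrose, synthase, activity], query "sucrose synthase": span 2 in order
  expect_equal(proximity_score(list(0L, 1L)), 1.0)
  # [synthase, x, sucrose]: span 3, out of order
  expect_equal(proximity_score(list(2L, 0L)), (2 / 3) * 0.8)
  # reversing a 2-term in-order window multiplies the score by exactly 0.8
  for (gap in 1:4) {
    in_order <- proximity_score(list(0L, as.integer(gap)))
    reversed <- proximity_score(list(as.integer(gap), 0L))
    expect_equal(reversed, in_order * 0.8, info = paste("gap", gap))
  }
  # minimal window is found among several occurrences
  expect_equal(proximity_score(list(c(0L, 10L), c(5L, 11L))), 2 / 2)
  expect_error(proximity_score(list()), "at least one")
  expect_error(proximity_score(list(integer(0))), "at least one")
})

test_that("keyword context scores 0, 0.5 or 1 by window membership", {
  cfg0 <- feature_config()
  expect_equal(keyword_context_score(c(2L), c("aa", "bb", "cc"), cfg0), 0.5)
  cfg <- feature_config(good_keywords = "characterized",
                        bad_keywords = "fragment")
  toks <- c("sucrose", "characterized", "filler", "filler", "filler",
            "filler", "filler", "filler", "fragment")
  expect_equal(keyword_context_score(0L, toks, cfg), 1.0)   # good adjacent
  expect_equal(keyword_context_score(4L, toks, cfg), 0.5)   # both in window
  expect_equal(keyword_context_score(8L, toks, cfg), 0.0)   # bad adjacent
  toksb <- c("sucrose", "fragment")
  expect_equal(keyword_context_score(0L, toksb, cfg), 0.0)  # bad only
  # outside the window: neutral
  far <- c("sucrose", rep("x1", 10), "characterized")
  expect_equal(keyword_context_score(0L, far, cfg), 0.5)
})

test_that("feature extraction reproduces hand-evaluated components", {
  idx <- one_attr_index(c("sucrose", "synthase", "activity", "in", "barley"))
  spec <- expand_synonyms(c("sucrose", "synthase"))
  ctx <- hit_context(spec, "r1", idx)
  f <- extract_features(spec, idx$records[["r1"]], ctx, idx)
  expect_named(f, FEATURE_NAMES)
  expect_equal(unname(f["text_position_coverage"]), 2 / 5)
  expect_equal(unname(f["cooccurrence"]), 1.0)
  expect_equal(unname(f["synonym_origin"]), 1.0)
  expect_equal(unname(f["organism_match"]), 0.5)
  expect_equal(unname(f["sequence_length_norm"]), 0.0)
  expect_equal(unname(f["query_coverage"]), 1.0)
  expect_equal(unname(f["term_frequency"]), 2 / 5)
  expect_equal(unname(f["attribute_weight"]), 0.5)
  expect_equal(unname(f["database_weight"]), 0.5)
})

test_that("a record with no query-term match gets the no-match defaults", {
  idx <- one_attr_index(c("unrelated", "filler", "tokens"))
  spec <- expand_synonyms(c("sucrose", "synthase"))
  ctx <- hit_context(spec, "r1", idx)
  f <- extract_features(spec, idx$records[["r1"]], ctx, idx)
  expect_equal(unname(f[c("term_frequency", "cooccurrence",
                          "text_position_coverage", "query_coverage",
                          "synonym_origin")]),
               rep(0, 5))
  expect_equal(unname(f[c("attribute_weight", "keyword_context",
                          "organism_match")]),
               rep(0.5, 3))
})

test_that("sequence length is log-normalized against the cap", {
  idx <- one_attr_index("barley", sequence_length = 999)
  spec <- expand_synonyms("barley")
  ctx <- hit_context(spec, "r1", idx)
  f <- extract_features(spec, idx$records[["r1"]], ctx, idx)
  expect_equal(unname(f["sequence_length_norm"]),
               log10(1000) / log10(100001), tolerance = 1e-12)
  # capped at 1 beyond the configured maximum
  cfg <- feature_config(length_cap = 100)
  idx2 <- one_attr_index("barley", sequence_length = 10000)
  f2 <- extract_features(spec, idx2$records[["r1"]],
                         hit_context(spec, "r1", idx2), idx2, cfg)
  expect_equal(unname(f2["sequence_length_norm"]), 1.0)
})

test_that("organism agreement distinguishes match, mismatch, and silence", {
  spec_org <- expand_synonyms(c("wus", "arabidopsis"))
  idx_same <- one_attr_index(c("wus", "meristem"),
                             organism = "Arabidopsis thaliana")
  idx_diff <- one_attr_index(c("wus", "meristem"),
                             organism = "Hordeum vulgare")
  idx_none <- one_attr_index(c("wus", "meristem"))
  get_org <- function(idx, spec) {
    ctx <- hit_context(spec, "r1", idx)
    unname(extract_features(spec, idx$records[["r1"]], ctx,
                            idx)["organism_match"])
  }
  expect_equal(get_org(idx_same, spec_org), 1.0)
  expect_equal(get_org(idx_diff, spec_org), 0.0)
  expect_equal(get_org(idx_none, spec_org), 0.5)
  # query naming no organism is silent regardless of the record
  expect_equal(get_org(idx_same, expand_synonyms("wus")), 0.5)
})

test_that("synonym-only hits are flagged by origin", {
  tab <- synonym_table(list(thermotolerance = "heatsafe"))
  idx <- one_attr_index(c("heatsafe", "filler"))
  spec <- expand_synonyms("thermotolerance", tab)
  ctx <- hit_context(spec, "r1", idx)
  f <- extract_features(spec, idx$records[["r1"]], ctx, idx)
  expect_equal(unname(f["synonym_origin"]), 0.0)
  expect_equal(unname(f["query_coverage"]), 1.0)
})

test_that("every extracted vector is 11-dimensional inside [0,1]", {
  spec_corpus <- corpus_spec(n_records = 60L, seed = 7L)
  corpus <- generate_corpus(spec_corpus)
  idx <- build_index(corpus$records)
  cfg <- synthetic_feature_config(spec_corpus)
  for (q in unique(corpus$gold$query)[1:10]) {
    spec <- parse_query(q)
    for (id in corpus$gold$record_id[corpus$gold$query == q]) {
      ctx <- hit_context(spec, id, idx)
      f <- extract_features(spec, idx$records[[id]], ctx, idx, cfg)
      expect_length(f, 11L)
      expect_named(f, FEATURE_NAMES)
      expect_true(all(f >= 0 & f <= 1), info = paste(q, id))
    }
  }
})

test_that("self-concatenating every attribute preserves the ratio features", {
  rec1 <- record("r1", "db",
                 list(description = "sucrose synthase activity in barley",
                      functional_note = "cleaves sucrose in vivo"))
  doubled <- lapply(rec1$attributes, function(x) paste(x, x))
  rec2 <- record("r1", "db", doubled)
  spec <- expand_synonyms(c("sucrose", "synthase"))
  f1 <- local({
    idx <- build_index(list(rec1))
    extract_features(spec, rec1, hit_context(spec, "r1", idx), idx)
  })
  f2 <- local({
    idx <- build_index(list(rec2))
    extract_features(spec, rec2, hit_context(spec, "r1", idx), idx)
  })
  expect_equal(f1["term_frequency"], f2["term_frequency"])
  expect_equal(f1["text_position_coverage"], f2["text_position_coverage"])
})

test_that("inconsistent hit contexts are rejected", {
  idx <- one_attr_index(c("barley", "yield"))
  spec <- expand_synonyms("barley")
  ctx <- hit_context(spec, "r1", idx)
  other <- record("r2", "db", list(a = "x y"))
  expect_error(extract_features(spec, other, ctx, idx), "belong")
  ctx2 <- ctx
  ctx2$group_matched <- c(TRUE, TRUE, TRUE)
  expect_error(extract_features(spec, idx$records[["r1"]], ctx2, idx),
               "inconsistent")
})
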
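test_that("edit distance matches a memoized recursive oracle", {
  cases <- list(c("barlye", "barley"), c("barlye", "parley"),
                c("maiz", "maize"), c("", "abc"), c("abc", ""),
                c("ca", "abc"), c("abc", "abc"))
  for (p in cases)
    expect_equal(dl_distance(p[1], p[2]), brute_dl(p[1], p[2]),
                 info = paste(p, collapse = "/"))
  # randomized property over a small alphabet (transposition-rich)
  set.seed(42)
  for (i in 1:100) {
    a <- paste(sample(letters[1:4], sample(0:7, 1), replace = TRUE),
               collapse = "")
    b <- paste(sample(letters[1:4], sample(0:7, 1), replace = TRUE),
               collapse = "")
    expect_equal(dl_distance(a, b), brute_dl(a, b),
                 info = paste(a, b, sep = "/"))
  }
})

spelling_index <- function(terms) {
  # one record per term so collection frequency can be controlled by
  # repeating terms inside the text
  build_index(lapply(seq_along(terms), function(i)
    record(sprintf("r%02d", i), "db", list(a = terms[i]))))
}

test_that("spelling suggestions respect distance bounds and ranking", {
  idx <- spelling_index(c("barley", "parley"))
  # a vocabulary term needs no correction
  expect_identical(correct_spelling("barley", idx), character(0))
  # transposition distance 1, substitutionx2 distance 2
  expect_identical(correct_spelling("barlye", idx), c("barley", "parley"))
  # 4-letter term: bound is 1
  idx2 <- spelling_index("maize")
  expect_identical(correct_spelling("maiz", idx2), "maize")
  expect_identical(correct_spelling("mz", idx2), character(0))
  expect_error(correct_spelling("x", build_index(list())), "empty")
})

test_that("suggestions exclude the input and satisfy the distance bound", {
  vocab <- c("barley", "barely", "parley", "yield", "yields", "maize",
             "stress", "starch", "stars")
  idx <- spelling_index(vocab)
  for (term in c("barlye", "yeild", "maiez", "stres", "strach", "bar")) {
    sug <- correct_spelling(term, idx)
    expect_false(term %in% sug)
    bound <- if (nchar(term) <= 4) 1L else 2L
    for (s in sug) expect_lte(brute_dl(term, s), bound)
    # completeness: every in-bound vocabulary word is suggested
    inbound <- vocab[vapply(vocab, function(v)
      brute_dl(term, v) <= bound, logical(1))]
    expect_setequal(sug, setdiff(inbound, term))
  }
})

test_that("collection frequency breaks distance ties", {
  # "tb" and "tc" both at distance 1 from "ta"; make "tc" more frequent
  idx <- build_index(list(record("r1", "db", list(a = "tb")),
                          record("r2", "db", list(a = "tc tc tc"))))
  expect_identical(correct_spelling("ta", idx), c("tc", "tb"))
})

test_that("synonym expansion builds one-level groups with origins", {
  # empty table: singleton exact groups, order preserved
  spec <- expand_synonyms(c("salt", "stress"))
  expect_s3_class(spec, "query_spec")
  expect_length(spec$groups, 2L)
  expect_identical(spec$groups[[1]]$members[[1]],
                   list(tokens = "salt", origin = "exact"))

  tab <- synonym_table(list(thermotolerance = "heat tolerance"))
  spec <- expand_synonyms("thermotolerance", tab)
  m <- spec$groups[[1]]$members
  expect_length(m, 2L)
  expect_identical(m[[1]], list(tokens = "thermotolerance", origin = "exact"))
  expect_identical(m[[2]],
                   list(tokens = c("heat", "tolerance"), origin = "synonym"))

  # chains are not followed transitively
  tab2 <- synonym_table(list(aa = "bb", bb = "cc"))
  spec2 <- expand_synonyms("aa", tab2)
  flat <- unlist(lapply(spec2$groups[[1]]$members, `[[`, "tokens"))
  expect_true("bb" %in% flat)
  expect_false("cc" %in% flat)
})

test_that("synonym tables drop self-synonyms and are case-insensitive", {
  tab <- synonym_table(list(Barley = c("barley", "Hordeum")))
  expect_identical(tab[["barley"]], "hordeum")
  spec <- expand_synonyms("BARLEY", tab)
  expect_length(spec$groups[[1]]$members, 2L)
})

test_that("synonym tables round-trip through TSV and OBO", {
  tab <- synonym_table(list(thermotolerance = c("heat tolerance"),
                            yield = c("crop output", "harvest")))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_synonym_tsv(tab, tsv)
  expect_identical(unclass(read_synonym_tsv(tsv)), unclass(tab))
  obo <- withr::local_tempfile(fileext = ".obo")
  write_synonym_obo(tab, obo)
  expect_identical(unclass(read_synonym_obo(obo)), unclass(tab))
})

test_that("OBO parsing reads Term stanzas and ignores scope tags", {
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: TO:0000001", "name: salt stress",
    "synonym: \"salinity stress\" EXACT []",
    "synonym: \"NaCl stress\" BROAD []", "",
    "[Typedef]", "id: part_of", "name: part of", "",
    "[Term]", "id: TO:0000002", "name: plain term"
  ), path)
  tab <- read_synonym_obo(path)
  expect_setequal(tab[["salt stress"]],
                  c("salinity stress", "nacl stress"))
  expect_null(tab[["plain term"]])
  expect_null(tab[["part of"]])
})

test_that("related entries follow brute-force pairwise cosine order", {
  # corpus of one record: nothing to suggest
  idx1 <- build_index(list(record("only", "db", list(a = "barley yield"))))
  expect_equal(nrow(suggest_related("only", idx1, k = 3)), 0L)

  # exact duplicate ranks first with similarity 1
  recs <- toy_records()
  dup <- record("rec0dup", recs[[1]]$source_db, recs[[1]]$attributes)
  idx <- build_index(c(recs, list(dup)))
  got <- suggest_related("rec1", idx, k = 3)
  expect_equal(got$record_id[1], "rec0dup")
  expect_equal(got$similarity[1], 1.0, tolerance = 1e-12)

  # order equals brute-force pairwise cosine on the 4-record corpus
  all_recs <- c(recs, list(dup))
  ids <- vapply(all_recs, function(r) r$record_id, character(1))
  toks <- lapply(all_recs, function(r)
    unlist(lapply(r$attributes, tokenize)))
  names(toks) <- ids
  vocab <- sort(unique(unlist(toks)))
  df <- vapply(vocab, function(t)
    sum(vapply(toks, function(tk) t %in% tk, logical(1))), numeric(1))
  dense <- function(id) {
    tf <- vapply(vocab, function(t) sum(toks[[id]] == t), numeric(1))
    tf * (1 + log(length(all_recs) / df))
  }
  brute_sim <- function(a, b) {
    wa <- dense(a); wb <- dense(b)
    sum(wa * wb) / (sqrt(sum(wa^2)) * sqrt(sum(wb^2)))
  }
  others <- setdiff(sort(ids), "rec1")
  want <- vapply(others, function(b) brute_sim("rec1", b), numeric(1))
  ord <- order(-want, others)
  got_all <- suggest_related("rec1", idx, k = 10)
  expect_identical(got_all$record_id, others[ord])
  # similarity in [0,1] and symmetric
  expect_true(all(got_all$similarity >= 0 & got_all$similarity <= 1))
  for (b in others)
    expect_equal(brute_sim("rec1", b), brute_sim(b, "rec1"),
                 tolerance = 1e-9)

  expect_error(suggest_related("ghost", idx), "ghost")
})
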
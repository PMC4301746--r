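#' Specification of a synthetic graded-relevance corpus
#'
#' Defines the generative conditions for a toy corpus with planted,
#' class-correlated relevance signal. For each benchmark query, records
#' are generated in one of the five relevance classes; higher classes
#' receive (on average) more of the query's terms, tighter and in-order
#' term proximity, a better-weighted attribute and source database,
#' stronger organism agreement, good rather than bad context keywords,
#' longer described sequences, and better annotation evidence. Lexical
#' filler text is drawn from a pseudo-word vocabulary
#' (consonant-vowel syllables) that cannot collide with query terms.
#'
#' All `class_*` vectors run from "no relevance" (first element) to
#' "fully agree" (last). `noise` shrinks every class profile toward its
#' mean: 0 gives the full planted effect, 1 erases all class signal.
#'
#' @param n_records Corpus size (default 1000).
#' @param n_databases Number of source databases (default 4; the first is
#'   the "curated" one that higher classes favour).
#' @param attributes Named numeric: attribute name -> mean token length.
#' @param vocab_size Pseudo-word vocabulary size.
#' @param organisms Organism labels records are drawn from.
#' @param class_mix Proportions of the five classes (sums to 1).
#' @param class_term_density Per-class probability that each query term is
#'   planted in a record.
#' @param class_proximity Per-class probability that planted terms appear
#'   as one contiguous in-order phrase rather than scattered.
#' @param class_organism_agreement Per-class probability that a record's
#'   organism matches the query's organism (when the query names one).
#' @param class_db_curated Per-class probability of the curated database.
#' @param class_attr_primary Per-class probability that terms are planted
#'   in the first (highest-weighted) attribute rather than the last.
#' @param class_keyword_good Per-class probability that a planted context
#'   keyword is a good one rather than a bad one.
#' @param class_seq_loglen Per-class mean log10 sequence length (sd 0.4).
#' @param class_evidence_probs 5x3 matrix of per-class HC/LC/NA evidence
#'   probabilities (rows sum to 1), consumed by [generate_mappings()].
#' @param keyword_rate Probability a record carries a context keyword.
#' @param noise Class-signal shrinkage in `[0,1]` (default 0.1).
#' @param seed Integer RNG seed.
#' @return An object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_records = 1000L,
                        n_databases = 4L,
                        attributes = c(description = 30, functional_note = 25,
                                       comment = 40),
                        vocab_size = 500L,
                        organisms = c("Hordeum vulgare",
                                      "Arabidopsis thaliana",
                                      "Oryza sativa", "Zea mays"),
                        class_mix = rep(0.2, 5),
                        class_term_density = c(0.30, 0.45, 0.60, 0.75, 0.90),
                        class_proximity = c(0.10, 0.30, 0.50, 0.70, 0.90),
                        class_organism_agreement = c(0.10, 0.30, 0.50, 0.70, 0.90),
                        class_db_curated = c(0.10, 0.25, 0.40, 0.55, 0.70),
                        class_attr_primary = c(0.20, 0.35, 0.50, 0.65, 0.80),
                        class_keyword_good = c(0.10, 0.30, 0.50, 0.70, 0.90),
                        class_seq_loglen = c(1.0, 1.8, 2.6, 3.4, 4.2),
                        class_evidence_probs = default_evidence_probs(),
                        keyword_rate = 0.7,
                        noise = 0.1,
                        seed = 1L) {
  spec <- as.list(environment())
  if (abs(sum(class_mix) - 1) > 1e-9) stop("class_mix must sum to 1")
  if (n_records < 1L || n_databases < 1L || vocab_size < 1L)
    stop("all counts must be >= 1")
  for (v in list(class_term_density, class_proximity,
                 class_organism_agreement, class_db_curated,
                 class_attr_primary, class_keyword_good)) {
    if (length(v) != 5L || any(v < 0) || any(v > 1))
      stop("class probability vectors must have 5 entries in [0,1]")
  }
  if (!is.matrix(class_evidence_probs) ||
      !all(dim(class_evidence_probs) == c(5L, 3L)) ||
      any(abs(rowSums(class_evidence_probs) - 1) > 1e-9))
    stop("class_evidence_probs must be a 5x3 matrix with rows summing to 1")
  if (noise < 0 || noise > 1) stop("noise must lie in [0,1]")
  structure(spec, class = "corpus_spec")
}

#' Per-class HC/LC/NA evidence probabilities (default)
#'
#' @return A 5x3 matrix, rows from "no relevance" to "fully agree",
#'   columns HC, LC, NA.
#' @export
default_evidence_probs <- function() {
  m <- cbind(HC = c(0.10, 0.25, 0.40, 0.55, 0.70),
             LC = c(0.30, 0.30, 0.30, 0.28, 0.22),
             `NA` = c(0.60, 0.45, 0.30, 0.17, 0.08))
  rownames(m) <- RELEVANCE_LABELS
  m
}

# Shrink a class-probability profile toward its mean by the noise fraction.
shrink_profile <- function(p, noise) mean(p) + (p - mean(p)) * (1 - noise)

#' Deterministic pseudo-word vocabulary
#'
#' Words are three consonant-vowel syllables chosen by the base-70
#' digits of the word's rank, so the vocabulary is reproducible without
#' any RNG and cannot collide with real query terms.
#'
#' @param n Number of words.
#' @param offset Rank offset (used to build disjoint vocabularies, e.g.
#'   for synonym pseudo-words).
#' @return Character vector of `n` distinct words.
#' @export
make_pseudo_words <- function(n, offset = 0L) {
  consonants <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s",
                  "t", "v", "z")
  vowels <- c("a", "e", "i", "o", "u")
  syl <- as.vector(outer(consonants, vowels, paste0))  # 70 syllables
  vapply(seq_len(n) + offset - 1L, function(i) {
    paste0(syl[(i %/% 4900L) %% 70L + 1L],
           syl[(i %/% 70L) %% 70L + 1L],
           syl[i %% 70L + 1L])
  }, character(1))
}

# insert values into a vector at random positions (0-based result order)
insert_at_random <- function(base, values) {
  for (v in values) {
    pos <- sample.int(length(base) + 1L, 1L)
    base <- append(base, v, after = pos - 1L)
  }
  base
}

#' Generate a graded synthetic corpus with gold judgments
#'
#' Records are generated per benchmark query and relevance class according
#' to the corpus specification; every record contains at least one query
#' term so all generated records are lexically retrievable. The gold
#' judgment table pairs each record with its generating query and true
#' class label.
#'
#' @param spec A `corpus_spec`.
#' @param queries Character vector of query strings (default: the shipped
#'   benchmark queries).
#' @return A list with `records` (list of `bio_record`), `gold` (data
#'   frame: query, record_id, label) and `classes` (integer class index
#'   1-5 per record).
#' @export
generate_corpus <- function(spec, queries = load_benchmark()$query) {
  stopifnot(inherits(spec, "corpus_spec"))
  vocab <- make_pseudo_words(spec$vocab_size)
  dbs <- c("curated_db", paste0("source_db_", seq_len(spec$n_databases - 1L)))
  attr_names <- names(spec$attributes)
  primary_attr <- attr_names[1]
  last_attr <- attr_names[length(attr_names)]

  density <- shrink_profile(spec$class_term_density, spec$noise)
  proximity <- shrink_profile(spec$class_proximity, spec$noise)
  org_agree <- shrink_profile(spec$class_organism_agreement, spec$noise)
  db_curated <- shrink_profile(spec$class_db_curated, spec$noise)
  attr_primary <- shrink_profile(spec$class_attr_primary, spec$noise)
  kw_good <- shrink_profile(spec$class_keyword_good, spec$noise)

  good_kw <- default_good_keywords()
  bad_kw <- default_bad_keywords()

  with_seed(spec$seed, {
    n_q <- length(queries)
    per_query <- diff(round(seq(0, spec$n_records, length.out = n_q + 1)))
    records <- vector("list", spec$n_records)
    gold_q <- character(spec$n_records)
    gold_l <- character(spec$n_records)
    classes <- integer(spec$n_records)
    k <- 0L

    for (qi in seq_len(n_q)) {
      q <- queries[qi]
      qtokens <- tokenize(q)
      q_org <- query_organism(qtokens, spec$organisms)
      for (r in seq_len(per_query[qi])) {
        k <- k + 1L
        cls <- sample.int(5L, 1L, prob = spec$class_mix)

        # filler text per attribute
        attrs <- lapply(spec$attributes, function(mu)
          sample(vocab, max(1L, stats::rpois(1, mu)), replace = TRUE))

        # planted query terms
        planted <- qtokens[stats::runif(length(qtokens)) < density[cls]]
        if (length(planted) == 0L)
          planted <- qtokens[sample.int(length(qtokens), 1L)]
        target_attr <- if (stats::runif(1) < attr_primary[cls]) primary_attr
                       else last_attr
        base <- attrs[[target_attr]]
        if (stats::runif(1) < proximity[cls]) {
          pos <- sample.int(length(base) + 1L, 1L)
          base <- append(base, planted, after = pos - 1L)
        } else {
          base <- insert_at_random(base, planted)
        }
        # occasional extra occurrences
        extra <- planted[stats::runif(length(planted)) < 0.3]
        if (length(extra)) base <- insert_at_random(base, extra)

        # context keyword adjacent to a planted term
        if (stats::runif(1) < spec$keyword_rate) {
          kw <- if (stats::runif(1) < kw_good[cls]) sample(good_kw, 1L)
                else sample(bad_kw, 1L)
          anchor <- which(base %in% planted)[1]
          base <- append(base, kw, after = anchor)
        }
        attrs[[target_attr]] <- base

        organism <- if (is.null(q_org)) {
          sample(spec$organisms, 1L)
        } else if (stats::runif(1) < org_agree[cls]) {
          q_org
        } else {
          sample(setdiff(spec$organisms, q_org), 1L)
        }

        db <- if (stats::runif(1) < db_curated[cls]) dbs[1]
              else sample(dbs[-1], 1L)

        seq_len_val <- max(1L, round(10^stats::rnorm(
          1, mean = spec$class_seq_loglen[cls], sd = 0.4)))

        records[[k]] <- record(
          record_id = sprintf("R%05d", k),
          source_db = db,
          attributes = lapply(attrs, paste, collapse = " "),
          organism = organism,
          sequence_length = min(seq_len_val, 10^7),
          cross_refs = character(0)
        )
        gold_q[k] <- q
        gold_l[k] <- RELEVANCE_LABELS[cls]
        classes[k] <- cls
      }
    }

    # one-hop cross-references (0-2 per record), assigned once ids exist
    ids <- vapply(records, function(r) r$record_id, character(1))
    for (i in seq_along(records)) {
      n_refs <- sample.int(3L, 1L) - 1L
      if (n_refs > 0L)
        records[[i]]$cross_refs <- sample(ids[-i], n_refs)
    }

    list(records = records,
         gold = data.frame(query = gold_q, record_id = ids, label = gold_l,
                           stringsAsFactors = FALSE),
         classes = classes)
  })
}

# Canonical organism named by query tokens, or NULL.
query_organism <- function(qtokens, organisms) {
  taxonomy <- default_taxonomy()
  taxonomy <- taxonomy[names(taxonomy) %in% organisms]
  hits <- names(taxonomy)[vapply(taxonomy, function(alias)
    any(tolower(qtokens) %in% alias), logical(1))]
  if (length(hits)) hits[1] else NULL
}

#' Default good / bad context keyword lists
#'
#' Pseudo-word-free English tokens the generator plants next to query
#' matches: curation-flavoured words as good keywords, quality-doubt
#' words as bad keywords. The same lists are the defaults the evaluation
#' harness configures the feature extractor with.
#'
#' @return Character vector.
#' @export
default_good_keywords <- function() {
  c("characterized", "validated", "curated", "confirmed")
}

#' @rdname default_good_keywords
#' @export
default_bad_keywords <- function() {
  c("fragment", "putative", "uncharacterized", "predicted")
}

#' Feature configuration matched to the synthetic generator
#'
#' Attribute and database weights reflecting the generator's planted
#' quality gradient (the curated database and the first attribute carry
#' more weight), plus the generator's keyword lists and the built-in
#' taxonomy.
#'
#' @param spec A `corpus_spec` (defaults supply the attribute names).
#' @return A `feature_config`.
#' @export
synthetic_feature_config <- function(spec = corpus_spec()) {
  attr_names <- names(spec$attributes)
  aw <- stats::setNames(
    seq(0.8, 0.4, length.out = length(attr_names)), attr_names)
  dbs <- c("curated_db",
           paste0("source_db_", seq_len(spec$n_databases - 1L)))
  dw <- stats::setNames(
    c(0.9, seq(0.5, 0.3, length.out = spec$n_databases - 1L)), dbs)
  feature_config(attribute_weights = aw, database_weights = dw,
                 good_keywords = default_good_keywords(),
                 bad_keywords = default_bad_keywords())
}

#' Generate a synthetic gene-to-record mapping table
#'
#' Each record receives 0-3 gene links; evidence classes are drawn
#' independently from `evidence_probs`.
#'
#' @param records List of `bio_record`s.
#' @param seed Integer RNG seed.
#' @param evidence_probs Named probabilities over HC, LC, NA (sums to 1).
#' @return Data frame with `gene_id`, `record_id`, `evidence`.
#' @export
generate_mappings <- function(records, seed = 1L,
                              evidence_probs = c(HC = 0.4, LC = 0.3,
                                                 `NA` = 0.3)) {
  if (length(evidence_probs) != 3L || any(evidence_probs < 0) ||
      abs(sum(evidence_probs) - 1) > 1e-9)
    stop("evidence_probs must be 3 non-negative values summing to 1")
  ids <- vapply(records, function(r) r$record_id, character(1))
  genes <- sprintf("G%04d", seq_len(max(50L, length(ids) %/% 2L)))
  with_seed(seed, {
    rows <- lapply(ids, function(id) {
      n_links <- sample.int(4L, 1L) - 1L
      if (n_links == 0L) return(NULL)
      data.frame(gene_id = sample(genes, n_links),
                 record_id = id,
                 evidence = sample(c("HC", "LC", "NA"), n_links,
                                   replace = TRUE, prob = evidence_probs),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- data.frame(gene_id = character(0), record_id = character(0),
                        evidence = character(0), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

#' Generate a synthetic synonym table
#'
#' Each vocabulary term receives one synonym with probability `rate`.
#' Synonyms are pseudo-words from a vocabulary range disjoint from every
#' generated corpus, so hits produced only by synonym expansion are
#' detectable.
#'
#' @param vocabulary Character vector of terms.
#' @param seed Integer RNG seed.
#' @param rate Probability in `[0,1]` that a term gets a synonym.
#' @return A `synonym_table`.
#' @export
generate_synonym_table <- function(vocabulary, seed = 1L, rate = 0.2) {
  if (rate < 0 || rate > 1) stop("rate must lie in [0,1]")
  with_seed(seed, {
    pick <- stats::runif(length(vocabulary)) < rate
    terms <- vocabulary[pick]
    syns <- make_pseudo_words(length(terms), offset = 200000L)
    mapping <- stats::setNames(as.list(syns), terms)
    synonym_table(mapping)
  })
}
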
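# Small fixture corpora and independent brute-force oracles used across
# the suite. Oracles deliberately avoid the package's index machinery.

toy_records <- function() {
  list(
    record(
      "rec1", "uniprot",
      list(description = "Sucrose synthase activity in barley",
           functional_note = "catalyzes sucrose cleavage"),
      organism = "Hordeum vulgare", sequence_length = 805
    ),
    record(
      "rec2", "ensembl",
      list(description = "putative synthase fragment",
           functional_note = "barley barley leaf tissue"),
      organism = "Hordeum vulgare"
    ),
    record(
      "rec3", "pdb",
      list(description = "photosystem II core protein",
           functional_note = "maize chloroplast membrane"),
      organism = "Zea mays", sequence_length = 353,
      cross_refs = c("rec1")
    )
  )
}

# brute-force document frequency: scan every record's tokenized attributes
brute_df <- function(records, term) {
  sum(vapply(records, function(r)
    term %in% unlist(lapply(r$attributes, tokenize)), logical(1)))
}

# brute-force TF-IDF cosine scores, computed from full dense vectors
brute_tfidf <- function(query_terms, records) {
  N <- length(records)
  toks <- lapply(records, function(r) unlist(lapply(r$attributes, tokenize)))
  vocab <- sort(unique(unlist(toks)))
  df <- vapply(vocab, function(t) brute_df(records, t), numeric(1))
  q <- unique(query_terms)
  q <- q[q %in% vocab]
  if (length(q) == 0L) return(stats::setNames(numeric(0), character(0)))
  scores <- vapply(seq_along(records), function(i) {
    tf <- vapply(vocab, function(t) sum(toks[[i]] == t), numeric(1))
    w <- tf * (1 + log(N / df))
    qv <- as.numeric(vocab %in% q)
    denom <- sqrt(sum(w^2)) * sqrt(sum(qv^2))
    if (denom == 0) 0 else sum(w * qv) / denom
  }, numeric(1))
  names(scores) <- vapply(records, function(r) r$record_id, character(1))
  scores[scores > 0]
}

# brute-force restricted Damerau-Levenshtein by plain memoized recursion
brute_dl <- function(a, b) {
  s <- strsplit(a, "")[[1]]
  t <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- if (i == 0L) j else if (j == 0L) i else {
      cost <- as.integer(s[i] != t[j])
      best <- min(rec(i - 1L, j) + 1L, rec(i, j - 1L) + 1L,
                  rec(i - 1L, j - 1L) + cost)
      if (i > 1L && j > 1L && s[i] == t[j - 1L] && s[i - 1L] == t[j])
        best <- min(best, rec(i - 2L, j - 2L) + cost)
      best
    }
    memo[[key]] <- v
    v
  }
  rec(length(s), length(t))
}

# five-number summary from first principles (type-7 interpolation)
brute_fivenum <- function(x) {
  x <- sort(x)
  n <- length(x)
  qt <- function(p) {
    h <- (n - 1) * p
    lo <- floor(h)
    x[lo + 1] + (h - lo) * (if (lo + 2 <= n) x[lo + 2] - x[lo + 1] else 0)
  }
  c(min = x[1], q1 = qt(0.25), median = qt(0.5), q3 = qt(0.75), max = x[n])
}

# Mann-Whitney AUC by enumerating every (positive, negative) pair
brute_auc <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (q in neg)
    wins <- wins + if (p > q) 1 else if (p == q) 0.5 else 0
  wins / (length(pos) * length(neg))
}

# numerical gradient of the training loss by central differences
numeric_grad <- function(network, X, y, param, idx, h = 1e-5) {
  perturb <- function(delta) {
    net2 <- network
    net2[[param]][idx] <- net2[[param]][idx] + delta
    bioranker:::nn_loss_grads(net2, X, y)$loss
  }
  (perturb(h) - perturb(-h)) / (2 * h)
}
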
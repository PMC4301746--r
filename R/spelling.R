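#' Damerau-Levenshtein edit distance
#'
#' Restricted (optimal string alignment) edit distance counting insertions,
#' deletions, substitutions, and adjacent transpositions. Transpositions
#' matter for biological term typos ("barlye" -> "barley" is one edit, not
#' two), which is why plain Levenshtein is not used here.
#'
#' @param a,b Strings.
#' @return Non-negative integer distance.
#' @export
dl_distance <- function(a, b) {
  s <- strsplit(a, "")[[1]]
  t <- strsplit(b, "")[[1]]
  n <- length(s)
  m <- length(t)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1L] <- 0:n
  d[1L, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cost <- if (s[i] == t[j]) 0L else 1L
      d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L,   # deletion
                               d[i + 1L, j] + 1L,   # insertion
                               d[i, j] + cost)      # substitution
      if (i > 1L && j > 1L && s[i] == t[j - 1L] && s[i - 1L] == t[j])
        d[i + 1L, j + 1L] <- min(d[i + 1L, j + 1L], d[i - 1L, j - 1L] + cost)
    }
  }
  d[n + 1L, m + 1L]
}

#' Suggest spelling corrections for a query term
#'
#' Real-time spelling assistance against the index vocabulary. Candidates
#' must lie within Damerau-Levenshtein distance 1 for terms of up to four
#' characters, or distance 2 for longer terms; a term already present in
#' the vocabulary needs no correction and yields an empty list. Suggestions
#' are ranked by (distance ascending, collection frequency descending,
#' lexicographic), so frequent corpus terms are preferred among equally
#' close candidates. Corrections are suggested, never silently applied.
#'
#' @param term A single token.
#' @param index A `bio_index` whose vocabulary is searched.
#' @return Character vector of suggested terms (possibly empty).
#' @export
correct_spelling <- function(term, index) {
  vocab <- names(index$df)
  if (length(vocab) == 0L) stop("index vocabulary is empty")
  term <- tolower(term)
  if (term %in% vocab) return(character(0))
  max_d <- if (nchar(term) <= 4L) 1L else 2L
  # cheap length pre-filter: |len(a) - len(b)| bounds the distance
  cand <- vocab[abs(nchar(vocab) - nchar(term)) <= max_d]
  if (length(cand) == 0L) return(character(0))
  dist <- vapply(cand, dl_distance, integer(1), a = term)
  keep <- dist <= max_d
  cand <- cand[keep]
  dist <- dist[keep]
  if (length(cand) == 0L) return(character(0))
  freq <- unname(index$cf[cand])
  cand[order(dist, -freq, cand)]
}
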
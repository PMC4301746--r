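#' Construct a synonym table
#'
#' Maps a term (or phrase) to a set of synonym phrases. Lookup is
#' case-insensitive and self-synonyms are dropped.
#'
#' @param mapping Named list: term -> character vector of synonyms.
#' @return An object of class `synonym_table`.
#' @export
synonym_table <- function(mapping = list()) {
  if (length(mapping) && is.null(names(mapping)))
    stop("mapping must be named")
  out <- list()
  for (term in names(mapping)) {
    key <- tolower(trimws(term))
    syns <- tolower(trimws(as.character(mapping[[term]])))
    syns <- setdiff(unique(syns[nzchar(syns)]), key)
    if (length(syns))
      out[[key]] <- sort(unique(c(out[[key]], syns)))
  }
  structure(out, class = "synonym_table")
}

#' @export
print.synonym_table <- function(x, ...) {
  cat("<synonym_table>", length(x), "terms\n")
  invisible(x)
}

#' Read a two-column TSV synonym table
#'
#' Columns: term, synonym; no header; "#"-prefixed lines are skipped.
#'
#' @param path Path to a TSV file.
#' @return A `synonym_table`.
#' @export
read_synonym_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  mapping <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("line ", i, ": expected 2 tab-separated columns, got ",
           length(parts))
    mapping[[parts[1]]] <- c(mapping[[parts[1]]], parts[2])
  }
  synonym_table(mapping)
}

#' Write a synonym table as two-column TSV
#'
#' @param table A `synonym_table`.
#' @param path Output path.
#' @export
write_synonym_tsv <- function(table, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (term in names(table))
    for (s in table[[term]])
      writeLines(paste(term, s, sep = "\t"), con, useBytes = TRUE)
  invisible(path)
}

#' Read synonyms from an OBO 1.2 flat file
#'
#' Parses `[Term]` stanzas, taking each stanza's `name:` line as the term
#' and every `synonym: "..."` line as a synonym; synonym scope tags
#' (EXACT, BROAD, ...) are ignored. Obsolete-term handling, cross-products
#' and relationship lines are out of scope.
#'
#' @param path Path to an OBO file.
#' @return A `synonym_table`.
#' @export
read_synonym_obo <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  mapping <- list()
  in_term <- FALSE
  name <- NULL
  syns <- character(0)
  for (ln in lines) {
    ln <- trimws(ln)
    if (startsWith(ln, "[")) {
      if (in_term && !is.null(name) && length(syns))
        mapping[[name]] <- c(mapping[[name]], syns)
      in_term <- identical(ln, "[Term]")
      name <- NULL
      syns <- character(0)
    } else if (in_term && startsWith(ln, "name:")) {
      name <- trimws(sub("^name:", "", ln))
    } else if (in_term && startsWith(ln, "synonym:")) {
      m <- regmatches(ln, regexpr("\"[^\"]*\"", ln))
      if (length(m)) syns <- c(syns, substr(m, 2, nchar(m) - 1))
    }
  }
  if (in_term && !is.null(name) && length(syns))
    mapping[[name]] <- c(mapping[[name]], syns)
  synonym_table(mapping)
}

#' Write a synonym table as a minimal OBO 1.2 file
#'
#' @param table A `synonym_table`.
#' @param path Output path.
#' @export
write_synonym_obo <- function(table, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("format-version: 1.2", con, useBytes = TRUE)
  i <- 0L
  for (term in names(table)) {
    i <- i + 1L
    writeLines(c("", "[Term]", sprintf("id: SYN:%07d", i),
                 paste0("name: ", term),
                 sprintf("synonym: \"%s\" EXACT []", table[[term]])),
               con, useBytes = TRUE)
  }
  invisible(path)
}

new_query_spec <- function(raw, groups) {
  structure(list(raw = raw, groups = groups), class = "query_spec")
}

#' Expand query tokens with table synonyms
#'
#' Each token becomes a term group containing the token itself (origin
#' "exact") plus its table synonyms (origin "synonym"). Multi-word synonyms
#' are kept as phrase members and later match as contiguous token
#' sequences. Expansion is one level only: synonym chains are not followed.
#'
#' @param tokens Character vector from [tokenize()].
#' @param table A `synonym_table` (or `NULL` for no expansion).
#' @param raw Original query string recorded on the result (optional).
#' @return A `query_spec`: ordered list of groups, each a list of members
#'   `list(tokens = <character>, origin = "exact"|"synonym"|"corrected")`.
#' @export
expand_synonyms <- function(tokens, table = NULL, raw = paste(tokens, collapse = " ")) {
  groups <- lapply(tokens, function(tok) {
    members <- list(list(tokens = tok, origin = "exact"))
    if (!is.null(table)) {
      for (s in table[[tolower(tok)]]) {
        syn_tokens <- tokenize(s)
        if (length(syn_tokens))
          members[[length(members) + 1L]] <-
            list(tokens = syn_tokens, origin = "synonym")
      }
    }
    list(members = members)
  })
  new_query_spec(raw, groups)
}

#' @export
print.query_spec <- function(x, ...) {
  cat("<query_spec> \"", x$raw, "\", ", length(x$groups), " groups\n", sep = "")
  for (g in x$groups) {
    cat(" -", paste(vapply(g$members, function(m)
      sprintf("%s[%s]", paste(m$tokens, collapse = " "), m$origin),
      character(1)), collapse = " | "), "\n")
  }
  invisible(x)
}

#' Parse a raw query string into an expanded query specification
#'
#' Tokenizes the query and applies synonym expansion. When an index is
#' supplied, out-of-vocabulary tokens additionally receive their top
#' spelling suggestion as a member with origin "corrected" (only if
#' `apply_corrections` is set; by default corrections are reported to the
#' user, not applied).
#'
#' @param raw Free-text query.
#' @param synonyms Optional `synonym_table`.
#' @param index Optional `bio_index` used for spelling correction.
#' @param apply_corrections Add the best spelling suggestion of unknown
#'   terms to their group (default `FALSE`).
#' @return A `query_spec`.
#' @export
parse_query <- function(raw, synonyms = NULL, index = NULL,
                        apply_corrections = FALSE) {
  tokens <- tokenize(raw)
  spec <- expand_synonyms(tokens, synonyms, raw = raw)
  if (apply_corrections && !is.null(index) && length(index$df)) {
    for (i in seq_along(spec$groups)) {
      tok <- tokens[i]
      if (!tok %in% names(index$df)) {
        sug <- correct_spelling(tok, index)
        if (length(sug))
          spec$groups[[i]]$members[[length(spec$groups[[i]]$members) + 1L]] <-
            list(tokens = sug[1], origin = "corrected")
      }
    }
  }
  spec
}
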
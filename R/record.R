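#' Construct a database record
#'
#' A record is one entry of a biological fact database: a unique identifier,
#' the name of its source database, an ordered set of named free-text
#' attributes (e.g. "description", "function", "comment"), an optional
#' organism label, an optional sequence length (residues or bases), and an
#' optional list of cross-referenced record identifiers.
#'
#' @param record_id Non-empty string, unique within a corpus.
#' @param source_db Name of the origin database.
#' @param attributes Named list (or named character vector) of attribute
#'   name -> free text; at least one attribute must hold non-empty text.
#' @param organism Optional taxon label string.
#' @param sequence_length Optional non-negative integer.
#' @param cross_refs Character vector of related record identifiers.
#' @return An object of class `bio_record`.
#' @export
record <- function(record_id, source_db, attributes, organism = NULL,
                   sequence_length = NULL, cross_refs = character(0)) {
  if (!is.character(record_id) || length(record_id) != 1L || !nzchar(record_id))
    stop("record_id must be a non-empty string")
  if (!is.character(source_db) || length(source_db) != 1L)
    stop("source_db must be a string")
  attributes <- as.list(attributes)
  if (length(attributes) == 0L || is.null(names(attributes)) ||
      any(!nzchar(names(attributes))))
    stop("attributes must be a non-empty named list")
  attributes <- lapply(attributes, function(x) as.character(x)[1])
  if (!any(nzchar(unlist(attributes))))
    stop("record '", record_id, "' needs at least one non-empty attribute")
  if (!is.null(sequence_length)) {
    sequence_length <- as.integer(sequence_length)
    if (is.na(sequence_length) || sequence_length < 0L)
      stop("sequence_length must be a non-negative integer")
  }
  if (!is.null(organism)) organism <- as.character(organism)[1]
  structure(
    list(record_id = record_id, source_db = source_db,
         attributes = attributes, organism = organism,
         sequence_length = sequence_length,
         cross_refs = as.character(cross_refs)),
    class = "bio_record"
  )
}

#' @export
print.bio_record <- function(x, ...) {
  cat("<bio_record>", x$record_id, "[", x$source_db, "]\n")
  if (!is.null(x$organism)) cat("  organism:", x$organism, "\n")
  if (!is.null(x$sequence_length)) cat("  sequence_length:", x$sequence_length, "\n")
  for (a in names(x$attributes)) {
    txt <- x$attributes[[a]]
    if (nchar(txt) > 60) txt <- paste0(substr(txt, 1, 57), "...")
    cat("  ", a, ": ", txt, "\n", sep = "")
  }
  if (length(x$cross_refs))
    cat("  cross_refs:", paste(x$cross_refs, collapse = ", "), "\n")
  invisible(x)
}

#' Read records from a JSON-lines file
#'
#' One JSON object per line with keys `record_id`, `source_db`, `attributes`
#' (object of name -> text), and optional `organism`, `sequence_length`,
#' `cross_refs`. UTF-8.
#'
#' @param path Path to a JSON-lines file.
#' @return A list of `bio_record` objects.
#' @export
read_records <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e)
                      stop("malformed JSON on line ", i, ": ", conditionMessage(e)))
    record(
      record_id = obj$record_id, source_db = obj$source_db,
      attributes = obj$attributes, organism = obj$organism,
      sequence_length = obj$sequence_length,
      cross_refs = if (is.null(obj$cross_refs)) character(0)
                   else as.character(unlist(obj$cross_refs))
    )
  })
}

#' Write records to a JSON-lines file
#'
#' Inverse of [read_records()]; optional fields are omitted when absent.
#'
#' @param records List of `bio_record` objects.
#' @param path Output path.
#' @export
write_records <- function(records, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (r in records) {
    obj <- list(record_id = r$record_id, source_db = r$source_db,
                attributes = r$attributes)
    if (!is.null(r$organism)) obj$organism <- r$organism
    if (!is.null(r$sequence_length)) obj$sequence_length <- r$sequence_length
    if (length(r$cross_refs)) obj$cross_refs <- as.list(r$cross_refs)
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), con, useBytes = TRUE)
  }
  invisible(path)
}
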
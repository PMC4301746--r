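#' Load a gene-to-record mapping file
#'
#' Mapping files link genes to functional annotation records. Format:
#' 3-column TSV (gene_id, record_id, evidence), UTF-8, no header;
#' "#"-prefixed comment lines are skipped. Evidence is one of `HC`
#' (high-confidence), `LC` (low-confidence) or `NA`; a blank evidence
#' column means `NA` (rendered "N/A" in output).
#'
#' @param path Path to a mapping TSV.
#' @return A data frame with columns `gene_id`, `record_id`, `evidence`
#'   and `line` (source line number, for diagnostics).
#' @export
load_mappings <- function(path) {
  if (!file.exists(path)) stop("mapping file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(lines, "#"))
  rows <- lapply(keep, function(i) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    # a trailing empty field (blank evidence) is dropped by strsplit
    if (length(parts) == 2L && grepl("\t$", lines[i])) parts <- c(parts, "")
    if (length(parts) != 3L)
      stop("line ", i, ": expected 3 tab-separated columns, got ",
           length(parts))
    ev <- trimws(parts[3])
    if (!nzchar(ev)) ev <- "NA"
    if (!ev %in% c("HC", "LC", "NA"))
      stop("line ", i, ": unknown evidence token '", ev,
           "' (expected HC, LC, NA or blank)")
    if (!nzchar(parts[1]) || !nzchar(parts[2]))
      stop("line ", i, ": empty gene_id or record_id")
    list(gene_id = parts[1], record_id = parts[2], evidence = ev, line = i)
  })
  data.frame(
    gene_id = vapply(rows, `[[`, character(1), "gene_id"),
    record_id = vapply(rows, `[[`, character(1), "record_id"),
    evidence = vapply(rows, `[[`, character(1), "evidence"),
    line = vapply(rows, `[[`, integer(1), "line"),
    stringsAsFactors = FALSE
  )
}

#' Write a mapping table as 3-column TSV
#'
#' `NA` evidence is written as a blank third column, the form understood
#' by [load_mappings()].
#'
#' @param mappings Data frame with `gene_id`, `record_id`, `evidence`.
#' @param path Output path.
#' @export
write_mappings <- function(mappings, path) {
  ev <- ifelse(mappings$evidence == "NA", "", mappings$evidence)
  writeLines(paste(mappings$gene_id, mappings$record_id, ev, sep = "\t"),
             path, useBytes = TRUE)
  invisible(path)
}

#' Resolve evidence-sorted gene-annotation links for a hit record
#'
#' Direct links are mapping entries pointing at the hit record itself;
#' indirect links are entries pointing at one of the hit record's
#' cross-references (exactly one hop). Links are ordered direct before
#' indirect; within each, by evidence class HC, then LC, then N/A; within
#' equal evidence, by ascending gene identifier.
#'
#' @param record_id Identifier of the hit record.
#' @param mappings Mapping table from [load_mappings()].
#' @param index A `bio_index` containing the record (supplies cross_refs).
#' @return A data frame with columns `gene_id`, `via_record_id`,
#'   `directness` ("direct"/"indirect") and `evidence` ("HC"/"LC"/"N/A").
#' @export
resolve_links <- function(record_id, mappings, index) {
  if (!record_id %in% names(index$records))
    stop("unknown record_id: ", record_id)
  rec <- index$records[[record_id]]
  direct <- mappings[mappings$record_id == record_id, , drop = FALSE]
  indirect <- mappings[mappings$record_id %in% rec$cross_refs, , drop = FALSE]

  fmt <- function(df, directness) {
    if (nrow(df) == 0L)
      return(data.frame(gene_id = character(0), via_record_id = character(0),
                        directness = character(0), evidence = character(0),
                        stringsAsFactors = FALSE))
    ev_rank <- match(df$evidence, c("HC", "LC", "NA"))
    df <- df[order(ev_rank, df$gene_id), , drop = FALSE]
    data.frame(gene_id = df$gene_id, via_record_id = df$record_id,
               directness = directness,
               evidence = ifelse(df$evidence == "NA", "N/A", df$evidence),
               stringsAsFactors = FALSE)
  }
  out <- rbind(fmt(direct, "direct"), fmt(indirect, "indirect"))
  rownames(out) <- NULL
  out
}

# Render links as the compact "gene|directness|evidence;..." export form.
format_links <- function(links) {
  if (is.null(links) || nrow(links) == 0L) return("")
  paste(paste(links$gene_id, links$directness, links$evidence, sep = "|"),
        collapse = ";")
}
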
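#' Export ranked search results as CSV or XLSX
#'
#' One row per result with a fixed, versioned 17-column schema: `rank`,
#' `record_id`, `source_db`, `score`, the 11 feature columns in
#' [FEATURE_NAMES] order, `excerpt`, and `links`
#' (semicolon-joined `gene_id|directness|evidence`). CSV is RFC-4180
#' quoted UTF-8 with scores rendered at full double precision so a
#' re-parse reproduces them exactly; XLSX carries identical cell values.
#'
#' @param results A data frame of search results as returned by
#'   [search_records()] (columns `rank`, `record_id`, `source_db`,
#'   `score`, features, `excerpt`, `links`); may have zero rows.
#' @param path Output file path.
#' @param format "csv" or "xlsx" (default: inferred from the file
#'   extension, falling back to csv).
#' @return The path, invisibly.
#' @export
export_results <- function(results, path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.xlsx$", path, ignore.case = TRUE)) "xlsx"
              else "csv"
  format <- match.arg(format, c("csv", "xlsx"))
  cols <- c("rank", "record_id", "source_db", "score", FEATURE_NAMES,
            "excerpt", "links")
  missing_cols <- setdiff(cols, names(results))
  if (length(missing_cols))
    stop("results lack required columns: ",
         paste(missing_cols, collapse = ", "))
  df <- results[, cols, drop = FALSE]

  # full-precision decimal rendering for all numeric cells
  cells <- df
  for (j in seq_along(cells)) {
    if (is.numeric(cells[[j]]) && !is.integer(cells[[j]]))
      cells[[j]] <- vapply(cells[[j]], function(x) sprintf("%.17g", x),
                           character(1))
    else cells[[j]] <- as.character(cells[[j]])
  }

  if (format == "csv") {
    quote_csv <- function(x) {
      needs <- grepl('[",\n\r]', x)
      x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
      x
    }
    lines <- c(paste(quote_csv(cols), collapse = ","),
               if (nrow(cells))
                 vapply(seq_len(nrow(cells)), function(i)
                   paste(quote_csv(unlist(cells[i, ])), collapse = ","),
                   character(1)))
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, useBytes = TRUE)
  } else {
    write_xlsx_sheet(rbind(cols, as.matrix(cells)), path)
  }
  invisible(path)
}

#' Re-read an exported CSV result file
#'
#' @param path A CSV written by [export_results()].
#' @return A data frame with the export schema and numeric columns
#'   restored.
#' @export
read_exported_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", encoding = "UTF-8")
  df$rank <- as.integer(df$rank)
  for (col in c("score", FEATURE_NAMES)) df[[col]] <- as.numeric(df[[col]])
  df
}

# ---- minimal XLSX writer -------------------------------------------------
# An .xlsx file is a ZIP container of OOXML parts. No xlsx writer or zip
# binary is assumed: parts are stored uncompressed in a hand-built ZIP
# (local file headers + central directory + CRC-32), with all strings as
# inline worksheet strings. Readers (Excel, openpyxl) accept stored
# entries.

crc32_table <- local({
  tab <- integer(256)
  poly <- -306674912L  # 0xEDB88320 as signed 32-bit
  for (i in 0:255) {
    r <- i
    for (k in 1:8) {
      r <- if (bitwAnd(r, 1L) != 0L)
        bitwXor(bitwShiftR(r, 1L), poly)
      else bitwShiftR(r, 1L)
    }
    tab[i + 1L] <- r
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L  # 0xFFFFFFFF
  for (b in as.integer(bytes)) {
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   crc32_table[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  }
  bitwXor(crc, -1L)
}

# little-endian byte encoding of a non-negative value (given as signed
# 32-bit int or double) over n bytes
le_bytes <- function(x, n) {
  if (is.integer(x) && x < 0) x <- x + 4294967296  # unsigned reinterpret
  x <- as.numeric(x)
  out <- raw(n)
  for (i in seq_len(n)) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

zip_store <- function(entries, path) {
  # entries: named list name -> raw content
  con <- file(path, open = "wb")
  on.exit(close(con))
  offsets <- integer(0)
  central <- list()
  offset <- 0
  dos_time <- le_bytes(0, 2)
  dos_date <- le_bytes(33, 2)  # 1980-01-01, fixed for determinism
  for (name in names(entries)) {
    data <- entries[[name]]
    nm <- charToRaw(name)
    crc <- crc32(data)
    header <- c(le_bytes(0x04034b50, 4), le_bytes(20, 2), le_bytes(0, 2),
                le_bytes(0, 2), dos_time, dos_date, le_bytes(crc, 4),
                le_bytes(length(data), 4), le_bytes(length(data), 4),
                le_bytes(length(nm), 2), le_bytes(0, 2))
    writeBin(c(header, nm, data), con)
    central[[name]] <- c(le_bytes(0x02014b50, 4), le_bytes(20, 2),
                         le_bytes(20, 2), le_bytes(0, 2), le_bytes(0, 2),
                         dos_time, dos_date, le_bytes(crc, 4),
                         le_bytes(length(data), 4), le_bytes(length(data), 4),
                         le_bytes(length(nm), 2), le_bytes(0, 2),
                         le_bytes(0, 2), le_bytes(0, 2), le_bytes(0, 2),
                         le_bytes(0, 4), le_bytes(offset, 4), nm)
    offset <- offset + length(header) + length(nm) + length(data)
  }
  cd <- do.call(c, unname(central))
  writeBin(cd, con)
  eocd <- c(le_bytes(0x06054b50, 4), le_bytes(0, 2), le_bytes(0, 2),
            le_bytes(length(central), 2), le_bytes(length(central), 2),
            le_bytes(length(cd), 4), le_bytes(offset, 4), le_bytes(0, 2))
  writeBin(eocd, con)
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

write_xlsx_sheet <- function(cells, path) {
  # cells: character matrix including the header row
  col_letter <- function(j) {
    s <- ""
    while (j > 0) {
      s <- paste0(LETTERS[(j - 1) %% 26 + 1], s)
      j <- (j - 1) %/% 26
    }
    s
  }
  rows_xml <- vapply(seq_len(nrow(cells)), function(i) {
    cs <- vapply(seq_len(ncol(cells)), function(j) {
      v <- cells[i, j]
      ref <- paste0(col_letter(j), i)
      sprintf('<c r="%s" t="inlineStr"><is><t xml:space="preserve">%s</t></is></c>',
              ref, xml_escape(v))
    }, character(1))
    sprintf('<row r="%d">%s</row>', i, paste(cs, collapse = ""))
  }, character(1))
  sheet <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    '<sheetData>', paste(rows_xml, collapse = ""), '</sheetData></worksheet>')
  content_types <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    '<Override PartName="/xl/worksheets/sheet1.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
    '</Types>')
  rels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    '</Relationships>')
  workbook <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    '<sheets><sheet name="results" sheetId="1" r:id="rId1"/></sheets></workbook>')
  wb_rels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet1.xml"/>',
    '</Relationships>')
  entries <- list(
    "[Content_Types].xml" = charToRaw(content_types),
    "_rels/.rels" = charToRaw(rels),
    "xl/workbook.xml" = charToRaw(workbook),
    "xl/_rels/workbook.xml.rels" = charToRaw(wb_rels),
    "xl/worksheets/sheet1.xml" = charToRaw(enc2utf8(sheet))
  )
  zip_store(entries, path)
}
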
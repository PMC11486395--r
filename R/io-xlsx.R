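# Minimal XLSX writing so generated fixtures can exercise the spreadsheet
# reader. Emits a store-only (uncompressed) OPC zip with one inline-string
# worksheet; numbers are written with 17 significant digits. No installed R
# package writes xlsx in this dependency set, hence the hand-rolled
# container; readers (readxl, Excel) accept stored entries.

.crc32le <- function(data) {
  hex <- digest::digest(data, algo = "crc32", serialize = FALSE)
  if (nchar(hex) < 8L) hex <- paste0(strrep("0", 8L - nchar(hex)), hex)
  rev(as.raw(strtoi(substring(hex, c(1, 3, 5, 7), c(2, 4, 6, 8)), 16L)))
}

.leBytes <- function(n, width) {
  r <- raw(width)
  for (i in seq_len(width)) {
    r[i] <- as.raw(n %% 256)
    n <- n %/% 256
  }
  r
}

# files: named list of raw vectors, names are archive paths
.writeZipStore <- function(files, zipPath) {
  con <- file(zipPath, "wb")
  on.exit(close(con))
  centrals <- vector("list", length(files))
  off <- 0L
  for (k in seq_along(files)) {
    data <- files[[k]]
    fn <- charToRaw(names(files)[k])
    crc <- .crc32le(data)
    lfh <- c(.leBytes(0x04034b50, 4), .leBytes(20, 2), .leBytes(0, 2),
             .leBytes(0, 2), .leBytes(0, 2), .leBytes(0, 2), crc,
             .leBytes(length(data), 4), .leBytes(length(data), 4),
             .leBytes(length(fn), 2), .leBytes(0, 2), fn)
    writeBin(lfh, con)
    writeBin(data, con)
    centrals[[k]] <- c(.leBytes(0x02014b50, 4), .leBytes(20, 2),
                       .leBytes(20, 2), .leBytes(0, 2), .leBytes(0, 2),
                       .leBytes(0, 2), .leBytes(0, 2), crc,
                       .leBytes(length(data), 4), .leBytes(length(data), 4),
                       .leBytes(length(fn), 2), .leBytes(0, 2),
                       .leBytes(0, 2), .leBytes(0, 2), .leBytes(0, 2),
                       .leBytes(0, 4), .leBytes(off, 4), fn)
    off <- off + length(lfh) + length(data)
  }
  cd <- do.call(c, centrals)
  writeBin(cd, con)
  writeBin(c(.leBytes(0x06054b50, 4), .leBytes(0, 2), .leBytes(0, 2),
             .leBytes(length(files), 2), .leBytes(length(files), 2),
             .leBytes(length(cd), 4), .leBytes(off, 4), .leBytes(0, 2)), con)
  invisible(zipPath)
}

.xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Write a data frame to a single-sheet XLSX file
#'
#' Numeric columns keep full double precision (17 significant digits);
#' everything else is written as inline strings.
#'
#' @param df a data.frame.
#' @param path output .xlsx path.
#' @return The path, invisibly.
#' @export
writeXlsx <- function(df, path) {
  colLetter <- function(j) {
    s <- ""
    while (j > 0) {
      s <- paste0(LETTERS[(j - 1) %% 26 + 1], s)
      j <- (j - 1) %/% 26
    }
    s
  }
  numCell <- function(ref, v) sprintf('<c r="%s"><v>%s</v></c>', ref,
                                      sprintf("%.17g", v))
  strCell <- function(ref, v)
    sprintf('<c r="%s" t="inlineStr"><is><t>%s</t></is></c>', ref,
            .xmlEscape(as.character(v)))
  rows <- character(nrow(df) + 1L)
  hdr <- vapply(seq_along(df), function(j)
    strCell(paste0(colLetter(j), 1L), names(df)[j]), "")
  rows[1] <- sprintf('<row r="1">%s</row>', paste(hdr, collapse = ""))
  isNum <- vapply(df, is.numeric, logical(1))
  for (i in seq_len(nrow(df))) {
    cells <- vapply(seq_along(df), function(j) {
      ref <- paste0(colLetter(j), i + 1L)
      if (isNum[j]) numCell(ref, df[[j]][i]) else strCell(ref, df[[j]][i])
    }, "")
    rows[i + 1L] <- sprintf('<row r="%d">%s</row>', i + 1L,
                            paste(cells, collapse = ""))
  }
  sheet <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    '<sheetData>', paste(rows, collapse = ""), '</sheetData></worksheet>')
  ct <- paste0(
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
  wb <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    '<sheets><sheet name="Sheet1" sheetId="1" r:id="rId1"/></sheets></workbook>')
  wbrels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet1.xml"/>',
    '</Relationships>')
  .writeZipStore(list(
    "[Content_Types].xml" = charToRaw(ct),
    "_rels/.rels" = charToRaw(rels),
    "xl/workbook.xml" = charToRaw(wb),
    "xl/_rels/workbook.xml.rels" = charToRaw(wbrels),
    "xl/worksheets/sheet1.xml" = charToRaw(sheet)), path)
}
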
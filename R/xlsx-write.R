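# Minimal single-sheet xlsx writer.
#
# An .xlsx file is a zip of a handful of XML parts; the generic qHTS layout
# only needs one worksheet of numeric and string cells, so the writer emits
# exactly that (inline strings, no shared-string table, no styles). Member
# timestamps are pinned so identical datasets produce byte-identical files.

col_letter <- function(j) {
  s <- ""
  while (j > 0) {
    r <- (j - 1L) %% 26L
    s <- paste0(LETTERS[r + 1L], s)
    j <- (j - 1L) %/% 26L
  }
  s
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

XLSX_STATIC <- list(
  "[Content_Types].xml" = paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    '<Override PartName="/xl/worksheets/sheet1.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
    '</Types>'),
  "_rels/.rels" = paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    '</Relationships>'),
  "xl/workbook.xml" = paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    '<sheets><sheet name="Sheet1" sheetId="1" r:id="rId1"/></sheets></workbook>'),
  "xl/_rels/workbook.xml.rels" = paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet1.xml"/>',
    '</Relationships>')
)

# txt: character matrix of cell texts ("" = empty cell);
# isnum: logical matrix marking cells written as numeric values.
write_cells_xlsx <- function(txt, isnum, path) {
  nr <- nrow(txt)
  nc <- ncol(txt)
  rows <- character(nr)
  for (i in seq_len(nr)) {
    cs <- character(0)
    for (j in seq_len(nc)) {
      v <- txt[i, j]
      if (is.na(v) || !nzchar(v)) next
      ref <- paste0(col_letter(j), i)
      cs <- c(cs, if (isnum[i, j]) {
        sprintf('<c r="%s"><v>%s</v></c>', ref, v)
      } else {
        sprintf('<c r="%s" t="inlineStr"><is><t xml:space="preserve">%s</t></is></c>',
                ref, xml_escape(v))
      })
    }
    rows[i] <- sprintf('<row r="%d">%s</row>', i, paste0(cs, collapse = ""))
  }
  sheet <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    '<sheetData>', paste0(rows, collapse = ""), '</sheetData></worksheet>')

  tmp <- tempfile("xlsx")
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  parts <- c(XLSX_STATIC, list("xl/worksheets/sheet1.xml" = sheet))
  for (nm in names(parts)) {
    dest <- file.path(tmp, nm)
    dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
    con <- file(dest, open = "wb")
    writeLines(parts[[nm]], con, sep = "")
    close(con)
  }
  files <- list.files(tmp, recursive = TRUE, all.files = TRUE, no.. = TRUE)
  # pin mtimes so equal content gives equal bytes
  for (f in file.path(tmp, files))
    Sys.setFileTime(f, as.POSIXct("2020-01-01 00:00:00", tz = "UTC"))
  if (file.exists(path)) unlink(path)
  zip::zip(zipfile = path, files = files, root = tmp,
           include_directories = FALSE)
  invisible(path)
}
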
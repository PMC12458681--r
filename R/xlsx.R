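# Minimal OOXML (.xlsx) workbook writer.
#
# A .xlsx file is a ZIP container of XML parts. This writer produces a
# single-sheet workbook with inline strings and solid background fills. The
# ZIP container is assembled directly: each member is deflate-compressed with
# memCompress(), whose gzip framing conveniently supplies both the raw
# deflate stream and the CRC32 checksum the ZIP directory needs. Timestamps
# are fixed so output is byte-deterministic.

.int2le <- function(x, nbytes) {
  # little-endian byte encoding of a non-negative (possibly > 2^31) value
  out <- raw(nbytes)
  for (k in seq_len(nbytes)) {
    out[k] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

.crcEnv <- new.env(parent = emptyenv())

.crc32Table <- function() {
  if (!is.null(.crcEnv$tab)) return(.crcEnv$tab)
  tab <- integer(256)
  poly <- -306674912L  # 0xEDB88320 in two's complement
  for (n in 0:255) {
    c <- n
    for (k in 1:8)
      c <- if (bitwAnd(c, 1L)) bitwXor(bitwShiftR(c, 1L), poly)
           else bitwShiftR(c, 1L)
    tab[n + 1] <- c
  }
  .crcEnv$tab <- tab
  tab
}

.crc32 <- function(bytes) {
  tab <- .crc32Table()
  crc <- -1L
  for (b in as.integer(bytes))
    crc <- bitwXor(bitwShiftR(crc, 8L), tab[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  crc <- bitwXor(crc, -1L)
  if (crc < 0) crc + 2^32 else as.numeric(crc)
}

.deflateMember <- function(content) {
  raw <- if (is.character(content)) charToRaw(paste(content, collapse = "\n"))
         else content
  z <- memCompress(raw, type = "gzip")  # zlib framing: 2-byte header,
  deflate <- z[3:(length(z) - 4)]       # deflate stream, 4-byte Adler32
  list(data = deflate, crc = .crc32(raw), size = length(raw))
}

# files: named list name -> character vector (lines) or raw
.writeZip <- function(files, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- numeric(length(files))
  members <- vector("list", length(files))
  pos <- 0
  dosTime <- .int2le(0, 2); dosDate <- .int2le(33, 2)  # fixed 1980-01-01
  for (k in seq_along(files)) {
    nm <- charToRaw(names(files)[k])
    m <- .deflateMember(files[[k]])
    members[[k]] <- m
    offsets[k] <- pos
    hdr <- c(charToRaw("PK\x03\x04"), .int2le(20, 2), .int2le(0, 2),
             .int2le(8, 2), dosTime, dosDate, .int2le(m$crc, 4),
             .int2le(length(m$data), 4), .int2le(m$size, 4),
             .int2le(length(nm), 2), .int2le(0, 2), nm)
    writeBin(hdr, con)
    writeBin(m$data, con)
    pos <- pos + length(hdr) + length(m$data)
  }
  cdStart <- pos
  for (k in seq_along(files)) {
    nm <- charToRaw(names(files)[k])
    m <- members[[k]]
    cd <- c(charToRaw("PK\x01\x02"), .int2le(20, 2), .int2le(20, 2),
            .int2le(0, 2), .int2le(8, 2), dosTime, dosDate,
            .int2le(m$crc, 4), .int2le(length(m$data), 4),
            .int2le(m$size, 4), .int2le(length(nm), 2), .int2le(0, 2),
            .int2le(0, 2), .int2le(0, 2), .int2le(0, 2), .int2le(0, 4),
            .int2le(offsets[k], 4), nm)
    writeBin(cd, con)
    pos <- pos + length(cd)
  }
  eocd <- c(charToRaw("PK\x05\x06"), .int2le(0, 2), .int2le(0, 2),
            .int2le(length(files), 2), .int2le(length(files), 2),
            .int2le(pos - cdStart, 4), .int2le(cdStart, 4), .int2le(0, 2))
  writeBin(eocd, con)
  invisible(path)
}

.xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.colLetter <- function(j) {
  out <- ""
  while (j > 0) {
    out <- paste0(LETTERS[(j - 1) %% 26 + 1], out)
    j <- (j - 1) %/% 26
  }
  out
}

# Fill palette: style index per (color, shade tier). ARGB hex.
.XLSX_FILLS <- c(
  none = "FFFFFFFF",
  blue1 = "FFC6DBEF", blue2 = "FF9ECAE1", blue3 = "FF4292C6",
  yellow1 = "FFFFF7BC", yellow2 = "FFFEE391", yellow3 = "FFFEC44F",
  green1 = "FFC7E9C0", green2 = "FFA1D99B", green3 = "FF41AB5D",
  gray1 = "FFD9D9D9", gray2 = "FFA6A6A6", gray3 = "FF595959")

# text: character matrix; fill: character matrix of palette keys ("" = none)
.writeXlsxMatrix <- function(text, fill, path) {
  nr <- nrow(text); nc <- ncol(text)
  fillKeys <- names(.XLSX_FILLS)
  styleOf <- function(key) match(key, fillKeys)  # 1-based; cellXf id = idx
  rowsXml <- vapply(seq_len(nr), function(i) {
    cells <- vapply(seq_len(nc), function(j) {
      v <- text[i, j]
      s <- if (nzchar(fill[i, j])) styleOf(fill[i, j]) else 1L
      if (!nzchar(v) && s == 1L) return("")
      sprintf('<c r="%s%d" s="%d" t="inlineStr"><is><t xml:space="preserve">%s</t></is></c>',
              .colLetter(j), i, s - 1L, .xmlEscape(v))
    }, character(1))
    sprintf('<row r="%d">%s</row>', i, paste(cells, collapse = ""))
  }, character(1))
  sheet <- c('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    "<sheetData>", rowsXml, "</sheetData>", "</worksheet>")
  fillsXml <- vapply(.XLSX_FILLS, function(argb) {
    sprintf('<fill><patternFill patternType="solid"><fgColor rgb="%s"/><bgColor rgb="%s"/></patternFill></fill>',
            argb, argb)
  }, character(1))
  styles <- c('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<styleSheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    '<fonts count="1"><font><sz val="11"/><name val="Calibri"/></font></fonts>',
    sprintf('<fills count="%d"><fill><patternFill patternType="none"/></fill><fill><patternFill patternType="gray125"/></fill>%s</fills>',
            length(.XLSX_FILLS) + 2, paste(fillsXml, collapse = "")),
    '<borders count="1"><border/></borders>',
    '<cellStyleXfs count="1"><xf/></cellStyleXfs>',
    sprintf('<cellXfs count="%d">%s</cellXfs>', length(.XLSX_FILLS),
            paste(sprintf('<xf fillId="%d" applyFill="1"/>',
                          seq_along(.XLSX_FILLS) + 1), collapse = "")),
    "</styleSheet>")
  files <- list(
    "[Content_Types].xml" = c(
      '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
      '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
      '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
      '<Default Extension="xml" ContentType="application/xml"/>',
      '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
      '<Override PartName="/xl/worksheets/sheet1.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
      '<Override PartName="/xl/styles.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.styles+xml"/>',
      "</Types>"),
    "_rels/.rels" = c(
      '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
      '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
      '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
      "</Relationships>"),
    "xl/workbook.xml" = c(
      '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
      '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
      '<sheets><sheet name="map" sheetId="1" r:id="rId1"/></sheets>',
      "</workbook>"),
    "xl/_rels/workbook.xml.rels" = c(
      '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
      '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
      '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet1.xml"/>',
      '<Relationship Id="rId2" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/styles" Target="styles.xml"/>',
      "</Relationships>"),
    "xl/styles.xml" = styles,
    "xl/worksheets/sheet1.xml" = sheet)
  .writeZip(files, path)
}
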
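## Minimal DICOM codec: explicit VR little endian only, which is the transfer
## syntax this package writes. Enough of PS3.5 is implemented to round-trip
## CT image slices and RT structure sets; anything else is rejected loudly.

.dcmUIDroot <- "1.2.826.0.1.3680043.9.7435."
.dcmImplUID <- paste0(.dcmUIDroot, "0.1")
.uidCT <- "1.2.840.10008.5.1.4.1.1.2"
.uidRTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"
.uidExplicitLE <- "1.2.840.10008.1.2.1"

# VRs carrying a 2-byte reserved field and 4-byte length
.dcmLongVRs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.dcmU16 <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256))
}

.dcmU32 <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

.dcmInt16Raw <- function(v) {
  v <- as.integer(v)
  v <- ifelse(v < 0, v + 65536L, v)
  lo <- v %% 256L
  hi <- v %/% 256L
  as.raw(as.vector(rbind(lo, hi)))
}

# encode a string value field, backslash-joining multiplicity, even-padded
.dcmStr <- function(values, ui = FALSE) {
  s <- paste(values, collapse = "\\")
  r <- charToRaw(s)
  if (length(r) %% 2 == 1) r <- c(r, if (ui) as.raw(0) else charToRaw(" "))
  r
}

.dcmDS <- function(x) .dcmStr(sprintf("%.4f", as.numeric(x)))
.dcmIS <- function(x) .dcmStr(sprintf("%d", as.integer(x)))

.dcmElem <- function(group, element, vr, body) {
  stopifnot(length(body) %% 2 == 0)
  hdr <- c(.dcmU16(group), .dcmU16(element), charToRaw(vr))
  if (vr %in% .dcmLongVRs) {
    c(hdr, as.raw(c(0, 0)), .dcmU32(length(body)), body)
  } else {
    if (length(body) > 65534) stop("value too long for short VR")
    c(hdr, .dcmU16(length(body)), body)
  }
}

# a sequence body: defined-length items, each wrapping an encoded dataset
.dcmItem <- function(content) {
  c(.dcmU16(0xFFFE), .dcmU16(0xE000), .dcmU32(length(content)), content)
}

.dcmFileMeta <- function(sopClass, sopInstance) {
  body <- c(
    .dcmElem(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    .dcmElem(0x0002, 0x0002, "UI", .dcmStr(sopClass, ui = TRUE)),
    .dcmElem(0x0002, 0x0003, "UI", .dcmStr(sopInstance, ui = TRUE)),
    .dcmElem(0x0002, 0x0010, "UI", .dcmStr(.uidExplicitLE, ui = TRUE)),
    .dcmElem(0x0002, 0x0012, "UI", .dcmStr(.dcmImplUID, ui = TRUE)),
    .dcmElem(0x0002, 0x0013, "SH", .dcmStr("structviews"))
  )
  c(.dcmElem(0x0002, 0x0000, "UL", .dcmU32(length(body))), body)
}

.dcmWriteFile <- function(path, sopClass, sopInstance, dataset) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(.dcmFileMeta(sopClass, sopInstance), con)
  writeBin(dataset, con)
  invisible(path)
}

## ---- parsing ----

.dcmReadU16 <- function(buf, pos) {
  as.integer(buf[pos]) + 256L * as.integer(buf[pos + 1L])
}

.dcmReadU32 <- function(buf, pos) {
  as.numeric(buf[pos]) + 256 * as.numeric(buf[pos + 1L]) +
    65536 * as.numeric(buf[pos + 2L]) + 16777216 * as.numeric(buf[pos + 3L])
}

.dcmDecode <- function(vr, body) {
  if (length(body) == 0) {
    return(switch(vr, DS = , IS = , US = , UL = , SS = , FD = numeric(0),
                  SQ = list(), ""))
  }
  txt <- function() {
    # strip the single even-padding byte the writer may have appended
    sub(" $", "", rawToChar(body))
  }
  switch(vr,
    UI = rawToChar(body[body != as.raw(0)]),
    LO = , SH = , PN = , CS = , DA = , TM = , ST = , LT = txt(),
    DS = as.numeric(strsplit(trimws(rawToChar(body)), "\\\\")[[1]]),
    IS = as.integer(strsplit(trimws(rawToChar(body)), "\\\\")[[1]]),
    US = readBin(body, "integer", n = length(body) / 2, size = 2,
                 signed = FALSE, endian = "little"),
    SS = readBin(body, "integer", n = length(body) / 2, size = 2,
                 signed = TRUE, endian = "little"),
    UL = .dcmReadU32(body, 1L),
    FD = readBin(body, "double", n = length(body) / 8, size = 8,
                 endian = "little"),
    body)
}

# parse one dataset spanning buf[pos..end]; returns list(elements, pos)
.dcmParseDataset <- function(buf, pos, end) {
  out <- list()
  while (pos + 7 <= end) {
    group <- .dcmReadU16(buf, pos)
    element <- .dcmReadU16(buf, pos + 2L)
    if (group == 0xFFFE) {
      # item/sequence delimiters are handled by the callers
      break
    }
    vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("unsupported transfer syntax (implicit VR?)")
    if (vr %in% .dcmLongVRs) {
      len <- .dcmReadU32(buf, pos + 8L)
      vpos <- pos + 12L
    } else {
      len <- .dcmReadU16(buf, pos + 6L)
      vpos <- pos + 8L
    }
    key <- sprintf("%04X%04X", group, element)
    if (vr == "SQ") {
      parsed <- .dcmParseSequence(buf, vpos, len, end)
      out[[key]] <- parsed$items
      pos <- parsed$pos
    } else {
      if (len == 4294967295) stop("undefined length outside SQ unsupported")
      body <- if (len > 0) buf[vpos:(vpos + len - 1L)] else raw(0)
      out[[key]] <- .dcmDecode(vr, body)
      pos <- vpos + len
    }
  }
  list(elements = out, pos = pos)
}

.dcmParseSequence <- function(buf, pos, len, end) {
  undefined <- (len == 4294967295)
  stopAt <- if (undefined) end else pos + len - 1L
  items <- list()
  while (pos + 7 <= stopAt) {
    group <- .dcmReadU16(buf, pos)
    element <- .dcmReadU16(buf, pos + 2L)
    ilen <- .dcmReadU32(buf, pos + 4L)
    pos <- pos + 8L
    if (group == 0xFFFE && element == 0xE0DD) break  # sequence delimiter
    if (!(group == 0xFFFE && element == 0xE000))
      stop("malformed sequence item")
    if (ilen == 4294967295) {
      parsed <- .dcmParseDataset(buf, pos, stopAt)
      items[[length(items) + 1L]] <- parsed$elements
      pos <- parsed$pos
      # expect item delimitation
      if (.dcmReadU16(buf, pos) == 0xFFFE &&
          .dcmReadU16(buf, pos + 2L) == 0xE00D) pos <- pos + 8L
    } else {
      parsed <- .dcmParseDataset(buf, pos, pos + ilen - 1L)
      items[[length(items) + 1L]] <- parsed$elements
      pos <- pos + ilen
    }
  }
  list(items = items, pos = pos)
}

.dcmParseFile <- function(path) {
  buf <- readBin(path, "raw", n = file.size(path))
  if (length(buf) < 140 || rawToChar(buf[129:132]) != "DICM")
    stop("not a DICOM file: ", path)
  ds <- .dcmParseDataset(buf, 133L, length(buf))$elements
  ts <- ds[["00020010"]]
  if (!is.null(ts) && ts != .uidExplicitLE)
    stop("unsupported transfer syntax: ", ts)
  ds
}

.dcmGet <- function(ds, key, default = NULL) {
  v <- ds[[key]]
  if (is.null(v)) default else v
}
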
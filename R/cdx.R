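# CDX binary dialect. The format is a tagged tree: property records
# (uint16 tag, uint16 length, payload) and object records (tag with the
# high bit set, uint32 id, children, zero terminator), little-endian,
# coordinates as 32-bit fixed point (value / 65536), 2-D positions stored
# y-before-x. Only the property subset needed for extraction is decoded;
# everything else is skip-logged, never fatal.

CDX_MAGIC <- "VjCD0100"
CDX_HEADER_RESERVED <- 20L

.CDX_OBJ <- c(page = 0x8001, group = 0x8002, fragment = 0x8003,
              node = 0x8004, bond = 0x8005, text = 0x8006,
              graphic = 0x8007, arrow = 0x8020)
.CDX_PROP <- c(pos2d = 0x0200, bbox = 0x0204, head3d = 0x0205,
               tail3d = 0x0206, nodeType = 0x0400, element = 0x0402,
               isotope = 0x0420, charge = 0x0421, bondOrder = 0x0600,
               bondDisplay = 0x0601, bondBegin = 0x0604, bondEnd = 0x0605,
               text = 0x0700, lineType = 0x0a01, arrowNoGo = 0x0a22)

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                             endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                             endian = "little")
.fix32 <- function(x) .u32(round(x * 65536))

cdxProp <- function(name, payload)
  c(.u16(.CDX_PROP[[name]]), .u16(length(payload)), payload)

cdxObj <- function(name, id, children = raw())
  c(.u16(.CDX_OBJ[[name]]), .u32(id), children, .u16(0))

cdxTextPayload <- function(s) {
  bytes <- iconv(s, from = "UTF-8", to = "latin1", sub = "?")
  c(.u16(0), charToRaw(bytes))  # zero style runs, Latin-1 text
}

.cdxOrderFlag <- c(`1` = 0x0001, `2` = 0x0002, `3` = 0x0004, `1.5` = 0x0080)
CDX_ORDER_DATIVE <- 0x0100
.cdxDisplayOut <- c(wedge = 6L, hash = 3L)

serializeCdxNode <- function(a, inner) {
  body <- cdxProp("pos2d", c(.fix32(a$y), .fix32(a$x)))
  if (a$kind == "element" && a$element != 6L)
    body <- c(body, cdxProp("element", .u16(a$element)))
  nt <- switch(a$kind, element = 1L, abbreviation = 5L, r_group = 7L, 1L)
  if (nt != 1L) body <- c(body, cdxProp("nodeType", .u16(nt)))
  if (!is.na(a$charge) && a$charge != 0L)
    body <- c(body, cdxProp("charge", as.raw(bitwAnd(a$charge, 0xFF))))
  if (!is.na(a$isotope))
    body <- c(body, cdxProp("isotope", .u16(a$isotope)))
  if (!is.na(a$label))
    body <- c(body, cdxObj("text", a$id * 100L + 1L,
                           cdxProp("text", cdxTextPayload(a$label))))
  if (!is.null(inner)) {
    base <- a$id * 1000L
    ib <- raw()
    for (i in seq_len(nrow(inner$atoms))) {
      ia <- inner$atoms[i, ]
      el <- elementNumber(ia$symbol)
      nb <- cdxProp("pos2d", c(.fix32(ia$y), .fix32(ia$x)))
      if (el != 6L) nb <- c(nb, cdxProp("element", .u16(el)))
      if (!is.na(ia$charge) && ia$charge != 0L)
        nb <- c(nb, cdxProp("charge", as.raw(bitwAnd(ia$charge, 0xFF))))
      ib <- c(ib, cdxObj("node", base + i, nb))
    }
    for (i in seq_len(nrow(inner$bonds))) {
      bd <- inner$bonds[i, ]
      bb <- c(cdxProp("bondBegin", .u32(base + bd$begin)),
              cdxProp("bondEnd", .u32(base + bd$end)))
      if (bd$order != 1)
        bb <- c(bb, cdxProp("bondOrder",
                            .u16(.cdxOrderFlag[[as.character(bd$order)]])))
      ib <- c(ib, cdxObj("bond", base + 500L + i, bb))
    }
    body <- c(body, cdxObj("fragment", base, ib))
  }
  cdxObj("node", a$id, body)
}

#' Serialize a SchemeGraph as CDX binary
#'
#' Emits the binary dialect (magic header, tagged record tree) covering the
#' object/property subset the reader decodes; used by the fixture generator
#' so every scheme is testable in both dialects.
#'
#' @param graph a [SchemeGraph].
#' @return raw vector.
#' @export
writeCdx <- function(graph) {
  maxId <- 1L
  body <- raw()
  for (f in graph@fragments) {
    fb <- raw()
    for (i in seq_len(nrow(f$atoms)))
      fb <- c(fb, serializeCdxNode(f$atoms[i, ],
                                   f$inner[[as.character(f$atoms$id[i])]]))
    for (i in seq_len(nrow(f$bonds))) {
      b <- f$bonds[i, ]
      bb <- c(cdxProp("bondBegin", .u32(b$begin)),
              cdxProp("bondEnd", .u32(b$end)))
      if (b$coordinative) {
        bb <- c(bb, cdxProp("bondOrder", .u16(CDX_ORDER_DATIVE)))
      } else if (b$order != 1) {
        bb <- c(bb, cdxProp("bondOrder",
                            .u16(.cdxOrderFlag[[as.character(b$order)]])))
      }
      if (b$display %in% names(.cdxDisplayOut))
        bb <- c(bb, cdxProp("bondDisplay",
                            .u16(.cdxDisplayOut[[b$display]])))
      fb <- c(fb, cdxObj("bond", 200000L + maxId, bb)); maxId <- maxId + 1L
    }
    body <- c(body, cdxObj("fragment", f$id, fb))
  }
  for (i in seq_len(nrow(graph@texts))) {
    t <- graph@texts[i, ]
    body <- c(body, cdxObj("text", t$id, c(
      cdxProp("pos2d", c(.fix32(t$y), .fix32(t$x))),
      cdxProp("bbox", c(.fix32(t$ymin), .fix32(t$xmin), .fix32(t$ymax),
                        .fix32(t$xmax))),
      cdxProp("text", cdxTextPayload(t$value)))))
  }
  for (i in seq_len(nrow(graph@arrows))) {
    a <- graph@arrows[i, ]
    ab <- c(cdxProp("tail3d", c(.fix32(a$tailx), .fix32(a$taily), .fix32(0))),
            cdxProp("head3d", c(.fix32(a$headx), .fix32(a$heady), .fix32(0))))
    if (a$style == "dashed") ab <- c(ab, cdxProp("lineType", .u16(1)))
    if (a$style == "crossed") ab <- c(ab, cdxProp("arrowNoGo", .u16(2)))
    body <- c(body, cdxObj("arrow", a$id, ab))
  }
  c(charToRaw(CDX_MAGIC), as.raw(c(1, 2, 3, 4)), raw(16),
    cdxObj("page", 900001L, body))
}

# --- reading ---------------------------------------------------------------

.rdU16 <- function(data, pos) {
  if (pos + 1L > length(data)) stop("truncated record at offset ", pos - 1L)
  sum(as.integer(data[pos:(pos + 1L)]) * c(1, 256))
}

.rdU32 <- function(data, pos) {
  if (pos + 3L > length(data)) stop("truncated record at offset ", pos - 1L)
  sum(as.numeric(data[pos:(pos + 3L)]) * c(1, 256, 65536, 16777216))
}

.rdI32 <- function(data, pos) {
  v <- .rdU32(data, pos)
  if (v >= 2147483648) v - 4294967296 else v
}

#' Read the CDX record tree
#'
#' Walks the tag/length/value structure after the file header and returns
#' the full tree of object and property records; every byte is either
#' consumed into a record or attributed to a skipped one.
#'
#' @param data raw vector of the whole file.
#' @param pos 1-based position of the first record byte.
#' @param end 1-based position of the last byte to read.
#' @return `list(records = <list>, pos = <next position>)`; each record is
#'   `list(kind, tag, id, children, payload, offset)`.
#' @keywords internal
readRecordTree <- function(data, pos, end) {
  records <- list()
  while (pos + 1L <= end + 1L) {
    if (pos > end) break
    tag <- .rdU16(data, pos)
    off <- pos - 1L
    pos <- pos + 2L
    if (tag == 0) break  # terminator of the enclosing object
    if (tag >= 0x8000) {
      id <- .rdU32(data, pos); pos <- pos + 4L
      sub <- readRecordTree(data, pos, end)
      pos <- sub$pos
      records[[length(records) + 1L]] <-
        list(kind = "obj", tag = tag, id = id, children = sub$records,
             payload = NULL, offset = off)
    } else {
      len <- .rdU16(data, pos); pos <- pos + 2L
      if (len == 0xFFFF) { len <- .rdU32(data, pos); pos <- pos + 4L }
      if (pos + len - 1L > end + 1L)
        stop("truncated record at offset ", off)
      payload <- if (len > 0) data[pos:(pos + len - 1L)] else raw()
      pos <- pos + len
      records[[length(records) + 1L]] <-
        list(kind = "prop", tag = tag, id = NA, children = NULL,
             payload = payload, offset = off)
    }
  }
  list(records = records, pos = pos)
}

#' Decode a typed CDX property payload
#'
#' @param tag property code (one of the supported table).
#' @param payload raw payload bytes.
#' @return typed value: `c(x, y)` points for coordinates, integers for
#'   element/charge/isotope/enums, character for text.
#' @keywords internal
decodeProperty <- function(tag, payload) {
  n <- length(payload)
  name <- names(.CDX_PROP)[match(tag, .CDX_PROP)]
  if (is.na(name)) stop("unsupported property tag ", tag)
  fix <- function(i) .rdI32(payload, i) / 65536
  switch(name,
    pos2d = {
      if (n != 8) stop("2-D position payload must be 8 bytes, got ", n)
      c(x = fix(5), y = fix(1))  # stored y first, normalized to (x, y)
    },
    bbox = {
      if (n != 16) stop("bounding-box payload must be 16 bytes, got ", n)
      c(ymin = fix(1), xmin = fix(5), ymax = fix(9), xmax = fix(13))
    },
    head3d = , tail3d = {
      if (n != 12) stop("3-D point payload must be 12 bytes, got ", n)
      c(x = fix(1), y = fix(5))
    },
    charge = {
      if (n == 1) { v <- as.integer(payload); if (v > 127) v - 256L else v }
      else if (n == 4) .rdI32(payload, 1)
      else stop("charge payload must be 1 or 4 bytes, got ", n)
    },
    text = {
      if (n < 2) stop("text payload too short")
      nruns <- .rdU16(payload, 1)
      start <- 3L + 10L * nruns
      if (start > n + 1L) stop("text style-run table exceeds payload")
      bytes <- if (start > n) raw() else payload[start:n]
      iconv(rawToChar(bytes), from = "latin1", to = "UTF-8")
    },
    {  # uint16 enums: nodeType, element, isotope, orders, displays, ...
      if (n == 2) .rdU16(payload, 1)
      else if (n == 4) .rdU32(payload, 1)
      else stop("property ", name, " payload must be 2 or 4 bytes, got ", n)
    })
}

.cdxPropsOf <- function(rec) {
  out <- list()
  for (ch in rec$children)
    if (ch$kind == "prop") {
      name <- names(.CDX_PROP)[match(ch$tag, .CDX_PROP)]
      if (!is.na(name)) out[[name]] <- decodeProperty(ch$tag, ch$payload)
    }
  out
}

.cdxChildObjs <- function(rec, what) {
  tag <- .CDX_OBJ[[what]]
  Filter(function(ch) ch$kind == "obj" && ch$tag == tag, rec$children)
}

.cdxNodeLabel <- function(rec) {
  for (tx in .cdxChildObjs(rec, "text")) {
    p <- .cdxPropsOf(tx)
    if (!is.null(p$text)) {
      v <- trimws(gsub("\\s+", " ", p$text))
      if (nzchar(v)) return(v)
    }
  }
  NA_character_
}

.cdxInnerTable <- function(rec) {
  frs <- .cdxChildObjs(rec, "fragment")
  if (length(frs) == 0) return(NULL)
  fr <- frs[[1]]
  nodes <- .cdxChildObjs(fr, "node")
  ids <- vapply(nodes, `[[`, 0, "id")
  props <- lapply(nodes, .cdxPropsOf)
  atoms <- data.frame(
    symbol = elementSymbol(vapply(props, function(p)
      as.integer(if (is.null(p$element)) 6L else p$element), 0L)),
    x = vapply(props, function(p) p$pos2d[["x"]], 0),
    y = vapply(props, function(p) p$pos2d[["y"]], 0),
    charge = vapply(props, function(p)
      as.integer(if (is.null(p$charge)) 0L else p$charge), 0L),
    isotope = NA_integer_, stringsAsFactors = FALSE)
  bonds <- emptyBonds()
  for (bd in .cdxChildObjs(fr, "bond")) {
    p <- .cdxPropsOf(bd)
    ord <- if (is.null(p$bondOrder)) 1 else .cdxOrderIn(p$bondOrder)$order
    bonds <- rbind(bonds, data.frame(
      begin = match(p$bondBegin, ids), end = match(p$bondEnd, ids),
      order = ord, display = "plain", coordinative = FALSE,
      stringsAsFactors = FALSE))
  }
  chemTable(atoms, bonds)
}

.cdxOrderIn <- function(flag) {
  if (bitwAnd(flag, CDX_ORDER_DATIVE) != 0)
    return(list(order = 1, coordinative = TRUE))
  order <- if (bitwAnd(flag, 0x0080) != 0) 1.5
    else if (bitwAnd(flag, 0x0004) != 0) 3
    else if (bitwAnd(flag, 0x0002) != 0) 2 else 1
  list(order = order, coordinative = FALSE)
}

.cdxDisplayIn <- function(v) {
  switch(as.character(v), `6` = "wedge", `7` = "wedge", `3` = "hash",
         `4` = "hash", "plain")
}

#' Parse CDX binary data into a SchemeGraph
#'
#' Same contract as [parseCdxml()]: nodes become atoms, bond objects
#' bonds, text objects text blocks and arrow objects arrows; property tags
#' outside the supported table are skipped. Object ids are remapped to the
#' global namespace with originals kept in `origId`.
#'
#' @param data raw vector beginning with the 8-byte magic `"VjCD0100"`.
#' @param source provenance string.
#' @return a [SchemeGraph].
#' @export
parseCdx <- function(data, source = "<cdx>") {
  if (length(data) < 8 ||
      rawToChar(data[1:8]) != CDX_MAGIC) stop("not CDX")
  pos <- 9L
  if (length(data) >= 8L + CDX_HEADER_RESERVED) pos <- 9L + CDX_HEADER_RESERVED
  if (pos > length(data))
    return(SchemeGraph(source = source))
  tree <- readRecordTree(data, pos, length(data))

  nextId <- 0L
  newId <- function() { nextId <<- nextId + 1L; nextId }
  fragments <- list(); texts <- emptyTexts(); arrows <- emptyArrows()

  walk <- function(recs) {
    for (rec in recs) {
      if (rec$kind != "obj") next
      name <- names(.CDX_OBJ)[match(rec$tag, .CDX_OBJ)]
      if (is.na(name)) next
      if (name %in% c("page", "group")) { walk(rec$children); next }
      if (name == "fragment") {
        fragments[[length(fragments) + 1L]] <<- .cdxFragment(rec, newId)
      } else if (name == "text") {
        p <- .cdxPropsOf(rec)
        if (is.null(p$text)) next
        value <- trimws(gsub("\\s+", " ", p$text))
        if (!nzchar(value)) next
        xy <- if (!is.null(p$pos2d)) p$pos2d else c(x = 0, y = 0)
        bb <- p$bbox
        if (is.null(bb)) {
          w <- 6 * nchar(value)
          bb <- c(ymin = xy[["y"]] - 10, xmin = xy[["x"]],
                  ymax = xy[["y"]], xmax = xy[["x"]] + w)
        }
        texts <<- rbind(texts, data.frame(
          id = newId(), value = value, x = xy[["x"]], y = xy[["y"]],
          xmin = bb[["xmin"]], ymin = bb[["ymin"]], xmax = bb[["xmax"]],
          ymax = bb[["ymax"]], stringsAsFactors = FALSE))
      } else if (name == "arrow") {
        p <- .cdxPropsOf(rec)
        if (is.null(p$tail3d) || is.null(p$head3d)) next
        style <- "plain"
        if (!is.null(p$lineType) && bitwAnd(p$lineType, 1) != 0)
          style <- "dashed"
        if (!is.null(p$arrowNoGo) && p$arrowNoGo == 2) style <- "crossed"
        arrows <<- rbind(arrows, data.frame(
          id = newId(), tailx = p$tail3d[["x"]], taily = p$tail3d[["y"]],
          headx = p$head3d[["x"]], heady = p$head3d[["y"]], style = style,
          stringsAsFactors = FALSE))
      }
      # graphics and other objects contribute nothing and are skipped
    }
  }
  walk(tree$records)
  SchemeGraph(fragments = fragments, texts = texts, arrows = arrows,
              source = source)
}

.cdxFragment <- function(rec, newId) {
  atoms <- emptyAtoms(); atoms$origId <- integer()
  inner <- list(); origIds <- numeric(0)
  for (nd in .cdxChildObjs(rec, "node")) {
    p <- .cdxPropsOf(nd)
    label <- .cdxNodeLabel(nd)
    innerTab <- .cdxInnerTable(nd)
    nt <- if (is.null(p$nodeType)) 1L else as.integer(p$nodeType)
    kind <- if (!is.na(label) && grepl(.R_GROUP_RE, label)) "r_group"
      else if (nt %in% c(5L, 7L) || (!is.na(label)) || !is.null(innerTab))
        "abbreviation" else "element"
    if (kind == "r_group" && is.na(label)) label <- "R"
    el <- if (kind == "element")
      as.integer(if (is.null(p$element)) 6L else p$element) else 0L
    id <- newId()
    atoms <- rbind(atoms, data.frame(
      id = id, element = el,
      charge = as.integer(if (is.null(p$charge)) 0L else p$charge),
      isotope = as.integer(if (is.null(p$isotope)) NA else p$isotope),
      x = p$pos2d[["x"]], y = p$pos2d[["y"]], label = label, kind = kind,
      origId = as.integer(nd$id), stringsAsFactors = FALSE))
    origIds <- c(origIds, nd$id)
    if (!is.null(innerTab)) inner[[as.character(id)]] <- innerTab
  }
  bonds <- emptyBonds()
  for (bd in .cdxChildObjs(rec, "bond")) {
    p <- .cdxPropsOf(bd)
    oi <- if (is.null(p$bondOrder)) list(order = 1, coordinative = FALSE)
      else .cdxOrderIn(p$bondOrder)
    dspRaw <- if (is.null(p$bondDisplay)) 0L else as.integer(p$bondDisplay)
    b <- match(p$bondBegin, origIds); e <- match(p$bondEnd, origIds)
    if (dspRaw %in% c(4L, 7L)) { tmp <- b; b <- e; e <- tmp }
    bonds <- rbind(bonds, data.frame(
      begin = atoms$id[b], end = atoms$id[e], order = oi$order,
      display = .cdxDisplayIn(dspRaw), coordinative = oi$coordinative,
      stringsAsFactors = FALSE))
  }
  list(id = newId(), atoms = atoms, bonds = bonds, inner = inner)
}
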
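# CDXML dialect: text serializer and reader. Both dialect readers produce
# the same SchemeGraph model; the serializer here is also the backend for
# the CDXML exporter and the fixture generator.

xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

fmtNum <- function(x) {
  out <- formatC(x, format = "f", digits = 2)
  sub("^-0\\.00$", "0.00", out)
}

.R_GROUP_RE <- "^(R\\d*'*|X\\d*)$"

.displayOut <- c(wedge = "WedgeBegin", hash = "WedgedHashBegin")

serializeFragment <- function(f, indent = "  ") {
  out <- sprintf('%s<fragment id="%d">', indent, f$id)
  for (i in seq_len(nrow(f$atoms))) {
    a <- f$atoms[i, ]
    attrs <- sprintf(' id="%d" p="%s %s"', a$id, fmtNum(a$x), fmtNum(a$y))
    if (a$kind == "element" && a$element != 6L)
      attrs <- paste0(attrs, sprintf(' Element="%d"', a$element))
    if (!is.na(a$charge) && a$charge != 0L)
      attrs <- paste0(attrs, sprintf(' Charge="%d"', a$charge))
    if (!is.na(a$isotope))
      attrs <- paste0(attrs, sprintf(' Isotope="%d"', a$isotope))
    if (a$kind == "abbreviation")
      attrs <- paste0(attrs, ' NodeType="Abbreviation"')
    if (a$kind == "r_group")
      attrs <- paste0(attrs, ' NodeType="GenericNickname"')
    inner <- f$inner[[as.character(a$id)]]
    if (!is.na(a$label) || !is.null(inner)) {
      out <- c(out, sprintf("%s  <n%s>", indent, attrs))
      if (!is.na(a$label))
        out <- c(out, sprintf("%s    <t><s>%s</s></t>", indent,
                              xmlEscape(a$label)))
      if (!is.null(inner))
        out <- c(out, serializeInnerFragment(inner, a$id,
                                             paste0(indent, "    ")))
      out <- c(out, sprintf("%s  </n>", indent))
    } else {
      out <- c(out, sprintf("%s  <n%s/>", indent, attrs))
    }
  }
  for (i in seq_len(nrow(f$bonds))) {
    b <- f$bonds[i, ]
    attrs <- sprintf(' B="%d" E="%d"', b$begin, b$end)
    if (b$order != 1) {
      ostr <- if (b$order == 1.5) "1.5" else sprintf("%d", as.integer(b$order))
      attrs <- paste0(attrs, sprintf(' Order="%s"', ostr))
    }
    if (b$coordinative) attrs <- paste0(attrs, ' Display="Dative"')
    else if (b$display %in% names(.displayOut))
      attrs <- paste0(attrs, sprintf(' Display="%s"', .displayOut[[b$display]]))
    out <- c(out, sprintf("%s  <b%s/>", indent, attrs))
  }
  c(out, sprintf("%s</fragment>", indent))
}

# Nested expansion fragment of an abbreviation node (chemistry table form;
# synthetic local ids offset from the host atom id).
serializeInnerFragment <- function(tab, hostId, indent) {
  base <- hostId * 1000L
  out <- sprintf('%s<fragment id="%d">', indent, base)
  for (i in seq_len(nrow(tab$atoms))) {
    a <- tab$atoms[i, ]
    el <- elementNumber(a$symbol)
    attrs <- sprintf(' id="%d" p="%s %s"', base + i, fmtNum(a$x), fmtNum(a$y))
    if (el != 6L) attrs <- paste0(attrs, sprintf(' Element="%d"', el))
    if (!is.na(a$charge) && a$charge != 0L)
      attrs <- paste0(attrs, sprintf(' Charge="%d"', a$charge))
    out <- c(out, sprintf("%s  <n%s/>", indent, attrs))
  }
  for (i in seq_len(nrow(tab$bonds))) {
    b <- tab$bonds[i, ]
    attrs <- sprintf(' B="%d" E="%d"', base + b$begin, base + b$end)
    if (b$order != 1)
      attrs <- paste0(attrs, sprintf(' Order="%s"',
        if (b$order == 1.5) "1.5" else sprintf("%d", as.integer(b$order))))
    out <- c(out, sprintf("%s  <b%s/>", indent, attrs))
  }
  c(out, sprintf("%s</fragment>", indent))
}

#' Serialize a SchemeGraph as CDXML text
#'
#' Writes the modern dialect: `n`/`b` elements inside `fragment`, `t` text
#' blocks with style runs, and `arrow` elements with `Tail3D`/`Head3D`
#' endpoints; dashed arrows carry `LineType="Dashed"` and crossed (failed)
#' arrows `NoGo="Cross"`.
#'
#' @param graph a [SchemeGraph].
#' @return CDXML document text.
#' @export
graphToCdxml <- function(graph) {
  out <- c('<?xml version="1.0" encoding="UTF-8"?>',
           '<CDXML BondLength="30">', " <page>")
  for (f in graph@fragments) out <- c(out, serializeFragment(f))
  for (i in seq_len(nrow(graph@texts))) {
    t <- graph@texts[i, ]
    out <- c(out, sprintf(
      '  <t id="%d" p="%s %s" BoundingBox="%s %s %s %s"><s>%s</s></t>',
      t$id, fmtNum(t$x), fmtNum(t$y), fmtNum(t$xmin), fmtNum(t$ymin),
      fmtNum(t$xmax), fmtNum(t$ymax), xmlEscape(t$value)))
  }
  for (i in seq_len(nrow(graph@arrows))) {
    a <- graph@arrows[i, ]
    style <- ""
    if (a$style == "dashed") style <- ' LineType="Dashed"'
    if (a$style == "crossed") style <- ' NoGo="Cross"'
    out <- c(out, sprintf(
      '  <arrow id="%d" Tail3D="%s %s 0" Head3D="%s %s 0"%s/>',
      a$id, fmtNum(a$tailx), fmtNum(a$taily), fmtNum(a$headx),
      fmtNum(a$heady), style))
  }
  paste(c(out, " </page>", "</CDXML>", ""), collapse = "\n")
}

#' Parse a coordinate attribute
#'
#' CDXML encodes positions as a `"x y"` decimal pair (scientific notation
#' accepted).
#'
#' @param attr attribute string.
#' @return numeric `c(x, y)`.
#' @export
parseCoordinate <- function(attr) {
  toks <- strsplit(trimws(attr), "\\s+")[[1]]
  if (length(toks) < 2) stop("coordinate needs two tokens: '", attr, "'")
  v <- suppressWarnings(as.numeric(toks[1:2]))
  if (anyNA(v)) stop("unparsable coordinate: '", attr, "'")
  c(x = v[1], y = v[2])
}

.attrOr <- function(el, name, default = NA_character_) {
  v <- xml2::xml_attr(el, name)
  if (is.na(v)) default else v
}

# One CDXML n element -> AtomNode row (+ inner expansion table).
parseNodeElement <- function(el, ctx) {
  idStr <- .attrOr(el, "id")
  p <- .attrOr(el, "p")
  if (is.na(p)) stop("node ", idStr, " has no position")
  xy <- tryCatch(parseCoordinate(p),
                 error = function(e) stop("node ", idStr, ": ",
                                          conditionMessage(e)))
  elno <- suppressWarnings(as.integer(.attrOr(el, "Element", "6")))
  charge <- suppressWarnings(as.integer(.attrOr(el, "Charge", "0")))
  iso <- suppressWarnings(as.integer(.attrOr(el, "Isotope", NA_character_)))
  label <- NA_character_
  tEl <- xml2::xml_find_first(el, "./t")
  if (!inherits(tEl, "xml_missing")) {
    label <- paste(xml2::xml_text(xml2::xml_find_all(tEl, ".//s")),
                   collapse = "")
    if (!nzchar(label)) label <- xml2::xml_text(tEl)
    label <- trimws(gsub("\\s+", " ", label))
    if (!nzchar(label)) label <- NA_character_
  }
  innerEl <- xml2::xml_find_first(el, "./fragment")
  inner <- NULL
  if (!inherits(innerEl, "xml_missing")) inner <- parseInnerFragment(innerEl)
  kind <- "element"
  if (!is.na(label)) {
    kind <- if (grepl(.R_GROUP_RE, label)) "r_group" else "abbreviation"
    if (kind == "abbreviation") elno <- 0L
    if (kind == "r_group") elno <- 0L
  } else if (!is.null(inner)) kind <- "abbreviation"
  list(atom = data.frame(id = ctx$newId(), element = elno, charge = charge,
                         isotope = iso, x = xy[["x"]], y = xy[["y"]],
                         label = label, kind = kind,
                         origId = suppressWarnings(as.integer(idStr)),
                         stringsAsFactors = FALSE),
       inner = inner)
}

# Inner (pre-expanded) fragment of an abbreviation node as chemistry table.
parseInnerFragment <- function(el) {
  ns <- xml2::xml_find_all(el, "./n")
  ids <- as.integer(xml2::xml_attr(ns, "id"))
  xy <- lapply(xml2::xml_attr(ns, "p"), parseCoordinate)
  atoms <- data.frame(
    symbol = elementSymbol(as.integer(ifelse(
      is.na(xml2::xml_attr(ns, "Element")), "6",
      xml2::xml_attr(ns, "Element")))),
    x = vapply(xy, `[[`, 0, "x"), y = vapply(xy, `[[`, 0, "y"),
    charge = as.integer(ifelse(is.na(xml2::xml_attr(ns, "Charge")), "0",
                               xml2::xml_attr(ns, "Charge"))),
    isotope = NA_integer_, stringsAsFactors = FALSE)
  bs <- xml2::xml_find_all(el, "./b")
  ordv <- xml2::xml_attr(bs, "Order"); ordv[is.na(ordv)] <- "1"
  bonds <- data.frame(
    begin = match(as.integer(xml2::xml_attr(bs, "B")), ids),
    end = match(as.integer(xml2::xml_attr(bs, "E")), ids),
    order = ifelse(ordv == "1.5", 1.5, as.numeric(ordv)),
    display = "plain", coordinative = FALSE, stringsAsFactors = FALSE)
  chemTable(atoms, bonds)
}

.displayIn <- c(WedgeBegin = "wedge", WedgedHashBegin = "hash",
                WedgeEnd = "wedge", WedgedHashEnd = "hash")

parseBondElement <- function(el, idMap, ctx) {
  b <- suppressWarnings(as.integer(.attrOr(el, "B")))
  e <- suppressWarnings(as.integer(.attrOr(el, "E")))
  if (is.na(b) || is.na(e)) stop("bond without both endpoints")
  ostr <- .attrOr(el, "Order", "1")
  order <- if (ostr %in% c("1.5", "A", "aromatic")) 1.5
           else suppressWarnings(as.numeric(ostr))
  if (is.na(order)) order <- 1
  disp <- .attrOr(el, "Display", "")
  coord <- identical(disp, "Dative")
  display <- if (disp %in% names(.displayIn)) .displayIn[[disp]] else "plain"
  # wedge orientation is narrow-at-begin; *End forms are normalized by swap
  if (disp %in% c("WedgeEnd", "WedgedHashEnd")) { tmp <- b; b <- e; e <- tmp }
  data.frame(begin = idMap[as.character(b)], end = idMap[as.character(e)],
             order = order, display = display, coordinative = coord,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Parse CDXML text into a SchemeGraph
#'
#' Every `n` element becomes an atom, `b` a bond, top-level `t` a text
#' block, and `arrow` elements (or legacy line graphics with an arrowhead)
#' become arrows. Unknown elements are skipped, never fatal. Object ids are
#' remapped to a single global namespace; original ids are kept in
#' `origId` columns.
#'
#' @param text CDXML document text (or an `xml_document`).
#' @param source provenance string recorded on the graph.
#' @return a [SchemeGraph].
#' @export
parseCdxml <- function(text, source = "<cdxml>") {
  doc <- if (inherits(text, "xml_document")) text else
    tryCatch(xml2::read_xml(text),
             error = function(e) stop("CDXML format error: ",
                                      conditionMessage(e), call. = FALSE))
  if (xml2::xml_name(xml2::xml_root(doc)) != "CDXML") stop("not CDXML")
  nextId <- 0L
  ctx <- list(newId = function() { nextId <<- nextId + 1L; nextId })

  fragments <- list()
  for (fEl in xml2::xml_find_all(doc, ".//fragment[not(ancestor::n)]")) {
    atoms <- emptyAtoms(); atoms$origId <- integer()
    inner <- list()
    for (nEl in xml2::xml_find_all(fEl, "./n")) {
      parsed <- parseNodeElement(nEl, ctx)
      atoms <- rbind(atoms, parsed$atom)
      if (!is.null(parsed$inner))
        inner[[as.character(parsed$atom$id)]] <- parsed$inner
    }
    idMap <- stats::setNames(atoms$id, as.character(atoms$origId))
    bonds <- emptyBonds()
    for (bEl in xml2::xml_find_all(fEl, "./b"))
      bonds <- rbind(bonds, parseBondElement(bEl, idMap, ctx))
    fragments[[length(fragments) + 1L]] <-
      list(id = ctx$newId(), atoms = atoms, bonds = bonds, inner = inner)
  }

  texts <- emptyTexts()
  for (tEl in xml2::xml_find_all(doc, ".//t[not(ancestor::n)]")) {
    value <- paste(xml2::xml_text(xml2::xml_find_all(tEl, ".//s")),
                   collapse = "")
    if (!nzchar(value)) value <- xml2::xml_text(tEl)
    value <- trimws(gsub("\\s+", " ", value))
    if (!nzchar(value)) next
    p <- .attrOr(tEl, "p", "0 0")
    xy <- parseCoordinate(p)
    bb <- .attrOr(tEl, "BoundingBox")
    if (!is.na(bb)) {
      v <- as.numeric(strsplit(trimws(bb), "\\s+")[[1]])
      box <- rect2d(min(v[1], v[3]), min(v[2], v[4]),
                    max(v[1], v[3]), max(v[2], v[4]))
    } else {
      w <- 6 * nchar(value)
      box <- rect2d(xy[["x"]], xy[["y"]] - 10, xy[["x"]] + w, xy[["y"]])
    }
    texts <- rbind(texts, data.frame(
      id = ctx$newId(), value = value, x = xy[["x"]], y = xy[["y"]],
      xmin = box[[1]], ymin = box[[2]], xmax = box[[3]], ymax = box[[4]],
      stringsAsFactors = FALSE))
  }

  arrows <- emptyArrows()
  crossBoxes <- list()
  for (aEl in xml2::xml_find_all(doc, ".//arrow")) {
    tl <- parseCoordinate(.attrOr(aEl, "Tail3D", .attrOr(aEl, "Tail", "0 0")))
    hd <- parseCoordinate(.attrOr(aEl, "Head3D", .attrOr(aEl, "Head", "0 0")))
    style <- "plain"
    if (grepl("Dashed", .attrOr(aEl, "LineType", ""))) style <- "dashed"
    if (identical(.attrOr(aEl, "NoGo"), "Cross")) style <- "crossed"
    arrows <- rbind(arrows, data.frame(
      id = ctx$newId(), tailx = tl[["x"]], taily = tl[["y"]],
      headx = hd[["x"]], heady = hd[["y"]], style = style,
      stringsAsFactors = FALSE))
  }
  for (gEl in xml2::xml_find_all(doc, ".//graphic")) {
    gt <- .attrOr(gEl, "GraphicType", "")
    bb <- .attrOr(gEl, "BoundingBox")
    if (gt == "Line" && !is.na(.attrOr(gEl, "ArrowType")) && !is.na(bb)) {
      # legacy arrow graphic: endpoints are the bbox corners,
      # tail at (right, bottom), head at (left, top)
      v <- as.numeric(strsplit(trimws(bb), "\\s+")[[1]])
      style <- if (grepl("Dashed", .attrOr(gEl, "LineType", "")))
        "dashed" else "plain"
      arrows <- rbind(arrows, data.frame(
        id = ctx$newId(), tailx = v[3], taily = v[4], headx = v[1],
        heady = v[2], style = style, stringsAsFactors = FALSE))
    } else if (gt == "Symbol" &&
               identical(.attrOr(gEl, "SymbolType"), "Cross") && !is.na(bb)) {
      v <- as.numeric(strsplit(trimws(bb), "\\s+")[[1]])
      crossBoxes[[length(crossBoxes) + 1L]] <-
        rect2d(min(v[1], v[3]), min(v[2], v[4]), max(v[1], v[3]),
               max(v[2], v[4]))
    }
  }
  # an X-graphic overlapping an arrow marks that arrow as crossed
  if (length(crossBoxes) && nrow(arrows)) {
    for (cb in crossBoxes) {
      cc <- rectCenter(cb)
      for (i in seq_len(nrow(arrows))) {
        pr <- projectOnArrow(cc, arrows[i, ])
        if (pr[["t"]] >= -0.1 && pr[["t"]] <= 1.1 &&
            abs(pr[["d"]]) <= max(10, (cb[3] - cb[1])))
          arrows$style[i] <- "crossed"
      }
    }
  }
  SchemeGraph(fragments = fragments, texts = texts, arrows = arrows,
              source = source)
}
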
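# Exporters: reaction SMILES, CML, CDXML (regenerated layout), tabular
# (CSV / minimal XLSX) and JSON.

#' Reaction SMILES of a step
#'
#' `reactants>agents>products` with dot-joined canonical components;
#' agents are the band reagent structures plus the text-identified
#' reagent and solvent SMILES.
#'
#' @param step a [ReactionStep].
#' @param strict error on a completely empty step (default) instead of
#'   returning an empty skeleton.
#' @return reaction SMILES string.
#' @export
reactionSmiles <- function(step, strict = TRUE) {
  left <- vapply(step@reactants, canoSmiles, "")
  agents <- c(vapply(step@reagents, canoSmiles, ""),
              step@reagentsSmiles, step@solventsSmiles)
  right <- vapply(step@products, canoSmiles, "")
  if (strict && length(left) == 0 && length(agents) == 0 &&
      length(right) == 0) stop("empty reaction step")
  paste0(paste(left, collapse = "."), ">",
         paste(agents, collapse = "."), ">",
         paste(right, collapse = "."))
}

# --- CML -------------------------------------------------------------------

.cmlOrder <- c(`1` = "S", `2` = "D", `3` = "T", `1.5` = "A")

.cmlMolecule <- function(m, id, indent) {
  atoms <- m@atoms; bonds <- m@bonds
  out <- sprintf('%s<molecule id="%s">', indent, id)
  out <- c(out, paste0(indent, " <atomArray>"))
  for (i in seq_len(nrow(atoms))) {
    a <- atoms[i, ]
    attrs <- sprintf(' id="%s.a%d" elementType="%s" x2="%s" y2="%s"',
                     id, i, if (a$symbol == "*") "Du" else a$symbol,
                     fmtNum(a$x), fmtNum(-a$y))
    if (!is.na(a$charge) && a$charge != 0)
      attrs <- paste0(attrs, sprintf(' formalCharge="%d"', a$charge))
    if (!is.na(a$isotope))
      attrs <- paste0(attrs, sprintf(' isotope="%d"', a$isotope))
    out <- c(out, sprintf("%s  <atom%s/>", indent, attrs))
  }
  out <- c(out, paste0(indent, " </atomArray>"),
           paste0(indent, " <bondArray>"))
  for (i in seq_len(nrow(bonds))) {
    b <- bonds[i, ]
    attrs <- sprintf(' atomRefs2="%s.a%d %s.a%d" order="%s"', id, b$begin,
                     id, b$end, .cmlOrder[[as.character(b$order)]])
    if (b$coordinative) attrs <- paste0(attrs, ' coordinative="true"')
    if (b$display %in% c("wedge", "hash")) {
      out <- c(out, sprintf("%s  <bond%s>", indent, attrs),
               sprintf("%s   <bondStereo>%s</bondStereo>", indent,
                       if (b$display == "wedge") "W" else "H"),
               sprintf("%s  </bond>", indent))
    } else out <- c(out, sprintf("%s  <bond%s/>", indent, attrs))
  }
  c(out, paste0(indent, " </bondArray>"), paste0(indent, "</molecule>"))
}

.cmlScalar <- function(dictRef, value, indent, units = NULL) {
  u <- if (is.null(units)) "" else sprintf(' units="%s"', xmlEscape(units))
  sprintf('%s<scalar dictRef="sm:%s"%s>%s</scalar>', indent, dictRef, u,
          xmlEscape(as.character(value)))
}

#' Write extraction results as CML
#'
#' One `reaction` element per step with `reactantList`/`productList`
#' molecule connection tables, a `substanceList` for agents, and scalar
#' children for time, temperature, yield and status (status is a named
#' property element: CML has no standard reaction-outcome field).
#'
#' @param steps list of [ReactionStep].
#' @param path optional file to write.
#' @return CML document text (invisibly when `path` is given).
#' @export
writeCml <- function(steps, path = NULL) {
  out <- c('<?xml version="1.0" encoding="UTF-8"?>',
           '<cml xmlns="http://www.xml-cml.org/schema" xmlns:sm="https://schememiner.invalid/dict">',
           ' <reactionList>')
  for (k in seq_along(steps)) {
    s <- steps[[k]]
    out <- c(out, sprintf('  <reaction id="r%d">', k), "   <reactantList>")
    for (i in seq_along(s@reactants))
      out <- c(out, .cmlMolecule(s@reactants[[i]],
                                 sprintf("r%d.re%d", k, i), "    "))
    out <- c(out, "   </reactantList>", "   <productList>")
    for (i in seq_along(s@products))
      out <- c(out, .cmlMolecule(s@products[[i]],
                                 sprintf("r%d.pr%d", k, i), "    "))
    out <- c(out, "   </productList>", "   <substanceList>")
    for (i in seq_along(s@reagents)) {
      out <- c(out, '    <substance role="reagent">',
               .cmlMolecule(s@reagents[[i]], sprintf("r%d.ag%d", k, i),
                            "     "),
               "    </substance>")
    }
    for (sm in s@reagentsSmiles)
      out <- c(out, sprintf(
        '    <substance role="reagent"><identifier convention="daylight:smiles" value="%s"/></substance>',
        xmlEscape(sm)))
    for (sm in s@solventsSmiles)
      out <- c(out, sprintf(
        '    <substance role="solvent"><identifier convention="daylight:smiles" value="%s"/></substance>',
        xmlEscape(sm)))
    out <- c(out, "   </substanceList>")
    if (!is.na(s@time$value))
      out <- c(out, .cmlScalar("time", s@time$value, "   ", s@time$unit))
    else if (!is.na(s@time$token))
      out <- c(out, .cmlScalar("time", s@time$token, "   "))
    if (!is.na(s@temperature$value))
      out <- c(out, .cmlScalar("temperature", s@temperature$value, "   ",
                               s@temperature$unit))
    else if (!is.na(s@temperature$token))
      out <- c(out, .cmlScalar("temperature", s@temperature$token, "   "))
    if (!is.na(s@yield))
      out <- c(out, .cmlScalar("yield", s@yield, "   ", "percent"))
    out <- c(out, .cmlScalar("status", s@status, "   "), "  </reaction>")
  }
  out <- paste(c(out, " </reactionList>", "</cml>", ""), collapse = "\n")
  if (!is.null(path)) { writeLines(out, path, sep = ""); return(invisible(out)) }
  out
}

# --- CDXML export (regenerated layout) -------------------------------------

.renderConditions <- function(step) {
  parts <- character(0)
  tmp <- step@temperature
  if (!is.na(tmp$value))
    parts <- c(parts, paste0(fmtShort(tmp$value), " ",
                             if (identical(tmp$unit, "°C")) "°C" else tmp$unit))
  else if (!is.na(tmp$token)) parts <- c(parts, tmp$token)
  tm <- step@time
  if (!is.na(tm$value)) parts <- c(parts, paste0(fmtShort(tm$value), " ",
                                                 tm$unit))
  else if (!is.na(tm$token)) parts <- c(parts, tm$token)
  if (!is.na(step@yield)) parts <- c(parts, paste0(fmtShort(step@yield), "%"))
  paste(parts, collapse = ", ")
}

fmtShort <- function(x) {
  out <- format(x, trim = TRUE, scientific = FALSE)
  sub("\\.0+$", "", out)
}

.statusToArrowStyle <- c(success = "plain", failed = "crossed",
                         planned = "dashed", unspecified = "plain")

moleculeTable <- function(m) chemTable(m@atoms, m@bonds)

# Lay one step onto a builder row; fixed grid (30-point bonds, 90-point
# arrows, 20-point band offset).
.layoutStep <- function(gb, step, y, bond = 30, arrowLen = 90,
                        bandOffset = 20) {
  x <- 60
  placeMol <- function(m) {
    tab <- placeTable(moleculeTable(m), 0, 0, bond)
    w <- max(tableWidth(tab), bond)
    tab <- placeTable(tab, x + w / 2, y, bond)
    x <<- x + w
    idx <- gb$addTable(tab)
    if (!is.na(m@label)) {
      h <- tableHeight(tab)
      gb$addText(m@label, x - w / 2, y + h / 2 + 16)
    }
    idx
  }
  for (i in seq_along(step@reactants)) {
    if (i > 1) { gb$addText("+", x + 12, y); x <- x + 24 }
    placeMol(step@reactants[[i]])
    x <- x + 20
  }
  x <- x + 10
  # arrow stretched so every band item's center stays inside the band
  rTabs <- lapply(step@reagents, function(m)
    placeTable(moleculeTable(m), 0, 0, bond))
  agents <- c(step@reagentsSmiles, step@solventsSmiles)
  agentTxt <- if (length(agents)) paste(agents, collapse = ", ") else NULL
  ws <- c(vapply(rTabs, function(tb) max(tableWidth(tb), 16), 0),
          if (!is.null(agentTxt)) 6 * nchar(agentTxt) else numeric(0))
  hs <- c(16, vapply(rTabs, function(tb) max(tableHeight(tb), 16), 0))
  depth <- bandOffset + max(hs) / 2 + 8
  spread <- if (length(ws)) (sum(ws) + 12 * (length(ws) - 1)) / 2 else 0
  aLen <- max(arrowLen, depth / 0.55, spread / 0.5)
  tailx <- x; headx <- x + aLen
  gb$addArrow(tailx, y, headx, y, .statusToArrowStyle[[step@status]])
  mid <- (tailx + headx) / 2
  if (length(ws)) {
    bx <- mid - (sum(ws) + 12 * (length(ws) - 1)) / 2
    for (k in seq_along(rTabs)) {
      h <- max(tableHeight(rTabs[[k]]), 16)
      gb$addTable(placeTable(rTabs[[k]], bx + ws[k] / 2,
                             y - bandOffset - h / 2, bond))
      bx <- bx + ws[k] + 12
    }
    if (!is.null(agentTxt))
      gb$addText(agentTxt, bx + ws[length(ws)] / 2, y - bandOffset - 8)
  }
  lower <- y + bandOffset
  cond <- .renderConditions(step)
  if (nzchar(cond)) { gb$addText(cond, mid, lower + 6); lower <- lower + 18 }
  if (!is.na(step@description) && nzchar(step@description))
    gb$addText(step@description, mid, lower + 6)
  x <- headx + 30
  for (i in seq_along(step@products)) {
    if (i > 1) { gb$addText("+", x + 12, y); x <- x + 24 }
    placeMol(step@products[[i]])
    x <- x + 20
  }
  invisible(gb)
}

#' Write steps, molecules or a graph as CDXML
#'
#' Steps are laid out on a fixed grid — reactants left, band content
#' above/below the arrow, products right, one row per step (bond length
#' 30 points, arrow length 90, band offset 20) — such that re-parsing the
#' document through the extraction pipeline reproduces the steps'
#' molecules, roles, conditions and statuses. A [SchemeGraph] is
#' serialized as-is; a [Molecule] (or list of them) becomes a
#' molecule-only document without arrows.
#'
#' @param x list of [ReactionStep], [SchemeGraph], [Molecule], or list of
#'   molecules.
#' @param path optional file to write.
#' @return CDXML text (invisibly when `path` is given).
#' @export
writeCdxml <- function(x, path = NULL) {
  if (is(x, "SchemeGraph")) {
    out <- graphToCdxml(x)
  } else {
    if (is(x, "Molecule")) x <- list(x)
    if (is(x, "ReactionStep")) x <- list(x)
    gb <- graphBuilder("<export>")
    y <- 100
    for (item in x) {
      if (is(item, "ReactionStep")) {
        .layoutStep(gb, item, y)
        y <- y + 220
      } else if (is(item, "Molecule")) {
        tab <- placeTable(moleculeTable(item), 0, 0, 30)
        tab <- placeTable(tab, 120 + tableWidth(tab) / 2, y, 30)
        gb$addTable(tab)
        if (!is.na(item@label))
          gb$addText(item@label, 120 + tableWidth(tab) / 2,
                     y + tableHeight(tab) / 2 + 16)
        y <- y + 160
      } else stop("cannot export object of class ", class(item)[1])
    }
    out <- graphToCdxml(gb$graph())
  }
  if (!is.null(path)) { writeLines(out, path, sep = ""); return(invisible(out)) }
  out
}

# --- tabular ---------------------------------------------------------------

.timeString <- function(f) {
  if (!is.na(f$value)) paste0(fmtShort(f$value), " ", f$unit)
  else if (!is.na(f$token)) f$token else ""
}

#' Tabulate extracted steps
#'
#' One row per step with the fixed, documented column set:
#' `reaction_smiles`, semicolon-joined `reactants`/`reagents`/`products`
#' SMILES, `solvents`, `time`, `temperature`, `yield`, `status`,
#' `description`, `source`.
#'
#' @param steps list of [ReactionStep].
#' @param source provenance string repeated per row.
#' @return data frame.
#' @export
stepsToTable <- function(steps, source = "") {
  rows <- lapply(steps, function(s) data.frame(
    reaction_smiles = reactionSmiles(s, strict = FALSE),
    reactants = paste(vapply(s@reactants, canoSmiles, ""), collapse = ";"),
    reagents = paste(c(vapply(s@reagents, canoSmiles, ""),
                       s@reagentsSmiles), collapse = ";"),
    products = paste(vapply(s@products, canoSmiles, ""), collapse = ";"),
    solvents = paste(s@solventsSmiles, collapse = ";"),
    time = .timeString(s@time), temperature = .timeString(s@temperature),
    yield = ifelse(is.na(s@yield), "", fmtShort(s@yield)),
    status = s@status,
    description = ifelse(is.na(s@description), "", s@description),
    source = source, stringsAsFactors = FALSE))
  if (length(rows)) do.call(rbind, rows) else
    data.frame(reaction_smiles = character(), reactants = character(),
               reagents = character(), products = character(),
               solvents = character(), time = character(),
               temperature = character(), yield = character(),
               status = character(), description = character(),
               source = character(), stringsAsFactors = FALSE)
}

.csvField <- function(x) {
  x <- as.character(x)
  need <- grepl('[",\n\r]', x)
  x[need] <- paste0('"', gsub('"', '""', x[need]), '"')
  x
}

#' Write the step table as CSV or a minimal spreadsheet
#'
#' CSV output is RFC 4180 (CRLF line ends, quoting only where needed);
#' the spreadsheet variant writes the same grid as a minimal XLSX
#' workbook with inline strings.
#'
#' @param steps list of [ReactionStep].
#' @param format `"csv"` or `"xlsx"`.
#' @param path optional file to write.
#' @param source provenance string for the `source` column.
#' @return CSV text, or raw XLSX bytes (invisibly when `path` is given).
#' @export
writeTable <- function(steps, format = c("csv", "xlsx"), path = NULL,
                       source = "") {
  format <- match.arg(format)
  df <- stepsToTable(steps, source)
  if (format == "csv") {
    lines <- c(paste(.csvField(names(df)), collapse = ","),
               vapply(seq_len(nrow(df)), function(i)
                 paste(.csvField(unlist(df[i, ])), collapse = ","), ""))
    out <- paste0(paste(lines, collapse = "\r\n"), "\r\n")
    if (!is.null(path)) {
      con <- file(path, "wb"); writeBin(charToRaw(out), con); close(con)
      return(invisible(out))
    }
    return(out)
  }
  out <- .xlsxBytes(df)
  if (!is.null(path)) { writeBin(out, path); return(invisible(out)) }
  out
}

.xlsxBytes <- function(df) {
  cell <- function(v) sprintf("<c t=\"inlineStr\"><is><t>%s</t></is></c>",
                              xmlEscape(as.character(v)))
  rows <- c(paste0("<row>", paste(vapply(names(df), cell, ""),
                                  collapse = ""), "</row>"),
            vapply(seq_len(nrow(df)), function(i)
              paste0("<row>", paste(vapply(unlist(df[i, ]), cell, ""),
                                    collapse = ""), "</row>"), ""))
  sheet <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    "<sheetData>", paste(rows, collapse = ""), "</sheetData></worksheet>")
  workbook <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    '<sheets><sheet name="reactions" sheetId="1" r:id="rId1"/></sheets></workbook>')
  wbRels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" ',
    'Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" ',
    'Target="worksheets/sheet1.xml"/></Relationships>')
  rels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" ',
    'Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" ',
    'Target="xl/workbook.xml"/></Relationships>')
  types <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    '<Override PartName="/xl/worksheets/sheet1.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
    "</Types>")
  zipWrite(list(
    "[Content_Types].xml" = charToRaw(types),
    "_rels/.rels" = charToRaw(rels),
    "xl/workbook.xml" = charToRaw(workbook),
    "xl/_rels/workbook.xml.rels" = charToRaw(wbRels),
    "xl/worksheets/sheet1.xml" = charToRaw(sheet)))
}

#' Serialize extraction results as JSON
#'
#' @param result a scan result from [scanScheme()] or [scanDocument()],
#'   or a list of [ReactionStep].
#' @param path optional file to write.
#' @return JSON text (invisibly when `path` is given).
#' @export
stepsToJson <- function(result, path = NULL) {
  steps <- if (is.list(result) && !is.null(result$steps)) result$steps
           else result
  mols <- if (is.list(result) && !is.null(result$molecules))
    result$molecules else list()
  stepObj <- function(s) list(
    step_index = s@stepIndex,
    reaction_smiles = reactionSmiles(s, strict = FALSE),
    reactants = vapply(s@reactants, canoSmiles, ""),
    reagents = vapply(s@reagents, canoSmiles, ""),
    reagents_smiles = s@reagentsSmiles,
    solvents_smiles = s@solventsSmiles,
    products = vapply(s@products, canoSmiles, ""),
    time = s@time, temperature = s@temperature, yield = s@yield,
    status = s@status, description = s@description,
    incomplete = s@incomplete)
  obj <- list(steps = lapply(steps, stepObj),
              molecules = lapply(mols, function(m)
                list(cano_smiles = canoSmiles(m), label = m@label)))
  out <- jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null",
                          na = "null", pretty = TRUE)
  if (!is.null(path)) { writeLines(out, path); return(invisible(out)) }
  out
}
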
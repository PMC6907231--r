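# Programmatic construction of SchemeGraphs (used by the CDXML exporter
# and the fixture generator).

# Rigidly rescale/translate a chemistry table so its median bond length is
# `bond` drawing points and its bbox center sits at (cx, cy).
placeTable <- function(tab, cx, cy, bond = 30) {
  atoms <- tab$atoms
  scale <- 1
  if (nrow(tab$bonds)) {
    lens <- sqrt((atoms$x[tab$bonds$begin] - atoms$x[tab$bonds$end])^2 +
                 (atoms$y[tab$bonds$begin] - atoms$y[tab$bonds$end])^2)
    med <- stats::median(lens[lens > 0])
    if (is.finite(med) && med > 0) scale <- bond / med
  }
  atoms$x <- atoms$x * scale; atoms$y <- atoms$y * scale
  atoms$x <- atoms$x - (min(atoms$x) + max(atoms$x)) / 2 + cx
  atoms$y <- atoms$y - (min(atoms$y) + max(atoms$y)) / 2 + cy
  chemTable(atoms, tab$bonds)
}

tableWidth <- function(tab)
  if (nrow(tab$atoms)) diff(range(tab$atoms$x)) else 0

tableHeight <- function(tab)
  if (nrow(tab$atoms)) diff(range(tab$atoms$y)) else 0

# Incremental builder around the shared graph model.
graphBuilder <- function(source = "<built>") {
  env <- new.env(parent = emptyenv())
  env$nextId <- 0L
  env$fragments <- list()
  env$texts <- emptyTexts()
  env$arrows <- emptyArrows()
  env$newId <- function() { env$nextId <- env$nextId + 1L; env$nextId }
  env$addTable <- function(tab, abbrevs = NULL) {
    # abbrevs: data.frame(atom = row index, label =) turning plain atoms
    # into abbreviation nodes (their symbol is ignored)
    n <- nrow(tab$atoms)
    ids <- vapply(seq_len(n), function(i) env$newId(), 0L)
    kind <- ifelse(tab$atoms$symbol == "*", "r_group", "element")
    label <- ifelse(kind == "r_group", "R", NA_character_)
    if (!is.null(abbrevs))
      for (i in seq_len(nrow(abbrevs))) {
        kind[abbrevs$atom[i]] <- "abbreviation"
        label[abbrevs$atom[i]] <- abbrevs$label[i]
      }
    atoms <- data.frame(
      id = ids, element = ifelse(kind == "element",
                                 elementNumber(tab$atoms$symbol), 0L),
      charge = as.integer(tab$atoms$charge), isotope = tab$atoms$isotope,
      x = tab$atoms$x, y = tab$atoms$y, label = label, kind = kind,
      origId = ids, stringsAsFactors = FALSE)
    bonds <- tab$bonds
    if (nrow(bonds)) {
      bonds$begin <- ids[bonds$begin]
      bonds$end <- ids[bonds$end]
    } else bonds <- emptyBonds()
    env$fragments[[length(env$fragments) + 1L]] <-
      list(id = env$newId(), atoms = atoms, bonds = bonds, inner = list())
    invisible(length(env$fragments))
  }
  env$setInner <- function(fragIdx, atomRow, tab) {
    f <- env$fragments[[fragIdx]]
    env$fragments[[fragIdx]]$inner[[as.character(f$atoms$id[atomRow])]] <- tab
  }
  env$addText <- function(value, cx, cy, width = NULL, height = 12) {
    if (is.null(width)) width <- 6 * nchar(value)
    env$texts <- rbind(env$texts, data.frame(
      id = env$newId(), value = value, x = cx - width / 2, y = cy + height / 2,
      xmin = cx - width / 2, ymin = cy - height / 2, xmax = cx + width / 2,
      ymax = cy + height / 2, stringsAsFactors = FALSE))
  }
  env$addArrow <- function(tailx, taily, headx, heady, style = "plain") {
    env$arrows <- rbind(env$arrows, data.frame(
      id = env$newId(), tailx = tailx, taily = taily, headx = headx,
      heady = heady, style = style, stringsAsFactors = FALSE))
  }
  env$graph <- function() SchemeGraph(fragments = env$fragments,
                                      texts = env$texts, arrows = env$arrows,
                                      source = source)
  env
}
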
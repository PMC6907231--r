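# Seeded synthetic-scheme generator. Writes CDXML/CDX drawings (and
# container wrappers) together with machine-readable ground truth so every
# pipeline stage is testable without external data. The generator's
# defaults define the study conditions of the test suite: 1-4 step
# schemes, 1-3 reactants, 0-3 band members, coordinate jitter up to 10%
# of the 30-point bond length.

.defaultMoleculePool <- function() c(
  "CCO", "CC=O", "CC(=O)O", "CCOC(C)=O", "c1ccccc1", "Cc1ccccc1",
  "COc1ccccc1", "c1ccncc1", "C1CCCCC1", "CCN", "CC(C)O", "CCCBr",
  "CCCCl", "C=CC=O", "CC(=O)Cl", "Clc1ccccc1", "Nc1ccccc1", "Oc1ccccc1",
  "N#Cc1ccccc1", "OC(=O)c1ccccc1", "CC(C)(C)OC(=O)NC", "CCOC(=O)CC",
  "BrCC=C", "OCC1CCCCC1")

.reagentNamePool <- function() c("NEt3", "DMAP", "DBU", "K2CO3", "NaH",
                                 "Cs2CO3", "DIPEA", "TsOH", "PPh3", "TFA")

.solventNamePool <- function() c("THF", "DMF", "toluene", "MeCN", "DCM",
                                 "EtOH", "dioxane", "DMSO")

#' Draw a random scheme specification
#'
#' Reproducibly samples a multistep scheme: a linear chain of 1 to
#' `maxSteps` transformations over distinct pool molecules, 1-3
#' reactants on the first step, 0-3 band members (reagent names, a
#' solvent, a drawn reagent structure), conditions (temperature or a
#' qualitative token, time, yield) and arrow styles including dashed and
#' crossed.
#'
#' @param seed integer seed; fully determines the spec.
#' @param maxSteps maximum chain length (default 4).
#' @param pool molecule SMILES pool.
#' @param layouts arrangement tokens to sample from.
#' @param jitter coordinate noise amplitude as a fraction of the bond
#'   length (default 0.1).
#' @return a scheme spec list.
#' @export
randomSpec <- function(seed, maxSteps = 4, pool = .defaultMoleculePool(),
                       layouts = c("horizontal-chain", "wrapped-chain",
                                   "vertical"),
                       jitter = 0.1) {
  if (length(pool) < maxSteps + 3) stop("molecule pool too small")
  set.seed(seed)
  k <- sample.int(maxSteps, 1)
  chain <- sample(pool, k + 1)
  rest <- setdiff(pool, chain)
  steps <- list()
  for (i in seq_len(k)) {
    reactants <- chain[i]
    if (i == 1) {
      nExtra <- sample(0:2, 1)
      if (nExtra > 0) {
        reactants <- c(reactants, rest[seq_len(nExtra)])
        rest <- rest[-seq_len(nExtra)]
      }
    }
    nReagents <- sample(0:2, 1)
    reagentNames <- if (nReagents) sample(.reagentNamePool(), nReagents)
                    else character(0)
    solvent <- if (stats::runif(1) < 0.6) sample(.solventNamePool(), 1)
               else ""
    drawn <- character(0)
    if (stats::runif(1) < 0.3 && length(rest)) {
      drawn <- rest[1]; rest <- rest[-1]
    }
    temperature <- switch(sample(3, 1),
      list(value = sample(seq(0, 160, 10), 1), unit = "°C",
           token = NA_character_),
      list(value = NA_real_, unit = NA_character_,
           token = sample(c("rt", "reflux"), 1)),
      list(value = NA_real_, unit = NA_character_, token = NA_character_))
    time <- switch(sample(3, 1),
      list(value = sample(1:48, 1), unit = "h", token = NA_character_),
      list(value = sample(seq(10, 90, 10), 1), unit = "min",
           token = NA_character_),
      list(value = NA_real_, unit = NA_character_, token = NA_character_))
    yield <- if (stats::runif(1) < 0.6) sample(30:99, 1) else NA_real_
    style <- sample(c("plain", "dashed", "crossed"), 1,
                    prob = c(0.7, 0.15, 0.15))
    steps[[i]] <- list(reactants = reactants, reagentNames = reagentNames,
                       solvent = solvent, drawnReagents = drawn,
                       temperature = temperature, time = time,
                       yield = yield, product = chain[i + 1],
                       arrowStyle = style)
  }
  list(steps = steps, layout = sample(layouts, 1), jitter = jitter,
       seed = seed, labels = FALSE)
}

.truthCond <- function(f)
  list(value = if (is.na(f$value)) NA_real_ else as.numeric(f$value),
       unit = f$unit, token = f$token)

# Ground truth computed directly from the spec through the libraries
# (canonicalization of the input SMILES; solvent/reagent split by the
# solvent dictionary) — independent of the drawing and extraction path.
.groundTruth <- function(spec, libs) {
  steps <- lapply(seq_along(spec$steps), function(i) {
    st <- spec$steps[[i]]
    textSmiles <- vapply(st$reagentNames, function(n)
      resolveName(n, libs), "", USE.NAMES = FALSE)
    solventSmiles <- if (nzchar(st$solvent))
      resolveName(st$solvent, libs) else character(0)
    roles <- vapply(textSmiles, classifySmilesRole, "", libs = libs)
    list(reactants = sort(canonicalizeSmiles(st$reactants)),
         reagents = sort(c(canonicalizeSmiles(st$drawnReagents),
                           textSmiles[roles == "reagent"])),
         solvents = sort(c(solventSmiles, textSmiles[roles == "solvent"])),
         products = sort(canonicalizeSmiles(st$product)),
         time = .truthCond(st$time),
         temperature = .truthCond(st$temperature),
         yield = if (is.na(st$yield)) NA_real_ else as.numeric(st$yield),
         status = interpretArrowStyle(st$arrowStyle))
  })
  list(steps = steps)
}

.specCondText <- function(st) {
  parts <- character(0)
  if (nzchar(st$solvent)) parts <- c(parts, st$solvent)
  tmp <- st$temperature
  if (!is.na(tmp$value)) parts <- c(parts, paste0(fmtShort(tmp$value), " ",
                                                  tmp$unit))
  else if (!is.na(tmp$token)) parts <- c(parts, tmp$token)
  tm <- st$time
  if (!is.na(tm$value)) parts <- c(parts, paste0(fmtShort(tm$value), " ",
                                                 tm$unit))
  else if (!is.na(tm$token)) parts <- c(parts, tm$token)
  if (!is.na(st$yield)) parts <- c(parts, paste0(fmtShort(st$yield), "%"))
  paste(parts, collapse = ", ")
}

#' Generate a synthetic scheme with ground truth
#'
#' Lays the spec's molecules out on a 2-D grid honoring the arrangement
#' token (`horizontal-chain`, `wrapped-chain` with two steps per row and
#' the intermediate redrawn, or `vertical`), renders band members and
#' condition text around each arrow, applies bounded coordinate jitter,
#' and returns the CDXML text, the CDX binary serialization, the
#' in-memory graph and the machine-readable ground truth. Output bytes
#' are fully determined by the spec (including its seed).
#'
#' @param spec scheme spec from [randomSpec()] or hand-built.
#' @param libs a [ChemLibraries].
#' @return `list(cdxml, cdx, graph, truth)`.
#' @export
generateScheme <- function(spec, libs = loadLibraries()) {
  set.seed(spec$seed + 1013L)
  bond <- 30
  jit <- function() if (spec$jitter > 0)
    stats::runif(2, -spec$jitter * bond, spec$jitter * bond) else c(0, 0)
  for (st in spec$steps)
    for (sm in c(st$reactants, st$drawnReagents, st$product))
      if (is.na(canonicalizeSmiles(sm)))
        stop("spec contains unparsable SMILES: ", sm)
  gb <- graphBuilder(sprintf("fixture-seed-%d", spec$seed))
  vertical <- identical(spec$layout, "vertical")
  wrapAfter <- if (identical(spec$layout, "wrapped-chain")) 2L else 999L
  arrowLen <- 90; gapX <- 26; rowH <- 260
  tabs <- new.env(parent = emptyenv())
  molTab <- function(sm) {
    if (is.null(tabs[[sm]])) tabs[[sm]] <- placeTable(smilesToTable(sm),
                                                      0, 0, bond)
    tabs[[sm]]
  }
  placeAt <- function(sm, cx, cy) {
    j <- jit()
    gb$addTable(placeTable(molTab(sm), cx + j[1], cy + j[2], bond))
  }
  # arrow long enough that every band item's center stays inside the
  # 0.6 x length half-width band and the t-span of the arrow (as a
  # chemist stretches the arrow under a crowded band)
  arrowLenFor <- function(st) {
    offset <- 24
    hs <- c(16, vapply(st$drawnReagents, function(s)
      max(tableHeight(molTab(s)), 16), 0))
    ws <- c(vapply(st$drawnReagents, function(s)
      max(tableWidth(molTab(s)), 16), 0),
            if (length(st$reagentNames))
              6 * nchar(paste(st$reagentNames, collapse = ", ")) else 0)
    depth <- offset + max(hs) / 2 + 8
    spread <- (sum(ws) + 12 * max(length(ws) - 1, 0)) / 2
    max(arrowLen, depth / 0.55, spread / 0.5)
  }
  bandFor <- function(st, midx, midy, len) {
    offset <- 24
    if (!vertical) {
      # drawn reagent structures and the reagent-name text sit side by
      # side above the arrow; conditions go below
      ws <- vapply(st$drawnReagents, function(s)
        max(tableWidth(molTab(s)), 16), 0)
      txt <- if (length(st$reagentNames))
        paste(st$reagentNames, collapse = ", ") else NULL
      if (!is.null(txt)) ws <- c(ws, 6 * nchar(txt))
      if (length(ws)) {
        tot <- sum(ws) + 12 * (length(ws) - 1)
        bx <- midx - tot / 2
        k <- 0L
        for (dsm in st$drawnReagents) {
          k <- k + 1L
          h <- max(tableHeight(molTab(dsm)), 16)
          placeAt(dsm, bx + ws[k] / 2, midy - offset - h / 2)
          bx <- bx + ws[k] + 12
        }
        if (!is.null(txt)) {
          j <- jit()
          gb$addText(txt, bx + ws[length(ws)] / 2 + j[1],
                     midy - offset - 8 + j[2])
        }
      }
      ct <- .specCondText(st)
      if (nzchar(ct)) {
        j <- jit()
        gb$addText(ct, midx + j[1], midy + offset + 6 + j[2])
      }
    } else {
      # vertical arrow: band content right of the axis, stacked along
      # it; conditions left of the axis
      by <- midy - len / 4
      for (dsm in st$drawnReagents) {
        placeAt(dsm, midx + 40, by)
        by <- by + max(tableHeight(molTab(dsm)), 16) / 2 + 16
      }
      if (length(st$reagentNames)) {
        j <- jit()
        gb$addText(paste(st$reagentNames, collapse = ", "),
                   midx + 40 + j[1], by + j[2])
      }
      ct <- .specCondText(st)
      if (nzchar(ct)) {
        j <- jit()
        gb$addText(ct, midx - 40 + j[1], midy + j[2])
      }
    }
  }
  if (!vertical) {
    x <- 60; y <- 150; col <- 0L
    for (i in seq_along(spec$steps)) {
      st <- spec$steps[[i]]
      newRow <- col >= wrapAfter
      if (newRow) { y <- y + rowH; x <- 60; col <- 0L }
      drawLead <- (i == 1) || newRow
      if (drawLead) {
        for (r in seq_along(st$reactants)) {
          if (r > 1) { gb$addText("+", x + 10, y); x <- x + 22 }
          w <- max(tableWidth(molTab(st$reactants[r])), bond)
          placeAt(st$reactants[r], x + w / 2, y)
          x <- x + w + gapX
        }
      } else if (length(st$reactants) > 1) {
        for (r in seq_along(st$reactants)[-1]) {
          gb$addText("+", x + 10, y); x <- x + 22
          w <- max(tableWidth(molTab(st$reactants[r])), bond)
          placeAt(st$reactants[r], x + w / 2, y)
          x <- x + w + gapX
        }
      }
      aLen <- arrowLenFor(st)
      gb$addArrow(x, y, x + aLen, y, st$arrowStyle)
      bandFor(st, x + aLen / 2, y, aLen)
      x <- x + aLen + gapX
      w <- max(tableWidth(molTab(st$product)), bond)
      placeAt(st$product, x + w / 2, y)
      if (isTRUE(spec$labels)) {
        h <- tableHeight(molTab(st$product))
        gb$addText(paste0(i), x + w / 2, y + h / 2 + 18)
      }
      x <- x + w + gapX
      col <- col + 1L
    }
  } else {
    x <- 200; y <- 80
    for (i in seq_along(spec$steps)) {
      st <- spec$steps[[i]]
      if (i == 1) {
        # co-reactants stacked on the axis above the first arrow
        for (r in seq_along(st$reactants)) {
          if (r > 1) { gb$addText("+", x + 20, y + 8); y <- y + 20 }
          h <- max(tableHeight(molTab(st$reactants[r])), bond)
          placeAt(st$reactants[r], x + 20, y + h / 2)
          y <- y + h + 10
        }
        y <- y + 6
      }
      stack <- sum(vapply(st$drawnReagents, function(s)
        max(tableHeight(molTab(s)), 16) / 2 + 16, 0)) +
        (if (length(st$reagentNames)) 14 else 0)
      aLen <- max(arrowLen, 2.2 * stack)
      gb$addArrow(x + 20, y, x + 20, y + aLen, st$arrowStyle)
      bandFor(st, x + 20, y + aLen / 2, aLen)
      y <- y + aLen + 16
      h <- max(tableHeight(molTab(st$product)), bond)
      placeAt(st$product, x + 20, y + h / 2)
      if (isTRUE(spec$labels))
        gb$addText(paste0(i), x + 20, y + h + 18)
      y <- y + h + 16
    }
  }
  graph <- gb$graph()
  list(cdxml = graphToCdxml(graph), cdx = writeCdx(graph), graph = graph,
       truth = .groundTruth(spec, libs))
}

#' Compare an extraction result against fixture ground truth
#'
#' Field-by-field comparison of the extracted steps with a
#' [generateScheme()] ground truth: role sets as sorted canonical
#' SMILES, status, time, temperature and yield. Returns a character
#' vector of human-readable mismatches, empty when extraction is exact.
#'
#' @param result scan result from [scanScheme()].
#' @param truth ground truth from [generateScheme()].
#' @return character vector of mismatch descriptions.
#' @export
compareToTruth <- function(result, truth) {
  errs <- character(0)
  say <- function(...) errs <<- c(errs, sprintf(...))
  if (length(result$steps) != length(truth$steps)) {
    say("expected %d steps, got %d", length(truth$steps),
        length(result$steps))
    return(errs)
  }
  condEq <- function(a, b)
    isTRUE(all.equal(a$value, b$value)) && identical(
      is.na(a$unit), is.na(b$unit)) &&
      (is.na(a$unit) || a$unit == b$unit) &&
      identical(is.na(a$token), is.na(b$token)) &&
      (is.na(a$token) || a$token == b$token)
  for (i in seq_along(truth$steps)) {
    tr <- truth$steps[[i]]; st <- result$steps[[i]]
    setEq <- function(what, got, want) {
      if (!identical(sort(unique(got)), sort(unique(want))))
        say("step %d %s: got {%s}, want {%s}", i, what,
            paste(got, collapse = ","), paste(want, collapse = ","))
    }
    setEq("reactants", vapply(st@reactants, canoSmiles, ""), tr$reactants)
    setEq("products", vapply(st@products, canoSmiles, ""), tr$products)
    setEq("reagents", c(vapply(st@reagents, canoSmiles, ""),
                        st@reagentsSmiles), tr$reagents)
    setEq("solvents", st@solventsSmiles, tr$solvents)
    if (st@status != tr$status)
      say("step %d status: got %s, want %s", i, st@status, tr$status)
    if (!condEq(st@time, tr$time))
      say("step %d time mismatch", i)
    if (!condEq(st@temperature, tr$temperature))
      say("step %d temperature mismatch", i)
    if (!identical(is.na(st@yield), is.na(tr$yield)) ||
        (!is.na(tr$yield) && st@yield != tr$yield))
      say("step %d yield: got %s, want %s", i, st@yield, tr$yield)
  }
  errs
}

#' Wrap a payload in a document container
#'
#' Builds a minimal but standards-conforming container from which
#' [extractFromDocx()] / [extractFromDoc()] / [extractFromElnXml()]
#' recover the payload byte-identically: a DOCX (OPC zip with the CDX
#' inside an OLE-wrapped embedded object), a DOC (OLE compound file with
#' an object-pool storage), or an ELN-export XML (CDXML island plus a
#' reaction table).
#'
#' @param payload raw CDX bytes (`docx`, `doc`) or CDXML text
#'   (`eln_xml`).
#' @param kind `"docx"`, `"doc"` or `"eln_xml"`.
#' @param records optional data frame (`role`, `identifier`, ...) for
#'   the ELN reaction table.
#' @return raw vector (`docx`, `doc`) or XML text (`eln_xml`).
#' @export
wrapInContainer <- function(payload, kind = c("docx", "doc", "eln_xml"),
                            records = NULL) {
  kind <- match.arg(kind)
  if (kind == "docx") {
    if (is.raw(payload)) payload <- list(payload)
    members <- list(
      "[Content_Types].xml" = charToRaw(paste0(
        '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
        '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
        '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
        '<Default Extension="xml" ContentType="application/xml"/>',
        '<Default Extension="bin" ContentType="application/vnd.openxmlformats-officedocument.oleObject"/>',
        "</Types>")),
      "_rels/.rels" = charToRaw(paste0(
        '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
        '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
        '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="word/document.xml"/>',
        "</Relationships>")),
      "word/document.xml" = charToRaw(paste0(
        '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
        '<w:document xmlns:w="http://schemas.openxmlformats.org/wordprocessingml/2006/main">',
        "<w:body/></w:document>")))
    for (i in seq_along(payload))
      members[[sprintf("word/embeddings/oleObject%d.bin", i)]] <-
        cfbWrite(list("CONTENTS" = payload[[i]]))
    return(zipWrite(members))
  }
  if (kind == "doc") {
    if (!is.list(payload)) payload <- list(payload)
    streams <- list("WordDocument" = charToRaw(
      "synthetic minimal Word binary fixture"))
    for (i in seq_along(payload))
      streams[[sprintf("ObjectPool/_10000%04d/CONTENTS", i)]] <-
        payload[[i]]
    return(cfbWrite(streams))
  }
  # eln_xml
  body <- sub("^<\\?xml[^>]*\\?>\\s*", "", payload)
  body <- sub("\\s+$", "", body)
  rows <- ""
  if (!is.null(records) && nrow(records)) {
    getc <- function(df, col) if (col %in% names(df)) df[[col]] else
      rep("", nrow(df))
    rows <- paste(sprintf(
      '   <row role="%s" identifier="%s" amount="%s" conditions="%s" observations="%s"/>',
      xmlEscape(records$role), xmlEscape(records$identifier),
      xmlEscape(getc(records, "amounts")),
      xmlEscape(getc(records, "conditions")),
      xmlEscape(getc(records, "observations"))), collapse = "\n")
    rows <- paste0("  <reactionTable>\n", rows, "\n  </reactionTable>\n")
  }
  paste0('<?xml version="1.0" encoding="UTF-8"?>\n<elnExport>\n <experiment>\n',
         body, "\n", rows, " </experiment>\n</elnExport>\n")
}
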
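# Reaction assembly: correlate object geometry with reaction roles per
# arrow (reactants beyond the tail, products beyond the head, reagents and
# solvents in the band around the arrow), interpret arrow styles, and
# split multistep schemes into single-step reactions.

#' Default geometry configuration for role assignment
#'
#' * `bandFrac`: band half-width as a fraction of arrow length (0.6),
#' * `bandCapBonds`: cap on the half-width in median bond lengths (4),
#' * `axisCapFrac`: band t-interval extension beyond tail/head (0.15),
#' * `onAxisFrac`: fraction of the half-width treated as "on the axis"
#'   when deciding side-vs-band in the extended caps (0.25),
#' * `gapFrac`: head-to-tail adjacency threshold for chaining arrows, as
#'   a fraction of arrow length (0.25),
#' * `labelDistBonds`: maximum label-below-structure distance in median
#'   bond lengths (1.5).
#'
#' @return named list of tunables.
#' @export
defaultScanConfig <- function()
  list(bandFrac = 0.6, bandCapBonds = 4, axisCapFrac = 0.15,
       onAxisFrac = 0.25, gapFrac = 0.25, labelDistBonds = 1.5)

.bandHalfWidth <- function(arrow, config, medBond) {
  hw <- config$bandFrac * arrowLength(arrow)
  if (is.finite(medBond)) hw <- min(hw, config$bandCapBonds * medBond)
  hw
}

#' Assign scheme objects to one arrow's role zones
#'
#' Projects every fragment and text bbox center onto the arrow axis:
#' beyond the tail (`t < 0`) is the reactant side, beyond the head
#' (`t > 1`) the product side, and the band around the arrow span (with a
#' small extension beyond tail and head) holds reagents, solvents and
#' condition text. Objects outside all zones are left unassigned for
#' other arrows.
#'
#' @param graph a [SchemeGraph].
#' @param arrow one row of `graph@arrows` (or an equivalent list).
#' @param config see [defaultScanConfig()].
#' @param medBond median bond length (computed when missing).
#' @param textKeep logical vector marking texts still available (labels
#'   and R-group definitions are consumed earlier).
#' @return a step context: `list(arrow, halfWidth, members)` with
#'   `members` a data frame of `kind`, `idx`, `role`, `t`, `d`, `dist`.
#' @export
assignRoles <- function(graph, arrow, config = defaultScanConfig(),
                        medBond = medianBondLength(graph),
                        textKeep = rep(TRUE, nrow(graph@texts))) {
  if (arrowLength(arrow) == 0) stop("zero-length arrow")
  hw <- .bandHalfWidth(arrow, config, medBond)
  cap <- config$axisCapFrac
  members <- data.frame(kind = character(), idx = integer(),
                        role = character(), t = numeric(), d = numeric(),
                        dist = numeric(), stringsAsFactors = FALSE)
  addMember <- function(kind, idx, role, pr, dist)
    members <<- rbind(members, data.frame(
      kind = kind, idx = idx, role = role, t = pr[["t"]], d = pr[["d"]],
      dist = dist, stringsAsFactors = FALSE))
  tailP <- c(arrow$tailx, arrow$taily); headP <- c(arrow$headx, arrow$heady)
  for (i in seq_along(graph@fragments)) {
    ctr <- rectCenter(fragmentBbox(graph@fragments[[i]]))
    pr <- projectOnArrow(ctr, arrow)
    tt <- pr[["t"]]; ad <- abs(pr[["d"]])
    if (tt >= 0 && tt <= 1 && ad <= hw) {
      addMember("fragment", i, "band", pr, ad)
    } else if (tt >= -cap && tt <= 1 + cap && ad > config$onAxisFrac * hw &&
               ad <= hw) {
      addMember("fragment", i, "band", pr, ad)
    } else if (tt < 0 && ad <= hw) {
      addMember("fragment", i, "reactant", pr, sqrt(sum((ctr - tailP)^2)))
    } else if (tt > 1 && ad <= hw) {
      addMember("fragment", i, "product", pr, sqrt(sum((ctr - headP)^2)))
    }
  }
  for (i in seq_len(nrow(graph@texts))) {
    if (!textKeep[i]) next
    ctr <- rectCenter(textBbox(graph@texts[i, ]))
    pr <- projectOnArrow(ctr, arrow)
    tt <- pr[["t"]]; ad <- abs(pr[["d"]])
    if (tt >= -cap && tt <= 1 + cap && ad <= hw) {
      addMember("text", i, "band", pr, ad)
    } else if (tt > 1 && ad <= hw) {
      addMember("text", i, "productText", pr, sqrt(sum((ctr - headP)^2)))
    }
  }
  list(arrow = arrow, halfWidth = hw, members = members)
}

#' Interpret an arrow's drawing style as a reaction status
#'
#' A strike through an arrow signals a failed reaction, a dashed arrow a
#' planned one, and a plain arrow a (presumed) successful one.
#'
#' @param a arrow row, context, or style string.
#' @return `"failed"`, `"planned"` or `"success"`.
#' @export
interpretArrowStyle <- function(a) {
  style <- if (is.character(a) && length(a) == 1) a
    else if (!is.null(a$style)) a$style
    else if (!is.null(a$arrow)) a$arrow$style
    else "plain"
  switch(style, crossed = "failed", dashed = "planned", "success")
}

# Reading order of arrows: rows top-to-bottom (grouped within a vertical
# tolerance), left-to-right within a row.
.readingOrder <- function(arrows, medBond) {
  if (nrow(arrows) <= 1) return(seq_len(nrow(arrows)))
  y <- (arrows$taily + arrows$heady) / 2
  x <- pmin(arrows$tailx, arrows$headx)
  tol <- max(2 * ifelse(is.finite(medBond), medBond, 20), 20)
  ord <- order(y)
  row <- integer(nrow(arrows)); cur <- 1L; row[ord[1]] <- 1L
  for (k in seq_along(ord)[-1]) {
    if (y[ord[k]] - y[ord[k - 1]] > tol) cur <- cur + 1L
    row[ord[k]] <- cur
  }
  order(row, x)
}

#' Link per-arrow contexts into single-step reactions
#'
#' Orders arrows into chains: arrow i feeds arrow j when they share a
#' fragment (product of i = reactant of j), when i's head is adjacent to
#' j's tail, or — for wrapped multi-row chains where the intermediate is
#' redrawn — when they are consecutive in reading order and a product
#' SMILES of i reappears among j's reactants. Each chain emits one
#' [ReactionStep] per arrow with a sequential `stepIndex`; a fragment
#' serving as product of step i and reactant of step i+1 appears in both.
#' Steps with an empty side are flagged incomplete, never dropped.
#'
#' @param graph a [SchemeGraph].
#' @param contexts list of step contexts from [assignRoles()] (one per
#'   arrow, same order as `graph@arrows`).
#' @param molecules list of built [Molecule]s parallel to
#'   `graph@fragments`.
#' @param libs a [ChemLibraries].
#' @param config see [defaultScanConfig()].
#' @return list of [ReactionStep].
#' @export
linkSteps <- function(graph, contexts, molecules, libs,
                      config = defaultScanConfig()) {
  nA <- length(contexts)
  if (nA == 0) return(list())
  # cross-arrow tie-break: an object claimed by two arrows in the same
  # role goes to the nearer arrow
  all <- do.call(rbind, lapply(seq_len(nA), function(ai) {
    m <- contexts[[ai]]$members
    if (nrow(m)) m$arrow <- ai
    m
  }))
  if (!is.null(all) && nrow(all)) {
    key <- paste(all$kind, all$idx, all$role)
    keep <- unlist(lapply(split(seq_len(nrow(all)), key), function(ii)
      ii[which.min(all$dist[ii])]))
    all <- all[sort(keep), , drop = FALSE]
    # band-vs-side arbitration: an object claimed both by some arrow's
    # band and by another arrow's side/product-text zone belongs to the
    # nearer of the two (a chain intermediate keeps both its product and
    # reactant roles: those are side roles of two different arrows)
    keep2 <- unlist(lapply(split(seq_len(nrow(all)),
                                 paste(all$kind, all$idx)), function(ii) {
      isBand <- all$role[ii] == "band"
      if (!any(isBand) || all(isBand)) return(ii)
      if (min(all$dist[ii[isBand]]) <= min(all$dist[ii[!isBand]]))
        ii[isBand] else ii[!isBand]
    }))
    all <- all[sort(keep2), , drop = FALSE]
  } else {
    all <- data.frame(kind = character(), idx = integer(), role = character(),
                      t = numeric(), d = numeric(), dist = numeric(),
                      arrow = integer())
  }
  memb <- function(ai, kind, role) {
    m <- all[all$arrow == ai & all$kind == kind & all$role == role, ,
             drop = FALSE]
    if (kind == "fragment") {
      cx <- vapply(m$idx, function(i)
        rectCenter(fragmentBbox(graph@fragments[[i]]))[1], 0)
      m$idx[order(cx)]
    } else m$idx[order(m$dist)]
  }
  reac <- lapply(seq_len(nA), memb, "fragment", "reactant")
  prod <- lapply(seq_len(nA), memb, "fragment", "product")
  bandF <- lapply(seq_len(nA), memb, "fragment", "band")
  bandT <- lapply(seq_len(nA), memb, "text", "band")
  prodT <- lapply(seq_len(nA), memb, "text", "productText")

  medBond <- medianBondLength(graph)
  rd <- .readingOrder(graph@arrows, medBond)
  pos <- match(seq_len(nA), rd)
  smilesOf <- function(ii) vapply(molecules[ii], canoSmiles, "")
  edges <- matrix(FALSE, nA, nA)
  for (i in seq_len(nA)) for (j in seq_len(nA)) {
    if (i == j) next
    ai <- graph@arrows[i, ]; aj <- graph@arrows[j, ]
    if (length(intersect(prod[[i]], reac[[j]]))) edges[i, j] <- TRUE
    else {
      gap <- sqrt((ai$headx - aj$tailx)^2 + (ai$heady - aj$taily)^2)
      if (gap <= config$gapFrac * max(arrowLength(ai), arrowLength(aj)))
        edges[i, j] <- TRUE
      else if (pos[j] == pos[i] + 1L &&
               length(intersect(smilesOf(prod[[i]]), smilesOf(reac[[j]]))))
        edges[i, j] <- TRUE
    }
  }
  # cycle check (DFS over the successor relation)
  colorState <- integer(nA)
  visit <- function(v) {
    colorState[v] <<- 1L
    for (w in which(edges[v, ])) {
      if (colorState[w] == 1L) stop("cyclic scheme")
      if (colorState[w] == 0L) visit(w)
    }
    colorState[v] <<- 2L
  }
  for (v in seq_len(nA)) if (colorState[v] == 0L) visit(v)

  starts <- which(colSums(edges) == 0)
  starts <- starts[order(pos[starts])]
  seen <- logical(nA)
  steps <- list()
  for (s in starts) {
    v <- s; k <- 0L
    while (!is.na(v) && !seen[v]) {
      seen[v] <- TRUE; k <- k + 1L
      steps[[length(steps) + 1L]] <-
        .buildStep(v, k, graph, contexts, molecules, libs,
                   reac[[v]], prod[[v]], bandF[[v]], bandT[[v]], prodT[[v]])
      nxt <- which(edges[v, ] & !seen)
      v <- if (length(nxt)) nxt[order(pos[nxt])][1] else NA_integer_
    }
  }
  # arrows unreachable from any start (defensive; cycles already error)
  for (v in which(!seen))
    steps[[length(steps) + 1L]] <-
      .buildStep(v, 1L, graph, contexts, molecules, libs,
                 reac[[v]], prod[[v]], bandF[[v]], bandT[[v]], prodT[[v]])
  steps
}

.buildStep <- function(ai, stepIndex, graph, contexts, molecules, libs,
                       reacIdx, prodIdx, bandFIdx, bandTIdx, prodTIdx) {
  step <- ReactionStep(
    reactants = molecules[reacIdx], products = molecules[prodIdx],
    reagents = molecules[bandFIdx],
    status = interpretArrowStyle(graph@arrows[ai, ]),
    stepIndex = stepIndex,
    incomplete = length(reacIdx) == 0 || length(prodIdx) == 0)
  attachBandContent(step, graph@texts$value[bandTIdx],
                    graph@texts$value[prodTIdx], libs)
}

#' Attach band text content to a step
#'
#' Band fragments have already been appended as reagent molecules; this
#' routes band *text* through the text interpreter: identified compounds
#' are split solvent-vs-reagent via [classifySmilesRole()], condition
#' tokens are merged into the step (first value wins), a percentage in
#' the band or next to the product becomes the yield, and residual text
#' is kept as the step description.
#'
#' @param step a [ReactionStep].
#' @param bandTexts character vector of band text values.
#' @param productTexts character vector of product-adjacent text values.
#' @param libs a [ChemLibraries].
#' @return the enriched [ReactionStep].
#' @export
attachBandContent <- function(step, bandTexts, productTexts = character(0),
                              libs) {
  residue <- character(0)
  for (v in bandTexts) {
    if (identical(trimws(v), "+")) next  # co-reactant separator
    cls <- classifyTextBlock(v, libs)
    for (sm in cls$smiles) {
      if (classifySmilesRole(sm, libs) == "solvent")
        step@solventsSmiles <- c(step@solventsSmiles, sm)
      else step@reagentsSmiles <- c(step@reagentsSmiles, sm)
    }
    cs <- cls$conditions
    if (is.na(step@time$value) && is.na(step@time$token) &&
        (!is.na(cs$time$value) || !is.na(cs$time$token)))
      step@time <- cs$time
    if (is.na(step@temperature$value) && is.na(step@temperature$token) &&
        (!is.na(cs$temperature$value) || !is.na(cs$temperature$token)))
      step@temperature <- cs$temperature
    if (!is.na(cs$yield)) {
      if (is.na(step@yield)) step@yield <- cs$yield
      else warning("conflicting yield values; keeping the first")
    }
    residue <- c(residue, cls$residue)
  }
  y <- extractYield(productTexts, step)
  if (!is.na(y) && is.na(step@yield)) step@yield <- y
  if (length(residue))
    step@description <- paste(residue, collapse = "; ")
  step
}

#' Extract a yield percentage from nearby text
#'
#' Binds the first percentage token found in the supplied texts (band or
#' product-adjacent) to the step; conflicting duplicates keep the first
#' with a warning.
#'
#' @param texts character vector of candidate texts.
#' @param step a [ReactionStep] (its current yield, if any, wins).
#' @return numeric percent or `NA`.
#' @export
extractYield <- function(texts, step = NULL) {
  found <- NA_real_
  for (v in texts) {
    for (tok in .condTokens(v)) {
      m <- regmatches(tok, regexec(
        paste0("^(?:(?:yield|yld)\\s*:?\\s*)?(", .NUM_RE, ")\\s*%$"), tok,
        ignore.case = TRUE))[[1]]
      if (length(m)) {
        v2 <- as.numeric(m[2])
        if (v2 < 0 || v2 > 100) next
        if (is.na(found)) found <- v2
        else if (found != v2) warning("conflicting yields; keeping the first")
      }
    }
  }
  if (!is.null(step) && !is.na(step@yield) && !is.na(found) &&
      found != step@yield) {
    warning("conflicting yields; keeping the first")
    return(NA_real_)
  }
  found
}

#' Extract molecules and reactions from one drawing
#'
#' Runs the full per-scheme pipeline: builds molecules for every fragment
#' (expanding abbreviations and applying any `R = <group>` definitions
#' found in the scheme text), attaches compound labels, assigns every
#' object to an arrow's role zones, splits multistep chains into
#' single-step reactions and interprets band text. Fragments in no
#' arrow's zones are reported as isolated molecules — nothing is silently
#' dropped.
#'
#' @param graph a [SchemeGraph].
#' @param libs a [ChemLibraries] (default: the seed libraries).
#' @param config see [defaultScanConfig()].
#' @return `list(steps = <list of ReactionStep>, molecules = <isolated
#'   Molecules>, allMolecules, graph)`.
#' @export
scanScheme <- function(graph, libs = loadLibraries(),
                       config = defaultScanConfig()) {
  medBond <- medianBondLength(graph)
  rdefs <- findRgroupDefs(graph@texts, libs)
  molecules <- lapply(graph@fragments, buildMolecule, libs = libs,
                      rgroupDefs = rdefs)
  textKeep <- rep(TRUE, nrow(graph@texts))
  # consume R-group definition texts
  for (i in seq_len(nrow(graph@texts)))
    if (grepl("^\\s*(R\\d*'*|X\\d*)\\s*=\\s*[A-Za-z0-9]+\\s*$",
              graph@texts$value[i])) textKeep[i] <- FALSE
  # compound labels: short alphanumeric token directly below a structure
  if (length(molecules) && nrow(graph@texts) && is.finite(medBond)) {
    maxDist <- config$labelDistBonds * medBond
    for (i in seq_len(nrow(graph@texts))) {
      if (!textKeep[i] || !.isLabelText(graph@texts$value[i])) next
      tb <- textBbox(graph@texts[i, ])
      tc <- rectCenter(tb)
      for (k in seq_along(graph@fragments)) {
        fb <- fragmentBbox(graph@fragments[[k]])
        xOverlap <- tc[1] >= fb[[1]] - maxDist && tc[1] <= fb[[3]] + maxDist
        below <- tb[[2]] >= fb[[4]] - 1e-6 && tb[[2]] - fb[[4]] <= maxDist
        if (xOverlap && below) {
          molecules[[k]]@label <- graph@texts$value[i]
          textKeep[i] <- FALSE
          break
        }
      }
    }
  }
  contexts <- lapply(seq_len(nrow(graph@arrows)), function(ai)
    assignRoles(graph, graph@arrows[ai, ], config, medBond, textKeep))
  steps <- linkSteps(graph, contexts, molecules, libs, config)
  used <- integer(0)
  for (ctx in contexts) {
    m <- ctx$members
    used <- union(used, m$idx[m$kind == "fragment"])
  }
  isolated <- molecules[setdiff(seq_along(molecules), used)]
  list(steps = steps, molecules = isolated, allMolecules = molecules,
       graph = graph)
}
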
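# Molecule construction: fragment -> chemically valid Molecule with
# abbreviations expanded, limitation rules applied, and both renderings
# (canonical SMILES, Molfile) populated.

# Convert a fragment's atoms/bonds (global ids) to a chemistry table with
# 1-based row indices; abbreviation and r_group nodes keep symbol "*"
# until expansion.
fragmentToTable <- function(f) {
  atoms <- data.frame(
    symbol = ifelse(f$atoms$kind == "element", elementSymbol(f$atoms$element),
                    "*"),
    x = f$atoms$x, y = f$atoms$y,
    charge = ifelse(is.na(f$atoms$charge), 0L, f$atoms$charge),
    isotope = f$atoms$isotope, stringsAsFactors = FALSE)
  bonds <- f$bonds
  if (nrow(bonds)) {
    bonds$begin <- match(bonds$begin, f$atoms$id)
    bonds$end <- match(bonds$end, f$atoms$id)
  }
  chemTable(atoms, bonds)
}

#' Expand one superatom abbreviation in a chemistry table
#'
#' Replaces the node at row `nodeIdx` by the entry's expansion, grafting
#' the expansion's attachment markers (dummy `*` atoms, ordered by their
#' position in the expansion SMILES) onto the node's neighbors; bond
#' orders to the neighbors are preserved. When the node degree does not
#' match the entry's attachment count the node is left as a wildcard atom
#' and a warning is emitted.
#'
#' @param tab chemistry table.
#' @param nodeIdx 1-based row of the abbreviation node.
#' @param entryTab expansion chemistry table (marker atoms have symbol
#'   `"*"`); typically from [resolveSuperatom()].
#' @param label node label, used in warnings.
#' @return the expanded chemistry table.
#' @export
expandAbbreviation <- function(tab, nodeIdx, entryTab, label = "?") {
  markers <- which(entryTab$atoms$symbol == "*")
  extBonds <- which(tab$bonds$begin == nodeIdx | tab$bonds$end == nodeIdx)
  if (length(extBonds) != length(markers)) {
    warning("superatom '", label, "' has ", length(markers),
            " attachment(s) but the node is drawn with ", length(extBonds),
            " bond(s); left as wildcard")
    return(tab)
  }
  keep <- setdiff(seq_len(nrow(entryTab$atoms)), markers)
  nOld <- nrow(tab$atoms)
  # rigid translation of the expansion so its first kept atom sits at the
  # abbreviation node's drawn position (coordinates are cosmetic here)
  ex <- entryTab$atoms[keep, , drop = FALSE]
  if (nrow(ex)) {
    ex$x <- ex$x - ex$x[1] + tab$atoms$x[nodeIdx]
    ex$y <- ex$y - ex$y[1] + tab$atoms$y[nodeIdx]
  }
  newIdx <- integer(nrow(entryTab$atoms))
  newIdx[keep] <- nOld + seq_along(keep)
  atoms <- rbind(tab$atoms, ex)
  bonds <- tab$bonds
  inBonds <- entryTab$bonds
  # bonds internal to the expansion (marker bonds re-routed below)
  for (i in seq_len(nrow(inBonds))) {
    b <- inBonds$begin[i]; e <- inBonds$end[i]
    if (b %in% markers || e %in% markers) next
    bonds <- rbind(bonds, data.frame(
      begin = newIdx[b], end = newIdx[e], order = inBonds$order[i],
      display = "plain", coordinative = FALSE, stringsAsFactors = FALSE))
  }
  # graft: k-th marker takes the k-th external neighbor, keeping the
  # external bond's order and display
  for (k in seq_along(markers)) {
    m <- markers[k]
    bi <- extBonds[k]
    nb <- if (tab$bonds$begin[bi] == nodeIdx) tab$bonds$end[bi]
          else tab$bonds$begin[bi]
    att <- inBonds[inBonds$begin == m | inBonds$end == m, , drop = FALSE]
    for (j in seq_len(nrow(att))) {
      other <- if (att$begin[j] == m) att$end[j] else att$begin[j]
      bonds <- rbind(bonds, data.frame(
        begin = nb, end = newIdx[other], order = tab$bonds$order[bi],
        display = tab$bonds$display[bi],
        coordinative = tab$bonds$coordinative[bi], stringsAsFactors = FALSE))
    }
  }
  bonds <- bonds[!(bonds$begin == nodeIdx | bonds$end == nodeIdx), ,
                 drop = FALSE]
  dropRow <- nodeIdx
  remap <- seq_len(nrow(atoms)); remap[remap > dropRow] <- remap[remap > dropRow] - 1L
  atoms <- atoms[-dropRow, , drop = FALSE]
  bonds$begin <- remap[bonds$begin]; bonds$end <- remap[bonds$end]
  rownames(atoms) <- NULL; rownames(bonds) <- NULL
  chemTable(atoms, bonds)
}

#' Canonical SMILES of a chemistry table or Molecule
#'
#' Deterministic canonical form; tetrahedral stereo is included only when
#' it is encoded by wedge or hashed-wedge bond displays in the drawing.
#' Coordinative bonds have no SMILES representation and are omitted.
#'
#' @param m a [Molecule] or chemistry table.
#' @return canonical SMILES string.
#' @export
canonicalSmiles <- function(m) {
  if (is(m, "Molecule")) return(m@canoSmiles)
  tableCanonicalSmiles(m)
}

#' Write a Molecule as Molfile V2000
#'
#' 2-D coordinates come from the drawing positions rescaled to a 1.5-unit
#' standard bond length; coordinative bonds are written as bond type 9.
#'
#' @param m a [Molecule] or chemistry table.
#' @param name header-line name.
#' @return Molfile text.
#' @export
toMolfile <- function(m, name = "") tableToMolfile(m, name)

#' Build a Molecule from a fragment
#'
#' Expands abbreviation nodes (the drawing's own nested expansion is
#' authoritative when present; otherwise the superatom library is
#' consulted), turns R-group nodes into wildcard atoms unless a
#' well-defined `R = <superatom>` definition is supplied, carries charges
#' and isotopes through, and populates both renderings. An abbreviation
#' with no library hit becomes a wildcard atom with a warning, never a
#' failure.
#'
#' @param f fragment record from a [SchemeGraph].
#' @param libs a [ChemLibraries].
#' @param rgroupDefs named character vector mapping R-group labels to
#'   superatom keys (from nearby `R = Me`-style texts).
#' @return a [Molecule].
#' @export
buildMolecule <- function(f, libs, rgroupDefs = character(0)) {
  tab <- fragmentToTable(f)
  # map from current row index to the original atom id, maintained across
  # expansions so inner-fragment lookup stays valid
  rowIds <- f$atoms$id
  repeat {
    idx <- which(vapply(seq_len(nrow(tab$atoms)), function(i) {
      k <- f$atoms$kind[match(rowIds[i], f$atoms$id)]
      !is.na(k) && k %in% c("abbreviation", "r_group")
    }, TRUE))
    if (length(idx) == 0) break
    i <- idx[1]
    aid <- rowIds[i]
    arow <- match(aid, f$atoms$id)
    label <- f$atoms$label[arow]
    kind <- f$atoms$kind[arow]
    entryTab <- NULL
    if (kind == "abbreviation") {
      inner <- f$inner[[as.character(aid)]]
      if (!is.null(inner) && any(inner$atoms$symbol == "*")) {
        entryTab <- inner  # the drawing's own expansion is ground truth
      } else if (!is.null(inner) && nrow(inner$atoms)) {
        # inner fragment without markers: first atom is the attachment
        inner$atoms$symbol <- as.character(inner$atoms$symbol)
        deg <- sum(tab$bonds$begin == i | tab$bonds$end == i)
        mk <- inner$atoms[rep(1, deg), , drop = FALSE]
        mk$symbol <- "*"
        entryTab <- chemTable(rbind(mk, inner$atoms),
          rbind(data.frame(begin = seq_len(deg), end = deg + 1L,
                           order = 1, display = "plain",
                           coordinative = FALSE, stringsAsFactors = FALSE),
                within(inner$bonds, { begin <- begin + deg
                                      end <- end + deg })))
      } else if (!is.na(label)) {
        entry <- resolveSuperatom(label, libs)
        if (!is.null(entry)) entryTab <- entry$table
      }
    } else if (kind == "r_group" && !is.na(label) &&
               label %in% names(rgroupDefs)) {
      entry <- resolveSuperatom(rgroupDefs[[label]], libs)
      if (!is.null(entry) && entry$nattach == 1L) entryTab <- entry$table
    }
    if (is.null(entryTab)) {
      if (kind == "abbreviation")
        warning("no superatom entry for '", label, "'; node kept as ",
                "wildcard atom")
      # wildcard atom stays; mark handled by clearing its bookkeeping id
      rowIds[i] <- NA_integer_
      next
    }
    n0 <- nrow(tab$atoms)
    tab2 <- expandAbbreviation(tab, i, entryTab, label = label)
    if (nrow(tab2$atoms) == n0 && identical(tab2, tab)) {
      rowIds[i] <- NA_integer_  # degree mismatch: left as wildcard
      next
    }
    nAdded <- nrow(tab2$atoms) - (n0 - 1L)
    rowIds <- c(rowIds[-i], rep(NA_integer_, nAdded))
    tab <- tab2
  }
  bbox <- fragmentBbox(f)
  new("Molecule", atoms = tab$atoms, bonds = tab$bonds,
      canoSmiles = tableCanonicalSmiles(tab, id = f$id),
      mdl = tableToMolfile(tab), label = NA_character_,
      description = NA_character_, bbox = bbox)
}

# R-group definitions harvested from scheme texts ("R = Me").
findRgroupDefs <- function(texts, libs) {
  defs <- character(0)
  for (v in texts$value) {
    m <- regmatches(v, regexec("^\\s*(R\\d*'*|X\\d*)\\s*=\\s*([A-Za-z0-9]+)\\s*$",
                               v))[[1]]
    if (length(m) == 3 && !is.null(resolveSuperatom(m[3], libs)))
      defs[m[2]] <- m[3]
  }
  defs
}
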
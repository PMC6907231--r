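# Chemistry tables: the internal connection-table form shared by fragments
# and Molecules. atoms: symbol, x, y, charge, isotope; bonds: begin, end
# (1-based row indices), order (1/2/3/1.5), display, coordinative.
#
# SMILES parsing/canonicalization and 2-D coordinate generation go through
# OpenBabel (ChemmineOB); Molfile text emitted by OpenBabel is parsed with
# ChemmineR. The V2000 *writer* is implemented here because coordinative
# bonds must be written with the nonstandard bond type 9.

chemTable <- function(atoms, bonds) list(atoms = atoms, bonds = bonds)

emptyChemAtoms <- function()
  data.frame(symbol = character(), x = numeric(), y = numeric(),
             charge = integer(), isotope = integer(), stringsAsFactors = FALSE)

obConvert <- function(from, to, source) {
  out <- tryCatch(ChemmineOB::convertFormat(from, to, source),
                  error = function(e) "")
  if (length(out) != 1 || is.na(out)) "" else out
}

# Canonical SMILES of a SMILES string; NA when OpenBabel cannot parse it.
canonicalizeSmiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    out <- obConvert("SMI", "CAN", s)
    out <- sub("[ \t].*$", "", sub("\n.*$", "", out))
    if (!nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

smilesIsValid <- function(smiles) !is.na(canonicalizeSmiles(smiles))

.chargeFromCode <- function(code) {
  map <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)
  out <- unname(map[as.character(code)])
  out[is.na(out)] <- 0L
  out
}

.codeFromCharge <- function(charge) {
  map <- c(`3` = 1L, `2` = 2L, `1` = 3L, `-1` = 5L, `-2` = 6L, `-3` = 7L)
  out <- unname(map[as.character(charge)])
  out[is.na(out)] <- 0L
  out
}

# Parse an SDF/MOL text block (as produced by OpenBabel) into a chemistry
# table. Drawing convention: y grows downward, so Molfile y is negated.
molBlockToTable <- function(molText) {
  sdf <- as(ChemmineR::read.SDFstr(textConnection(molText)), "SDFset")[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  n <- nrow(ab)
  symbol <- sub("_.*$", "", rownames(ab))
  symbol[symbol %in% c("R", "Du", "R#")] <- "*"
  charge <- if (ncol(ab) >= 5) .chargeFromCode(ab[, 5]) else integer(n)
  atoms <- data.frame(symbol = symbol, x = ab[, 1], y = -ab[, 2],
                      charge = as.integer(charge), isotope = NA_integer_,
                      stringsAsFactors = FALSE, row.names = NULL)
  # M CHG / M ISO property lines override the legacy atom-block columns
  for (ln in grep("^M  (CHG|ISO)", strsplit(molText, "\n")[[1]], value = TRUE)) {
    v <- as.integer(strsplit(trimws(substring(ln, 7)), "\\s+")[[1]])
    k <- v[1]
    idx <- v[seq(2, by = 2, length.out = k)]
    val <- v[seq(3, by = 2, length.out = k)]
    if (grepl("CHG", ln)) atoms$charge[idx] <- val else atoms$isotope[idx] <- val
  }
  if (nrow(bb)) {
    order <- as.numeric(bb[, 3])
    order[order == 4] <- 1.5
    stereo <- if (ncol(bb) >= 4) as.integer(bb[, 4]) else integer(nrow(bb))
    display <- rep("plain", nrow(bb))
    display[stereo == 1] <- "wedge"
    display[stereo == 6] <- "hash"
    bonds <- data.frame(begin = as.integer(bb[, 1]), end = as.integer(bb[, 2]),
                        order = order, display = display,
                        coordinative = FALSE, stringsAsFactors = FALSE,
                        row.names = NULL)
  } else bonds <- emptyBonds()[, c("begin", "end", "order", "display",
                                   "coordinative")]
  chemTable(atoms, bonds)
}

# SMILES -> chemistry table with generated 2-D coordinates.
smilesToTable <- function(smiles) {
  sdf <- obConvert("SMI", "SDF", smiles)
  if (!nzchar(sdf) || !grepl("V2000", sdf))
    stop("cannot parse SMILES: ", smiles)
  molBlockToTable(sdf)
}

fmtCoord <- function(x) formatC(x, format = "f", digits = 4, width = 10)

#' Write a chemistry table as a Molfile (V2000) block
#'
#' Drawing coordinates are rescaled so the median bond length becomes the
#' standard 1.5 units, and the y axis is flipped to the Molfile convention
#' (y up). Coordinative (dative) bonds are written with the nonstandard
#' bond type 9; wedge and hashed-wedge displays map to bond stereo 1 and 6.
#'
#' @param tab chemistry table (`list(atoms, bonds)`) or a [Molecule].
#' @param name molecule name for the header line.
#' @return Molfile V2000 text.
#' @export
tableToMolfile <- function(tab, name = "") {
  if (is(tab, "Molecule")) tab <- chemTable(tab@atoms, tab@bonds)
  atoms <- tab$atoms; bonds <- tab$bonds
  if (nrow(atoms) == 0) stop("empty molecule")
  if (nrow(atoms) > 999)
    stop("more than 999 atoms; V3000 output is not supported")
  scale <- 1
  if (nrow(bonds)) {
    lens <- sqrt((atoms$x[bonds$begin] - atoms$x[bonds$end])^2 +
                 (atoms$y[bonds$begin] - atoms$y[bonds$end])^2)
    med <- stats::median(lens[lens > 0])
    if (is.finite(med) && med > 0) scale <- 1.5 / med
  }
  x <- (atoms$x - mean(atoms$x)) * scale
  y <- -(atoms$y - mean(atoms$y)) * scale
  hdr <- c(name, " SchemeMineR 2D", "",
           sprintf("%3d%3d  0  0  %d  0  0  0  0  0999 V2000",
                   nrow(atoms), nrow(bonds),
                   as.integer(any(bonds$display %in% c("wedge", "hash")))))
  chg <- ifelse(is.na(atoms$charge), 0L, atoms$charge)
  alines <- sprintf("%s%s%s %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
                    fmtCoord(x), fmtCoord(y), fmtCoord(0),
                    atoms$symbol, .codeFromCharge(chg))
  blines <- character(0)
  if (nrow(bonds)) {
    btype <- as.integer(bonds$order)
    btype[bonds$order == 1.5] <- 4L
    btype[bonds$coordinative] <- 9L
    bstereo <- integer(nrow(bonds))
    bstereo[bonds$display == "wedge"] <- 1L
    bstereo[bonds$display == "hash"] <- 6L
    blines <- sprintf("%3d%3d%3d%3d  0  0  0", bonds$begin, bonds$end,
                      btype, bstereo)
  }
  prop <- character(0)
  ci <- which(chg != 0)
  if (length(ci))
    prop <- c(prop, vapply(split(ci, ceiling(seq_along(ci) / 8)), function(ii)
      paste0("M  CHG", sprintf("%3d", length(ii)),
             paste0(sprintf("%4d%4d", ii, chg[ii]), collapse = "")),
      character(1), USE.NAMES = FALSE))
  ii <- which(!is.na(atoms$isotope))
  if (length(ii))
    prop <- c(prop, paste0("M  ISO", sprintf("%3d", length(ii)),
                           paste0(sprintf("%4d%4d", ii, atoms$isotope[ii]),
                                  collapse = "")))
  paste(c(hdr, alines, blines, prop, "M  END", ""), collapse = "\n")
}

# Canonical SMILES of a chemistry table. Coordinative bonds have no SMILES
# representation and are dropped before conversion (components may become
# dot-separated).
tableCanonicalSmiles <- function(tab, id = NULL) {
  bonds <- tab$bonds[!tab$bonds$coordinative, , drop = FALSE]
  mol <- tableToMolfile(chemTable(tab$atoms, bonds))
  out <- obConvert("MOL", "CAN", mol)
  out <- sub("[ \t].*$", "", sub("\n.*$", "", out))
  if (!nzchar(out))
    stop("molecule could not be sanitized",
         if (!is.null(id)) paste0(" (fragment ", id, ")") else "")
  out
}
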
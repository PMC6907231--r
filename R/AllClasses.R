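#' @import methods
NULL

# Periodic table lookup used throughout (index = atomic number).
.ELEMENTS <- c(
  "H","He","Li","Be","B","C","N","O","F","Ne","Na","Mg","Al","Si","P","S",
  "Cl","Ar","K","Ca","Sc","Ti","V","Cr","Mn","Fe","Co","Ni","Cu","Zn","Ga",
  "Ge","As","Se","Br","Kr","Rb","Sr","Y","Zr","Nb","Mo","Tc","Ru","Rh","Pd",
  "Ag","Cd","In","Sn","Sb","Te","I","Xe","Cs","Ba","La","Ce","Pr","Nd","Pm",
  "Sm","Eu","Gd","Tb","Dy","Ho","Er","Tm","Yb","Lu","Hf","Ta","W","Re","Os",
  "Ir","Pt","Au","Hg","Tl","Pb","Bi","Po","At","Rn","Fr","Ra","Ac","Th","Pa",
  "U","Np","Pu","Am","Cm","Bk","Cf","Es","Fm","Md","No","Lr","Rf","Db","Sg",
  "Bh","Hs","Mt","Ds","Rg","Cn","Nh","Fl","Mc","Lv","Ts","Og")

elementNumber <- function(symbol) {
  i <- match(symbol, .ELEMENTS)
  ifelse(is.na(i), 0L, as.integer(i))
}

elementSymbol <- function(number) {
  out <- rep("*", length(number))
  ok <- !is.na(number) & number >= 1 & number <= length(.ELEMENTS)
  out[ok] <- .ELEMENTS[number[ok]]
  out
}

emptyAtoms <- function() {
  data.frame(id = integer(), element = integer(), charge = integer(),
             isotope = integer(), x = numeric(), y = numeric(),
             label = character(), kind = character(),
             stringsAsFactors = FALSE)
}

emptyBonds <- function() {
  data.frame(begin = integer(), end = integer(), order = numeric(),
             display = character(), coordinative = logical(),
             stringsAsFactors = FALSE)
}

emptyTexts <- function() {
  data.frame(id = integer(), value = character(), x = numeric(), y = numeric(),
             xmin = numeric(), ymin = numeric(), xmax = numeric(),
             ymax = numeric(), stringsAsFactors = FALSE)
}

emptyArrows <- function() {
  data.frame(id = integer(), tailx = numeric(), taily = numeric(),
             headx = numeric(), heady = numeric(), style = character(),
             stringsAsFactors = FALSE)
}

#' In-memory model of one ChemDraw drawing
#'
#' A `SchemeGraph` is the lossy-but-faithful representation of one drawing
#' that all readers produce and the whole extraction pipeline consumes:
#' chemical fragments (atoms + bonds with drawing coordinates), free text
#' blocks, and reaction arrows. Coordinates are in drawing points with the
#' y axis growing *downward* (the convention of the source format), so
#' "above the arrow" means smaller y.
#'
#' @slot fragments list of fragment records; each is a `list(id, atoms,
#'   bonds, inner)` where `atoms`/`bonds` are data frames and `inner` holds
#'   chemistry tables of nested (pre-expanded) abbreviation fragments keyed
#'   by atom id.
#' @slot texts data frame of text blocks (`id`, `value`, position and
#'   bounding box).
#' @slot arrows data frame of arrows (`id`, tail/head coordinates, `style`
#'   one of `"plain"`, `"dashed"`, `"crossed"`).
#' @slot source provenance string (file name, plus member path and byte
#'   offset for embedded payloads).
#' @export
setClass("SchemeGraph", representation(
  fragments = "list", texts = "data.frame", arrows = "data.frame",
  source = "character"))

setValidity("SchemeGraph", function(object) {
  ids <- c(unlist(lapply(object@fragments, function(f)
    c(f$id, f$atoms$id))), object@texts$id, object@arrows$id)
  if (anyDuplicated(ids)) return("object ids are not unique across the graph")
  for (f in object@fragments) {
    if (anyDuplicated(f$atoms$id)) return("duplicate atom ids in a fragment")
    bad <- !(f$bonds$begin %in% f$atoms$id) | !(f$bonds$end %in% f$atoms$id)
    if (any(bad)) return("bond endpoint references a missing atom id")
    if (any(f$bonds$begin == f$bonds$end)) return("bond with begin == end")
  }
  if (nrow(object@arrows) &&
      any(object@arrows$tailx == object@arrows$headx &
          object@arrows$taily == object@arrows$heady))
    return("zero-length arrow")
  TRUE
})

SchemeGraph <- function(fragments = list(), texts = emptyTexts(),
                        arrows = emptyArrows(), source = "<memory>") {
  new("SchemeGraph", fragments = fragments, texts = texts, arrows = arrows,
      source = source)
}

#' @export
setMethod("show", "SchemeGraph", function(object) {
  natoms <- sum(vapply(object@fragments, function(f) nrow(f$atoms), 0L))
  cat("SchemeGraph:", length(object@fragments), "fragment(s) (", natoms,
      "atoms ),", nrow(object@texts), "text(s),", nrow(object@arrows),
      "arrow(s)\n  source:", object@source, "\n")
})

#' One extracted structure in chemistry-table form
#'
#' Holds the connection table of a single structure together with its two
#' renderings — canonical SMILES and a Molfile (V2000) — plus the compound
#' label and free-text description picked up near the drawing, and the
#' bounding box in drawing coordinates used for reaction-role assignment.
#'
#' @slot atoms data frame: `symbol`, `x`, `y`, `charge`, `isotope`.
#' @slot bonds data frame: `begin`, `end` (1-based atom row indices),
#'   `order` (1, 2, 3 or 1.5 for aromatic), `display`, `coordinative`.
#' @slot canoSmiles canonical SMILES string.
#' @slot mdl Molfile V2000 string (coordinative bonds as bond type 9).
#' @slot label compound label (e.g. "13a") or `NA`.
#' @slot description attached free text or `NA`.
#' @slot bbox numeric `c(xmin, ymin, xmax, ymax)` in drawing points.
#' @export
setClass("Molecule", representation(
  atoms = "data.frame", bonds = "data.frame", canoSmiles = "character",
  mdl = "character", label = "character", description = "character",
  bbox = "numeric"))

setValidity("Molecule", function(object) {
  n <- nrow(object@atoms)
  if (nrow(object@bonds) &&
      (any(object@bonds$begin < 1 | object@bonds$begin > n) ||
       any(object@bonds$end < 1 | object@bonds$end > n)))
    return("bond references atom outside the table")
  TRUE
})

#' @export
setMethod("show", "Molecule", function(object) {
  cat("Molecule:", nrow(object@atoms), "atoms,", nrow(object@bonds),
      "bonds\n  SMILES:", object@canoSmiles, "\n")
  if (!is.na(object@label)) cat("  label:", object@label, "\n")
})

#' @export
setGeneric("canoSmiles", function(x) standardGeneric("canoSmiles"))
#' @describeIn Molecule canonical SMILES accessor.
#' @param x a `Molecule`.
#' @export
setMethod("canoSmiles", "Molecule", function(x) x@canoSmiles)

#' @export
setGeneric("mdl", function(x) standardGeneric("mdl"))
#' @describeIn Molecule Molfile (V2000) accessor.
#' @export
setMethod("mdl", "Molecule", function(x) x@mdl)

#' @export
setGeneric("moleculeLabel", function(x) standardGeneric("moleculeLabel"))
#' @describeIn Molecule compound-label accessor.
#' @export
setMethod("moleculeLabel", "Molecule", function(x) x@label)

#' One single-step reaction
#'
#' A reaction always carries three molecule groups — reactants (left of the
#' arrow), reagents (structures drawn in the band around the arrow) and
#' products (right of the arrow) — plus compounds identified from band
#' *text* (split into reagent and solvent SMILES), the parsed conditions
#' (time, temperature, yield), and a status flag derived from the arrow
#' style (plain = success, dashed = planned, crossed = failed).
#'
#' @slot reactants,reagents,products lists of [Molecule] objects.
#' @slot reagentsSmiles,solventsSmiles canonical SMILES identified from
#'   band text.
#' @slot time,temperature named lists `list(value, unit, token)`; `value`
#'   is `NA` when only a qualitative token (e.g. "rt", "reflux",
#'   "overnight") was found.
#' @slot yield percent in `[0, 100]` or `NA`.
#' @slot status one of `"success"`, `"failed"`, `"planned"`,
#'   `"unspecified"`.
#' @slot description residual band text not consumed by interpretation.
#' @slot stepIndex 1-based position within its multistep chain.
#' @slot incomplete `TRUE` when a side is empty (flagged, never dropped).
#' @export
setClass("ReactionStep", representation(
  reactants = "list", reagents = "list", products = "list",
  reagentsSmiles = "character", solventsSmiles = "character",
  time = "list", temperature = "list", yield = "numeric",
  status = "character", description = "character", stepIndex = "integer",
  incomplete = "logical"))

setValidity("ReactionStep", function(object) {
  if (!object@status %in% c("success", "failed", "planned", "unspecified"))
    return("unknown status")
  if (!is.na(object@yield) && (object@yield < 0 || object@yield > 100))
    return("yield outside [0, 100]")
  TRUE
})

ReactionStep <- function(reactants = list(), reagents = list(),
                         products = list(), reagentsSmiles = character(),
                         solventsSmiles = character(),
                         time = list(value = NA_real_, unit = NA_character_,
                                     token = NA_character_),
                         temperature = list(value = NA_real_,
                                            unit = NA_character_,
                                            token = NA_character_),
                         yield = NA_real_, status = "unspecified",
                         description = NA_character_, stepIndex = 1L,
                         incomplete = FALSE) {
  new("ReactionStep", reactants = reactants, reagents = reagents,
      products = products, reagentsSmiles = reagentsSmiles,
      solventsSmiles = solventsSmiles, time = time, temperature = temperature,
      yield = yield, status = status, description = description,
      stepIndex = as.integer(stepIndex), incomplete = incomplete)
}

#' @export
setMethod("show", "ReactionStep", function(object) {
  cat(sprintf("ReactionStep %d [%s]%s\n", object@stepIndex, object@status,
              if (object@incomplete) " (incomplete)" else ""))
  cat("  ", reactionSmiles(object, strict = FALSE), "\n", sep = "")
  if (!is.na(object@yield)) cat("  yield:", object@yield, "%\n")
})

#' @export
setGeneric("reactants", function(x) standardGeneric("reactants"))
#' @describeIn ReactionStep reactant molecules.
#' @param x a `ReactionStep`.
#' @export
setMethod("reactants", "ReactionStep", function(x) x@reactants)

#' @export
setGeneric("reagents", function(x) standardGeneric("reagents"))
#' @describeIn ReactionStep reagent molecules drawn in the band.
#' @export
setMethod("reagents", "ReactionStep", function(x) x@reagents)

#' @export
setGeneric("products", function(x) standardGeneric("products"))
#' @describeIn ReactionStep product molecules.
#' @export
setMethod("products", "ReactionStep", function(x) x@products)

#' @export
setGeneric("stepStatus", function(x) standardGeneric("stepStatus"))
#' @describeIn ReactionStep status flag accessor.
#' @export
setMethod("stepStatus", "ReactionStep", function(x) x@status)

#' Superatom, name, solvent and reagent dictionaries
#'
#' Bundles the four lookup tables used during extraction: superatom label
#' expansions, name-to-SMILES entries (with source priority internal >
#' corpus > editor), the solvent set (canonical SMILES) and the reagent
#' list. Seed subsets ship with the package; [loadLibraries()] accepts
#' full-size files in the same format.
#'
#' @slot superatoms data frame: `key`, `smiles` (expansion with `[*]`
#'   attachment markers), `nattach`.
#' @slot names data frame: `key`, `smiles`, `canonical`, `source`.
#' @slot solvents data frame: `name`, `smiles`, `canonical`.
#' @slot reagents data frame: `name`, `smiles`, `canonical`.
#' @slot patterns condition-grammar configuration (see
#'   [parseConditions()]).
#' @slot cache environment memoizing parsed expansion tables.
#' @export
setClass("ChemLibraries", representation(
  superatoms = "data.frame", names = "data.frame", solvents = "data.frame",
  reagents = "data.frame", patterns = "list", cache = "environment"))

#' @export
setMethod("show", "ChemLibraries", function(object) {
  cat("ChemLibraries:", nrow(object@superatoms), "superatoms,",
      nrow(object@names), "names,", nrow(object@solvents), "solvents,",
      nrow(object@reagents), "reagents\n")
})
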
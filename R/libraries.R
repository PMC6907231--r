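# Superatom / name / solvent / reagent dictionaries. File format: UTF-8
# TSV, `key<TAB>smiles[<TAB>source]`, `#` comments. Seed subsets ship in
# inst/extdata; full-size files in the same format load identically.

readLibraryTsv <- function(path, ncolMax = 3) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  do.call(rbind, lapply(parts, function(p) {
    p <- trimws(p)
    length(p) <- ncolMax
    as.data.frame(as.list(p), stringsAsFactors = FALSE,
                  col.names = paste0("V", seq_len(ncolMax)))
  }))
}

.seedPath <- function(file)
  system.file("extdata", file, package = "SchemeMineR", mustWork = TRUE)

#' Load the extraction dictionaries
#'
#' Reads the superatom, name-to-SMILES, solvent and reagent dictionaries
#' (tab-separated `key<TAB>smiles[<TAB>source]` files) plus the
#' condition-grammar pattern table. Entries whose SMILES does not parse
#' are dropped with a warning; the shipped seed libraries load with zero
#' warnings.
#'
#' @param superatoms,names,solvents,reagents file paths; defaults are the
#'   seed files shipped with the package.
#' @param patterns path to the condition-grammar YAML configuration.
#' @return a [ChemLibraries].
#' @export
loadLibraries <- function(superatoms = .seedPath("superatoms.tsv"),
                          names = .seedPath("names.tsv"),
                          solvents = .seedPath("solvents.tsv"),
                          reagents = .seedPath("reagents.tsv"),
                          patterns = .seedPath("conditions.yaml")) {
  for (p in c(superatoms, names, solvents, reagents, patterns))
    if (!file.exists(p)) stop("library file not found: ", p)
  dropBad <- function(df, what) {
    if (is.null(df) || nrow(df) == 0)
      return(data.frame(V1 = character(), V2 = character(),
                        V3 = character(), canonical = character(),
                        stringsAsFactors = FALSE))
    df$canonical <- canonicalizeSmiles(df$V2)
    bad <- is.na(df$canonical)
    if (any(bad))
      warning(sum(bad), " ", what, " entr", if (sum(bad) == 1) "y" else "ies",
              " with unparsable SMILES dropped: ",
              paste(df$V1[bad], collapse = ", "))
    df[!bad, , drop = FALSE]
  }
  sa <- dropBad(readLibraryTsv(superatoms), "superatom")
  saDf <- data.frame(key = sa$V1, smiles = sa$V2,
                     nattach = vapply(sa$V2, function(s)
                       sum(gregexpr("\\[\\*\\]", s)[[1]] > 0), 0L,
                       USE.NAMES = FALSE),
                     stringsAsFactors = FALSE)
  if (anyDuplicated(saDf$key)) stop("duplicate superatom keys")
  nm <- dropBad(readLibraryTsv(names), "name")
  nmDf <- data.frame(key = gsub("\\s+", " ", trimws(nm$V1)), smiles = nm$V2,
                     canonical = nm$canonical,
                     source = ifelse(is.na(nm$V3), "internal", nm$V3),
                     stringsAsFactors = FALSE)
  if (!all(nmDf$source %in% c("internal", "corpus", "editor")))
    stop("name entry source must be internal, corpus or editor")
  if (anyDuplicated(nmDf[c("key", "source")]))
    stop("duplicate name keys within one source tier")
  sv <- dropBad(readLibraryTsv(solvents), "solvent")
  svDf <- data.frame(name = sv$V1, smiles = sv$V2, canonical = sv$canonical,
                     stringsAsFactors = FALSE)
  rg <- dropBad(readLibraryTsv(reagents), "reagent")
  rgDf <- data.frame(name = rg$V1, smiles = rg$V2, canonical = rg$canonical,
                     stringsAsFactors = FALSE)
  pat <- yaml::read_yaml(patterns)
  new("ChemLibraries", superatoms = saDf, names = nmDf, solvents = svDf,
      reagents = rgDf, patterns = pat, cache = new.env(parent = emptyenv()))
}

#' Look up a superatom label
#'
#' Exact-match lookup first; on a miss the label is retried with leading
#' and trailing hyphens stripped, then case-insensitively. Returns the
#' entry with its expansion parsed to a chemistry table (memoized), or
#' `NULL`.
#'
#' @param label node label, e.g. `"OMe"`, `"Boc"`.
#' @param libs a [ChemLibraries].
#' @return `list(key, smiles, nattach, table)` or `NULL`.
#' @export
resolveSuperatom <- function(label, libs) {
  if (is.na(label) || !nzchar(label)) return(NULL)
  sa <- libs@superatoms
  i <- match(label, sa$key)
  if (is.na(i)) i <- match(gsub("^-+|-+$", "", label), sa$key)
  if (is.na(i)) i <- match(tolower(gsub("^-+|-+$", "", label)),
                           tolower(sa$key))
  if (is.na(i)) return(NULL)
  key <- sa$key[i]
  cacheKey <- paste0("sa:", key)
  tab <- libs@cache[[cacheKey]]
  if (is.null(tab)) {
    tab <- smilesToTable(sa$smiles[i])
    assign(cacheKey, tab, envir = libs@cache)
  }
  list(key = key, smiles = sa$smiles[i], nattach = sa$nattach[i], table = tab)
}

#' Resolve a compound name or abbreviation to canonical SMILES
#'
#' Lookup order follows the source priority internal > corpus > editor
#' (the curated entries take priority over editor-derived ones); within
#' each pass exact-case match is tried before the case-insensitive
#' fallback, and finally keys with `.` and `,` stripped. Returns `NULL`
#' on a miss.
#'
#' @param text name text, e.g. `"DMF"`, `"NEt3"`.
#' @param libs a [ChemLibraries].
#' @return canonical SMILES string or `NULL`.
#' @export
resolveName <- function(text, libs) {
  key <- gsub("\\s+", " ", trimws(text))
  if (!nzchar(key)) return(NULL)
  nm <- libs@names
  nm <- nm[order(match(nm$source, c("internal", "corpus", "editor"))), ,
           drop = FALSE]
  i <- match(key, nm$key)
  if (is.na(i)) i <- match(tolower(key), tolower(nm$key))
  if (is.na(i)) {
    stripped <- gsub("[.,]", "", key)
    i <- match(tolower(stripped), tolower(gsub("[.,]", "", nm$key)))
  }
  if (is.na(i)) return(NULL)
  nm$canonical[i]
}

#' Classify a compound as solvent or reagent
#'
#' A compound is a solvent iff its canonical SMILES is in the solvent
#' dictionary; every other band compound is a reagent.
#'
#' @param smiles SMILES string (must parse).
#' @param libs a [ChemLibraries].
#' @return `"solvent"` or `"reagent"`.
#' @export
classifySmilesRole <- function(smiles, libs) {
  can <- canonicalizeSmiles(smiles)
  if (is.na(can)) stop("unparsable SMILES: ", smiles)
  if (can %in% libs@solvents$canonical) "solvent" else "reagent"
}
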
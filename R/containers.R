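# Locating CDX/CDXML payloads inside document containers: DOCX (zip/OPC),
# DOC (OLE compound file) and ELN-export XML, plus the scheme-vs-table
# reconciliation for ELN exports.

embeddedPayload <- function(data, dialect, origin)
  list(data = data, dialect = dialect, origin = origin)

.looksLikeCdxml <- function(bytes) {
  head <- rawToChar(bytes[seq_len(min(length(bytes), 2000L))])
  grepl("<CDXML", head, fixed = TRUE)
}

.startsWithCdxMagic <- function(bytes)
  length(bytes) >= 8 && rawToChar(bytes[1:8]) == CDX_MAGIC

#' Find CDX signatures in a byte stream
#'
#' Returns the 0-based offsets of every occurrence of the 8-byte CDX
#' magic, ascending; the robust fallback for mildly corrupt containers.
#'
#' @param data raw vector.
#' @return numeric vector of 0-based byte offsets.
#' @export
scanForCdxSignatures <- function(data) {
  if (length(data) < 8) return(numeric(0))
  magic <- charToRaw(CDX_MAGIC)
  hits <- which(data == magic[1])
  hits <- hits[hits + 7 <= length(data)]
  keep <- vapply(hits, function(i) identical(data[i:(i + 7)], magic), TRUE)
  sort(hits[keep] - 1)
}

.payloadsFromCfb <- function(bytes, origin) {
  parsed <- tryCatch(cfbRead(bytes), error = function(e) NULL)
  out <- list()
  if (is.null(parsed)) return(out)
  for (path in names(parsed$streams)) {
    s <- parsed$streams[[path]]
    if (.startsWithCdxMagic(s)) {
      out[[length(out) + 1L]] <-
        embeddedPayload(s, "cdx", paste0(origin, "!", path, "@0"))
    } else {
      offs <- scanForCdxSignatures(s)
      if (length(offs))
        out[[length(out) + 1L]] <- embeddedPayload(
          s[(offs[1] + 1):length(s)], "cdx",
          paste0(origin, "!", path, "@", offs[1], " (signature-scan)"))
    }
  }
  out
}

#' Extract embedded ChemDraw payloads from a DOCX archive
#'
#' Opens every member of the zip archive: raw CDX members and CDXML
#' members are returned directly; OLE-wrapped embedded objects are
#' descended into and their ChemDraw stream returned. Members with no
#' CDX payload are skipped. Extraction order is document (archive) order,
#' ties by stream path.
#'
#' @param data raw vector of the DOCX file.
#' @param origin container path recorded in payload provenance.
#' @return list of payloads `list(data, dialect, origin)`.
#' @export
extractFromDocx <- function(data, origin = "<docx>") {
  if (!isZip(data)) stop("not DOCX")
  members <- zipRead(data)
  out <- list()
  for (nm in names(members)) {
    bytes <- members[[nm]]
    memberOrigin <- paste0(origin, "!", nm)
    if (.startsWithCdxMagic(bytes)) {
      out[[length(out) + 1L]] <-
        embeddedPayload(bytes, "cdx", paste0(memberOrigin, "@0"))
    } else if (isCfb(bytes)) {
      out <- c(out, .payloadsFromCfb(bytes, memberOrigin))
    } else if (grepl("\\.(xml|cdxml)$", nm) && .looksLikeCdxml(bytes)) {
      out[[length(out) + 1L]] <-
        embeddedPayload(rawToChar(bytes), "cdxml", paste0(memberOrigin, "@0"))
    }
  }
  out
}

#' Extract embedded ChemDraw payloads from a DOC compound file
#'
#' Walks the OLE storage tree (the object pool of a Word binary file) and
#' returns each embedded object's ChemDraw stream; when storage walking
#' finds nothing (real DOC files are frequently mildly corrupt) a
#' whole-file signature scan recovers raw CDX payloads, marked
#' `signature-scan` in their origin.
#'
#' @param data raw vector of the DOC file.
#' @param origin container path recorded in payload provenance.
#' @return list of payloads `list(data, dialect, origin)`.
#' @export
extractFromDoc <- function(data, origin = "<doc>") {
  if (!isCfb(data)) stop("not DOC")
  out <- .payloadsFromCfb(data, origin)
  if (length(out) == 0) {
    for (off in scanForCdxSignatures(data))
      out[[length(out) + 1L]] <- embeddedPayload(
        data[(off + 1):length(data)], "cdx",
        paste0(origin, "@", off, " (signature-scan)"))
  }
  out
}

.defaultElnMapping <- function()
  yaml::read_yaml(.seedPath("eln-mapping.yaml"))

#' Extract CDXML payloads and reaction-table records from ELN-export XML
#'
#' CDXML sub-documents embedded in the export are separated out as
#' payloads; reaction-table rows are mapped to records with a closed role
#' set (`reactant`, `reagent`, `solvent`, `product`). The element-path to
#' record-field mapping is configuration-driven; the shipped default
#' covers the synthetic fixture dialect.
#'
#' @param text XML text.
#' @param mapping mapping configuration (see
#'   `inst/extdata/eln-mapping.yaml`).
#' @param origin provenance string.
#' @return `list(payloads, records)`; `records` is a data frame with
#'   `role`, `identifier`, `amounts`, `conditions`, `observations`.
#' @export
extractFromElnXml <- function(text, mapping = .defaultElnMapping(),
                              origin = "<eln>") {
  doc <- xml2::read_xml(text)
  payloads <- list()
  # islands are cut from the original text (not re-serialized through the
  # XML tree) so payload bytes survive extraction unchanged
  el <- if (!is.null(mapping$payload_element)) mapping$payload_element
        else "CDXML"
  text1 <- paste(text, collapse = "\n")
  pat <- sprintf("(?s)<%s[ >].*?</%s>", el, el)
  islands <- regmatches(text1, gregexpr(pat, text1, perl = TRUE))[[1]]
  for (k in seq_along(islands))
    payloads[[k]] <- embeddedPayload(islands[[k]], "cdxml",
                                     paste0(origin, "!cdxml[", k, "]"))
  records <- data.frame(role = character(), identifier = character(),
                        amounts = character(), conditions = character(),
                        observations = character(), stringsAsFactors = FALSE)
  rows <- xml2::xml_find_all(doc, mapping$table_row_xpath)
  for (r in rows) {
    getF <- function(field) {
      v <- xml2::xml_attr(r, mapping$fields[[field]])
      if (is.na(v)) "" else v
    }
    rawRole <- getF("role")
    role <- mapping$role_map[[rawRole]]
    if (is.null(role)) {
      warning("unknown reaction-table role '", rawRole, "'; row skipped")
      next
    }
    records <- rbind(records, data.frame(
      role = role, identifier = getF("identifier"),
      amounts = getF("amounts"), conditions = getF("conditions"),
      observations = getF("observations"), stringsAsFactors = FALSE))
  }
  list(payloads = payloads, records = records)
}

.stepSmilesSet <- function(step)
  unique(c(vapply(step@reactants, canoSmiles, ""),
           vapply(step@reagents, canoSmiles, ""),
           vapply(step@products, canoSmiles, ""),
           step@reagentsSmiles, step@solventsSmiles))

#' Reconcile extracted steps against an ELN reaction table
#'
#' Compares the compounds of the drawn scheme with the reaction-table
#' records as canonical-SMILES sets: table compounds missing from the
#' scheme extraction are reported as `missing-in-scheme`, scheme
#' compounds absent from the table as `missing-in-table`, and
#' identifiers that resolve to no structure as `unresolved` (reported,
#' never fatal).
#'
#' @param steps list of [ReactionStep] from scheme extraction.
#' @param records record data frame from [extractFromElnXml()].
#' @param libs a [ChemLibraries].
#' @return data frame of discrepancies: `type`, `identifier`, `smiles`,
#'   `step`.
#' @export
reconcile <- function(steps, records, libs) {
  disc <- data.frame(type = character(), identifier = character(),
                     smiles = character(), step = integer(),
                     stringsAsFactors = FALSE)
  add <- function(type, identifier, smiles, step)
    disc <<- rbind(disc, data.frame(type = type, identifier = identifier,
                                    smiles = smiles, step = step,
                                    stringsAsFactors = FALSE))
  tableSmiles <- character(0)
  for (i in seq_len(nrow(records))) {
    ident <- records$identifier[i]
    sm <- resolveName(ident, libs)
    if (is.null(sm)) sm <- canonicalizeSmiles(ident)
    if (is.null(sm) || is.na(sm)) {
      add("unresolved", ident, NA_character_, NA_integer_)
    } else tableSmiles <- union(tableSmiles, sm)
  }
  schemeSmiles <- unique(unlist(lapply(steps, .stepSmilesSet)))
  stepNo <- if (length(steps) == 1) 1L else NA_integer_
  for (sm in setdiff(tableSmiles, schemeSmiles))
    add("missing-in-scheme", NA_character_, sm, stepNo)
  for (sm in setdiff(schemeSmiles, tableSmiles))
    add("missing-in-table", NA_character_, sm, stepNo)
  disc
}
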
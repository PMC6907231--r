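# Document-level pipeline: sniff the input kind, locate drawings
# (directly or inside containers), and run scheme extraction on each.

#' Detect a file's container kind from its leading bytes
#'
#' @param data raw vector (or character text).
#' @return one of `"cdx"`, `"cdxml"`, `"docx"`, `"doc"`, `"eln_xml"`,
#'   `"unknown"`.
#' @export
sniffFormat <- function(data) {
  if (is.character(data)) {
    txt <- paste(data, collapse = "\n")
    if (grepl("^\\s*(<\\?xml[^>]*\\?>\\s*)?<CDXML", txt)) return("cdxml")
    if (grepl("^\\s*(<\\?xml[^>]*\\?>)?\\s*<", txt)) return("eln_xml")
    return("unknown")
  }
  if (.startsWithCdxMagic(data)) return("cdx")
  if (isZip(data)) return("docx")
  if (isCfb(data)) return("doc")
  head <- rawToChar(data[seq_len(min(length(data), 400L))])
  if (grepl("<CDXML", head, fixed = TRUE)) return("cdxml")
  if (grepl("^\\s*(<\\?xml[^>]*\\?>)?\\s*<", head)) return("eln_xml")
  "unknown"
}

#' Extract molecules and reactions from a file or byte stream
#'
#' Accepts CDX, CDXML, DOCX, DOC and ELN-export XML inputs. Container
#' formats are descended into; every located drawing is parsed into a
#' [SchemeGraph] and run through [scanScheme()]. For ELN exports the
#' reaction table is reconciled against the extraction.
#'
#' @param input file path, raw vector, or XML/CDXML text.
#' @param libs a [ChemLibraries].
#' @param config see [defaultScanConfig()].
#' @return `list(schemes = <list of per-drawing scan results>,
#'   discrepancies = <reconciliation data frame or NULL>, source)`. Each
#'   scheme result carries the payload provenance in
#'   `result$graph@source`.
#' @export
scanDocument <- function(input, libs = loadLibraries(),
                         config = defaultScanConfig()) {
  source <- "<memory>"
  if (is.character(input) && length(input) == 1 && !grepl("<", input) &&
      file.exists(input)) {
    source <- input
    input <- readBin(input, "raw", n = file.size(input))
  }
  kind <- sniffFormat(input)
  asText <- function(x) if (is.raw(x)) rawToChar(x) else
    paste(x, collapse = "\n")
  payloads <- list(); records <- NULL
  if (kind == "cdx") {
    payloads <- list(embeddedPayload(input, "cdx", paste0(source, "@0")))
  } else if (kind == "cdxml") {
    payloads <- list(embeddedPayload(asText(input), "cdxml",
                                     paste0(source, "@0")))
  } else if (kind == "docx") {
    payloads <- extractFromDocx(input, origin = source)
  } else if (kind == "doc") {
    payloads <- extractFromDoc(input, origin = source)
  } else if (kind == "eln_xml") {
    eln <- extractFromElnXml(asText(input), origin = source)
    payloads <- eln$payloads
    records <- eln$records
  } else stop("unsupported input format")
  schemes <- lapply(payloads, function(p) {
    graph <- if (p$dialect == "cdx") parseCdx(p$data, source = p$origin)
             else parseCdxml(p$data, source = p$origin)
    scanScheme(graph, libs, config)
  })
  disc <- NULL
  if (!is.null(records)) {
    steps <- unlist(lapply(schemes, `[[`, "steps"), recursive = FALSE)
    disc <- reconcile(steps, records, libs)
  }
  list(schemes = schemes, discrepancies = disc, source = source)
}
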
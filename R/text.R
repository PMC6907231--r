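# Text interpretation: condition grammar (time / temperature / yield),
# compound identification via the name library, compound labels. The
# grammar (units, qualitative tokens) is data-driven from the shipped
# conditions.yaml so it can be extended without code changes.

.NUM_RE <- "[+-]?\\d+(?:\\.\\d+)?"

emptyConditionSet <- function()
  list(time = list(value = NA_real_, unit = NA_character_,
                   token = NA_character_),
       temperature = list(value = NA_real_, unit = NA_character_,
                          token = NA_character_),
       yield = NA_real_, residue = character(0))

# Split a condition string into tokens; commas act as separators except
# between digits, where the decimal comma is normalized to a point first.
.condTokens <- function(text) {
  text <- gsub("(\\d),(\\d)", "\\1.\\2", text)
  toks <- strsplit(text, "[;,]")[[1]]
  toks <- trimws(toks)
  toks[nzchar(toks)]
}

#' Parse reaction conditions from scheme text
#'
#' Scans comma/semicolon-separated tokens with the shipped pattern table:
#' number + unit for time (`h`, `min`, `d`, ...), number + `°C`/`K` for
#' temperature, qualitative tokens (`rt`, `reflux`, `overnight`) and a
#' `number %` yield (optionally prefixed `yield:`). Decimal commas are
#' accepted. Unmatched tokens are returned as `residue`; the function
#' always returns, possibly empty.
#'
#' @param text condition string, e.g. `"THF, 80 °C, 12 h"`.
#' @param patterns pattern table (default: the table in the seed
#'   libraries); a [ChemLibraries] may be passed.
#' @return a condition set: `list(time, temperature, yield, residue)`.
#' @export
parseConditions <- function(text, patterns = NULL) {
  if (is(patterns, "ChemLibraries")) patterns <- patterns@patterns
  if (is.null(patterns))
    patterns <- yaml::read_yaml(.seedPath("conditions.yaml"))
  out <- emptyConditionSet()
  if (is.na(text) || !nzchar(trimws(text))) return(out)
  for (tok in .condTokens(text)) {
    parsed <- .parseConditionToken(tok, patterns)
    if (is.null(parsed)) { out$residue <- c(out$residue, tok); next }
    slotName <- parsed$what
    if (slotName == "yield") {
      if (is.na(out$yield)) out$yield <- parsed$value
      else out$residue <- c(out$residue, tok)
    } else {
      cur <- out[[slotName]]
      if (is.na(cur$value) && is.na(cur$token)) out[[slotName]] <- parsed$field
      else out$residue <- c(out$residue, tok)
    }
  }
  out
}

.parseConditionToken <- function(tok, patterns) {
  yw <- paste(patterns$yield_words, collapse = "|")
  m <- regmatches(tok, regexec(
    paste0("^(?:(?:", yw, ")\\s*:?\\s*)?(", .NUM_RE, ")\\s*%$"), tok,
    ignore.case = TRUE))[[1]]
  if (length(m)) {
    v <- as.numeric(m[2])
    if (v >= 0 && v <= 100)
      return(list(what = "yield", value = v))
  }
  m <- regmatches(tok, regexec(
    paste0("^(", .NUM_RE, ")\\s*(°\\s*C|ºC|oC|C|K)$"), tok))[[1]]
  if (length(m)) {
    unit <- patterns$temp_units[[gsub("\\s", "", m[3])]]
    if (!is.null(unit))
      return(list(what = "temperature",
                  field = list(value = as.numeric(m[2]), unit = unit,
                               token = NA_character_)))
  }
  m <- regmatches(tok, regexec(
    paste0("^(", .NUM_RE, ")\\s*([A-Za-z]+)\\.?$"), tok))[[1]]
  if (length(m)) {
    unit <- patterns$time_units[[tolower(m[3])]]
    if (!is.null(unit))
      return(list(what = "time",
                  field = list(value = as.numeric(m[2]), unit = unit,
                               token = NA_character_)))
  }
  low <- tolower(tok)
  if (low %in% tolower(unlist(patterns$temp_tokens)))
    return(list(what = "temperature",
                field = list(value = NA_real_, unit = NA_character_,
                             token = low)))
  if (low %in% tolower(unlist(patterns$time_tokens)))
    return(list(what = "time",
                field = list(value = NA_real_, unit = NA_character_,
                             token = low)))
  NULL
}

.smilesTokenRe <- "^[A-Za-z0-9@+\\-\\[\\]()=#$%/\\\\.*]+$"

.tokenToSmiles <- function(tok, libs) {
  hit <- resolveName(tok, libs)
  if (!is.null(hit)) return(hit)
  # unambiguous line notation written directly into the scheme
  if (grepl(.smilesTokenRe, tok, perl = TRUE) && grepl("[A-Za-z]", tok) &&
      !grepl("^\\d+$", tok)) {
    can <- canonicalizeSmiles(tok)
    if (!is.na(can)) return(can)
  }
  NULL
}

#' Classify one scheme text block
#'
#' Attempts, in order: resolving the whole string as a compound name;
#' splitting on separators and resolving each piece as a compound name,
#' direct SMILES, or condition token; the compound-label pattern
#' (`"13a"`-style, geometry checked by the caller); otherwise the text is
#' `unknown` with the raw string preserved. No token is lost: compounds,
#' conditions and residue jointly account for the input.
#'
#' @param value text string.
#' @param libs a [ChemLibraries].
#' @return `list(kind, smiles, conditions, residue, raw)` where `kind` is
#'   one of `"compound"`, `"condition"`, `"label"`, `"unknown"`.
#' @export
classifyTextBlock <- function(value, libs) {
  raw <- value
  out <- list(kind = "unknown", smiles = character(0),
              conditions = emptyConditionSet(), residue = character(0),
              raw = raw)
  whole <- resolveName(value, libs)
  if (!is.null(whole)) {
    out$kind <- "compound"; out$smiles <- whole
    return(out)
  }
  toks <- .condTokens(value)
  if (length(toks) == 0) return(out)
  condSet <- emptyConditionSet()
  anyCond <- FALSE
  for (tok in toks) {
    cm <- resolveName(tok, libs)
    if (is.null(cm)) {
      parsed <- .parseConditionToken(tok, libs@patterns)
      if (!is.null(parsed)) {
        anyCond <- TRUE
        if (parsed$what == "yield") {
          if (is.na(condSet$yield)) condSet$yield <- parsed$value
          else condSet$residue <- c(condSet$residue, tok)
        } else {
          cur <- condSet[[parsed$what]]
          if (is.na(cur$value) && is.na(cur$token))
            condSet[[parsed$what]] <- parsed$field
          else condSet$residue <- c(condSet$residue, tok)
        }
        next
      }
      cm <- .tokenToSmiles(tok, libs)
    }
    if (!is.null(cm)) out$smiles <- c(out$smiles, cm)
    else condSet$residue <- c(condSet$residue, tok)
  }
  out$conditions <- condSet
  out$residue <- condSet$residue
  out$kind <- if (anyCond) "condition"
    else if (length(out$smiles)) "compound"
    else if (grepl("^\\d+[a-z]?$", trimws(value))) "label"
    else "unknown"
  out
}

.isLabelText <- function(value) grepl("^\\d+[a-z]?$", trimws(value))
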
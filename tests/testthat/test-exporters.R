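mkStep <- function(left, agents, right) {
  mol <- function(sm) {
    g <- drawnGraph(sm)
    buildMolecule(g@fragments[[1]], testLibs)
  }
  ReactionStep <- SchemeMineR:::ReactionStep
  ReactionStep(reactants = lapply(left, mol), products = lapply(right, mol),
               reagentsSmiles = agents, status = "success")
}

test_that("reaction SMILES follows the reactants>agents>products grammar", {
  expect_equal(reactionSmiles(mkStep("CCO", character(0), "CC=O")),
               "CCO>>CC=O")
  expect_equal(reactionSmiles(mkStep("CCO", "O", "CC=O")), "CCO>O>CC=O")
  can <- SchemeMineR:::canonicalizeSmiles
  two <- reactionSmiles(mkStep(c("CCO", "CC(=O)O"), character(0),
                               "CCOC(C)=O"))
  # left side dot-joined in drawing order
  expect_equal(two, paste0(can("CCO"), ".", can("CC(=O)O"), ">>",
                           can("CCOC(C)=O")))
  expect_error(reactionSmiles(SchemeMineR:::ReactionStep()), "empty")
  # components individually re-parsable and canonical
  for (part in strsplit(strsplit(two, ">")[[1]], "\\.")) for (sm in part)
    if (nzchar(sm))
      expect_equal(SchemeMineR:::canonicalizeSmiles(sm), sm)
})

test_that("CML re-parses through an independent reader to the same set", {
  fx <- generateScheme(randomSpec(9), testLibs)
  res <- suppressWarnings(scanScheme(parseCdxml(fx$cdxml), testLibs))
  cml <- writeCml(res$steps)
  expect_silent(xml2::read_xml(cml))
  got <- sort(unique(obabelCan(cml, "cml")))
  want <- sort(unique(unlist(lapply(res$steps, function(s)
    vapply(c(s@reactants, s@reagents, s@products), canoSmiles, "")))))
  expect_equal(got, want)
  # empty export is still a valid document; yields become scalars
  expect_silent(xml2::read_xml(writeCml(list())))
  st <- mkStep("CCO", character(0), "CC=O")
  st@yield <- 95
  expect_match(writeCml(list(st)), '<scalar dictRef="sm:yield"[^>]*>95')
})

test_that("CDXML export re-extracts to identical steps", {
  for (seed in c(7, 8, 16)) {
    fx <- generateScheme(randomSpec(seed), testLibs)
    res <- suppressWarnings(scanScheme(parseCdxml(fx$cdxml), testLibs))
    back <- suppressWarnings(scanScheme(parseCdxml(writeCdxml(res$steps)),
                                        testLibs))
    expect_identical(sigSteps(res$steps), sigSteps(back$steps))
  }
  # crossed status serializes to a crossed arrow
  st <- mkStep("CCO", character(0), "CC=O")
  st@status <- "failed"
  expect_match(writeCdxml(list(st)), 'NoGo="Cross"')
  # molecule-only export: one fragment, no arrows
  g <- drawnGraph("c1ccccc1")
  m <- buildMolecule(g@fragments[[1]], testLibs)
  g2 <- parseCdxml(writeCdxml(m))
  expect_length(g2@fragments, 1)
  expect_equal(nrow(g2@arrows), 0)
})

test_that("CSV output is RFC 4180 with one row per step", {
  fx <- generateScheme(randomSpec(10), testLibs)
  res <- suppressWarnings(scanScheme(parseCdxml(fx$cdxml), testLibs))
  csv <- writeTable(res$steps, "csv")
  lines <- strsplit(csv, "\r\n")[[1]]
  expect_length(lines, length(res$steps) + 1)
  st <- mkStep("CCO", character(0), "CC=O")
  st@description <- "heat, then cool"
  csv2 <- writeTable(list(st), "csv")
  expect_match(csv2, '"heat, then cool"', fixed = TRUE)
  expect_equal(length(strsplit(writeTable(list(), "csv"), "\r\n")[[1]]), 1)
})

test_that("the spreadsheet variant writes the same grid", {
  st <- mkStep("CCO", "O", "CC=O")
  xl <- writeTable(list(st), "xlsx")
  members <- SchemeMineR:::zipRead(xl)
  expect_true("xl/worksheets/sheet1.xml" %in% names(members))
  sheet <- rawToChar(members[["xl/worksheets/sheet1.xml"]])
  expect_silent(xml2::read_xml(sheet))
  expect_match(sheet, "CCO&gt;O&gt;CC=O")
})

test_that("JSON serialization captures steps and isolated molecules", {
  fx <- generateScheme(randomSpec(11), testLibs)
  res <- suppressWarnings(scanScheme(parseCdxml(fx$cdxml), testLibs))
  js <- jsonlite::fromJSON(stepsToJson(res), simplifyVector = FALSE)
  expect_length(js$steps, length(res$steps))
  expect_equal(js$steps[[1]]$status, res$steps[[1]]@status)
})
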
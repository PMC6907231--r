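test_that("CDX signature scan finds every occurrence in order", {
  magic <- charToRaw("VjCD0100")
  expect_length(scanForCdxSignatures(as.raw(1:20)), 0)
  expect_equal(scanForCdxSignatures(magic), 0)
  expect_equal(scanForCdxSignatures(c(magic, raw(5), magic)), c(0, 13))
})

test_that("DOCX wrap-then-extract is the identity on payload bytes", {
  fx <- generateScheme(randomSpec(2), testLibs)
  docx <- wrapInContainer(fx$cdx, "docx")
  p <- extractFromDocx(docx)
  expect_length(p, 1)
  expect_identical(p[[1]]$data, fx$cdx)
  expect_equal(p[[1]]$dialect, "cdx")
  # two embedded schemes come back in document order
  fx2 <- generateScheme(randomSpec(3), testLibs)
  docx2 <- wrapInContainer(list(fx$cdx, fx2$cdx), "docx")
  p2 <- extractFromDocx(docx2)
  expect_length(p2, 2)
  expect_identical(p2[[1]]$data, fx$cdx)
  expect_identical(p2[[2]]$data, fx2$cdx)
  # an archive without embeddings is empty, not an error
  plain <- SchemeMineR:::zipWrite(list("doc.xml" = charToRaw("<a/>")))
  expect_length(extractFromDocx(plain), 0)
  expect_error(extractFromDocx(as.raw(1:10)), "not DOCX")
})

test_that("DOC wrap-then-extract is the identity on payload bytes", {
  fx <- generateScheme(randomSpec(4), testLibs)
  doc <- wrapInContainer(fx$cdx, "doc")
  p <- extractFromDoc(doc)
  expect_length(p, 1)
  expect_identical(p[[1]]$data, fx$cdx)
  # OLE file with no object pool
  empty <- SchemeMineR:::cfbWrite(list("WordDocument" = charToRaw("hi")))
  expect_length(extractFromDoc(empty), 0)
  expect_error(extractFromDoc(as.raw(1:10)), "not DOC")
})

test_that("payloads buried mid-stream are found by signature scan", {
  fx <- generateScheme(randomSpec(5), testLibs)
  buried <- SchemeMineR:::cfbWrite(list(
    "ObjectPool/_1/Contents" = c(charToRaw("junkheader"), fx$cdx)))
  p <- extractFromDoc(buried)
  expect_length(p, 1)
  expect_identical(p[[1]]$data, fx$cdx)
  expect_match(p[[1]]$origin, "signature-scan")
})

test_that("ELN XML separates CDXML payloads and maps table rows", {
  fx <- generateScheme(randomSpec(6), testLibs)
  recs <- data.frame(role = c("startingMaterial", "solvent", "product"),
                     identifier = c("EtOH", "THF", "EtOAc"),
                     stringsAsFactors = FALSE)
  eln <- wrapInContainer(fx$cdxml, "eln_xml", records = recs)
  out <- extractFromElnXml(eln)
  expect_length(out$payloads, 1)
  body <- sub("^<\\?xml[^>]*\\?>\\s*", "", fx$cdxml)
  body <- sub("\\s+$", "", body)
  expect_identical(out$payloads[[1]]$data, body)
  expect_equal(nrow(out$records), 3)
  expect_equal(out$records$role, c("reactant", "solvent", "product"))
  expect_equal(out$records$identifier[2], "THF")
  # unrelated XML yields nothing
  none <- extractFromElnXml("<foo><bar/></foo>")
  expect_length(none$payloads, 0)
  expect_equal(nrow(none$records), 0)
})

test_that("reconciliation reports exactly the planted discrepancies", {
  g <- simpleScheme("CCO", "CC=O", bandAbove = "NEt3, THF")
  res <- scanScheme(g, testLibs)
  consistent <- data.frame(
    role = c("reactant", "reagent", "solvent", "product"),
    identifier = c("CCO", "NEt3", "THF", "CC=O"), stringsAsFactors = FALSE)
  expect_equal(nrow(reconcile(res$steps, consistent, testLibs)), 0)
  # table lists EtOH twice is fine; MeOH only in table, product only in scheme
  planted <- data.frame(role = c("reactant", "solvent"),
                        identifier = c("CCO", "MeOH"),
                        stringsAsFactors = FALSE)
  disc <- reconcile(res$steps, planted, testLibs)
  expect_setequal(disc$type[disc$type == "missing-in-scheme"],
                  "missing-in-scheme")
  expect_equal(sum(disc$type == "missing-in-scheme"), 1)
  expect_equal(disc$smiles[disc$type == "missing-in-scheme"],
               SchemeMineR:::canonicalizeSmiles("CO"))
  expect_gte(sum(disc$type == "missing-in-table"), 3)
  unresolved <- data.frame(role = "reagent", identifier = "florblitz",
                           stringsAsFactors = FALSE)
  disc2 <- reconcile(res$steps, unresolved, testLibs)
  expect_true("unresolved" %in% disc2$type)
})
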
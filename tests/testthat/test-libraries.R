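test_that("seed libraries load complete and clean", {
  expect_warning(libs <- loadLibraries(), NA)
  expect_gte(nrow(libs@superatoms), 30)
  expect_gte(nrow(libs@names), 60)
  expect_gte(nrow(libs@solvents), 15)
  expect_gte(nrow(libs@reagents), 20)
})

test_that("entries with unparsable SMILES are dropped with a warning", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("OMe\t[*]OC", "XYZ\tnot-a-smiles"), tf)
  expect_warning(libs <- loadLibraries(superatoms = tf), "XYZ")
  expect_equal(nrow(libs@superatoms), 1)
  writeLines(character(0), tf)
  expect_silent(libs2 <- loadLibraries(superatoms = tf))
  expect_equal(nrow(libs2@superatoms), 0)
  expect_error(loadLibraries(superatoms = "/nonexistent/file.tsv"),
               "not found")
})

test_that("superatom lookup is exact first, then hyphen-stripped", {
  e <- resolveSuperatom("OMe", testLibs)
  expect_equal(e$nattach, 1L)
  expect_equal(canonicalSmiles(e$table), canonicalSmiles(
    SchemeMineR:::smilesToTable("[*]OC")))
  expect_equal(resolveSuperatom("-OMe-", testLibs)$key, "OMe")
  expect_equal(resolveSuperatom("Boc", testLibs)$key, "Boc")
  expect_null(resolveSuperatom("Qqq", testLibs))
})

test_that("name lookup honors source priority and normalization", {
  expect_equal(resolveName("DMF", testLibs),
               SchemeMineR:::canonicalizeSmiles("CN(C)C=O"))
  expect_null(resolveName("florblitz", testLibs))
  expect_equal(resolveName("dmf", testLibs), resolveName("DMF", testLibs))
  # same key in two tiers: the internal entry wins over the editor one
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("XX\tCCO\teditor", "XX\tCCN\tinternal"), tf)
  libs <- loadLibraries(names = tf)
  expect_equal(resolveName("XX", libs),
               SchemeMineR:::canonicalizeSmiles("CCN"))
})

test_that("solvent membership splits band compounds", {
  expect_equal(classifySmilesRole("C1CCOC1", testLibs), "solvent")
  expect_equal(classifySmilesRole("O", testLibs), "solvent")
  expect_equal(classifySmilesRole("CCN(CC)CC", testLibs), "reagent")
  expect_error(classifySmilesRole("xx$$", testLibs), "unparsable")
})
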
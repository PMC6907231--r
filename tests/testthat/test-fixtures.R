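test_that("generation is byte-deterministic for a fixed seed", {
  a <- generateScheme(randomSpec(8), testLibs)
  b <- generateScheme(randomSpec(8), testLibs)
  expect_identical(a$cdxml, b$cdxml)
  expect_identical(a$cdx, b$cdx)
})

test_that("different seeds give (almost always) different specs", {
  specs <- lapply(1:100, function(s) randomSpec(s))
  keys <- vapply(specs, function(sp)
    paste(unlist(sp[c("steps", "layout")]), collapse = "|"), "")
  expect_gte(length(unique(keys)), 99)
})

test_that("step count controls arrow count", {
  spec <- randomSpec(11, maxSteps = 3)
  while (length(spec$steps) != 3) spec <- randomSpec(spec$seed + 1,
                                                     maxSteps = 3)
  spec$layout <- "wrapped-chain"
  fx <- generateScheme(spec, testLibs)
  expect_equal(nrow(fx$graph@arrows), 3)
  spec1 <- randomSpec(12, maxSteps = 1)
  expect_length(spec1$steps, 1)
})

test_that("unparsable SMILES in a spec is rejected", {
  spec <- randomSpec(13)
  spec$steps[[1]]$reactants <- "xx$$"
  expect_error(generateScheme(spec, testLibs), "unparsable SMILES")
})

test_that("jittered fixtures still extract exactly (bounded jitter)", {
  for (seed in c(31, 57)) {
    fx <- generateScheme(randomSpec(seed, jitter = 0.1), testLibs)
    res <- suppressWarnings(scanScheme(parseCdxml(fx$cdxml), testLibs))
    expect_length(compareToTruth(res, fx$truth), 0)
  }
})

test_that("labelled products carry their labels through extraction", {
  spec <- randomSpec(40, maxSteps = 2)
  spec$labels <- TRUE
  fx <- generateScheme(spec, testLibs)
  res <- suppressWarnings(scanScheme(parseCdxml(fx$cdxml), testLibs))
  lab <- moleculeLabel(res$steps[[1]]@products[[1]])
  expect_equal(lab, "1")
})
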
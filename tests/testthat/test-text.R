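test_that("parseConditions reads the documented grammar", {
  cs <- parseConditions("80 °C, 12 h", testLibs)
  expect_equal(cs$temperature$value, 80)
  expect_equal(cs$temperature$unit, "°C")
  expect_equal(cs$time$value, 12)
  expect_equal(cs$time$unit, "h")
  cs2 <- parseConditions("rt, overnight", testLibs)
  expect_equal(cs2$temperature$token, "rt")
  expect_equal(cs2$time$token, "overnight")
  expect_true(is.na(parseConditions("", testLibs)$yield))
  # decimal comma, minutes, Kelvin, yield forms
  cs3 <- parseConditions("1,5 h; 300 K; yield: 73 %", testLibs)
  expect_equal(cs3$time$value, 1.5)
  expect_equal(cs3$temperature$unit, "K")
  expect_equal(cs3$yield, 73)
  expect_equal(parseConditions("95%", testLibs)$yield, 95)
})

test_that("unmatched tokens survive as residue", {
  cs <- parseConditions("80 °C, sealed tube, 2 h", testLibs)
  expect_equal(cs$residue, "sealed tube")
})

test_that("classifyTextBlock splits compounds from conditions", {
  c1 <- classifyTextBlock("DMF", testLibs)
  expect_equal(c1$kind, "compound")
  expect_equal(c1$smiles, resolveName("DMF", testLibs))
  c2 <- classifyTextBlock("NaH, 0 °C", testLibs)
  expect_equal(c2$kind, "condition")
  expect_equal(c2$smiles, resolveName("NaH", testLibs))
  expect_equal(c2$conditions$temperature$value, 0)
  c3 <- classifyTextBlock("13a", testLibs)
  expect_equal(c3$kind, "label")
  c4 <- classifyTextBlock("see procedure B", testLibs)
  expect_equal(c4$kind, "unknown")
  expect_equal(c4$raw, "see procedure B")
  # no token is lost: compounds + conditions + residue cover the input
  c5 <- classifyTextBlock("NEt3, 80 °C, mystery", testLibs)
  expect_length(c5$smiles, 1)
  expect_equal(c5$conditions$temperature$value, 80)
  expect_equal(c5$residue, "mystery")
})

test_that("extractYield binds the first percentage and warns on conflicts", {
  expect_equal(extractYield("95%"), 95)
  expect_equal(extractYield("yield: 73 %"), 73)
  expect_true(is.na(extractYield(c("no numbers here"))))
  expect_warning(y <- extractYield(c("80%", "60%")), "conflicting")
  expect_equal(y, 80)
})
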
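test_that("objects map to reactant, product and band zones by geometry", {
  g <- simpleScheme("CCO", "CC=O", bandAbove = "NEt3")
  ctx <- assignRoles(g, g@arrows[1, ])
  m <- ctx$members
  expect_equal(m$role[m$kind == "fragment"][1], "reactant")
  expect_equal(m$role[m$kind == "fragment"][2], "product")
  expect_equal(m$role[m$kind == "text"], "band")
  # far above the tail: outside band and side caps -> unassigned
  gb <- SchemeMineR:::graphBuilder()
  gb$addTable(SchemeMineR:::placeTable(SchemeMineR:::smilesToTable("CCO"),
                                       60, -300))
  gb$addArrow(100, 200, 220, 200)
  ctx2 <- assignRoles(gb$graph(), gb$graph()@arrows[1, ])
  expect_equal(nrow(ctx2$members), 0)
})

test_that("arrow styles map to reaction statuses", {
  expect_equal(interpretArrowStyle("crossed"), "failed")
  expect_equal(interpretArrowStyle("dashed"), "planned")
  expect_equal(interpretArrowStyle("plain"), "success")
  for (style in c("plain", "dashed", "crossed")) {
    g <- simpleScheme("CCO", "CC=O", style = style)
    res <- scanScheme(g, testLibs)
    expect_equal(stepStatus(res$steps[[1]]), interpretArrowStyle(style))
  }
})

test_that("a single arrow with co-reactants yields one two-reactant step", {
  g <- simpleScheme(c("CCO", "CC(=O)O"), "CCOC(C)=O",
                    bandBelow = "TsOH, reflux")
  res <- scanScheme(g, testLibs)
  expect_length(res$steps, 1)
  s <- res$steps[[1]]
  expect_length(reactants(s), 2)
  expect_length(products(s), 1)
  expect_equal(s@temperature$token, "reflux")
  expect_false(s@incomplete)
})

test_that("graphs without arrows report isolated molecules, never steps", {
  g <- drawnGraph("c1ccccc1")
  res <- scanScheme(g, testLibs)
  expect_length(res$steps, 0)
  expect_length(res$molecules, 1)
})

test_that("multistep chains split into k steps with shared intermediates", {
  for (k in 2:4) {
    spec <- randomSpec(1000 + k, maxSteps = k)
    while (length(spec$steps) != k)
      spec <- randomSpec(spec$seed + 7, maxSteps = k)
    spec$layout <- "horizontal-chain"
    fx <- generateScheme(spec, testLibs)
    res <- suppressWarnings(scanScheme(parseCdxml(fx$cdxml), testLibs))
    expect_length(res$steps, k)
    expect_equal(vapply(res$steps, function(s) s@stepIndex, 0L), 1:k)
    for (i in seq_len(k - 1)) {
      pi <- vapply(res$steps[[i]]@products, canoSmiles, "")
      ri <- vapply(res$steps[[i + 1]]@reactants, canoSmiles, "")
      expect_true(any(pi %in% ri))
    }
  }
})

test_that("cyclic arrow arrangements are rejected", {
  gb <- SchemeMineR:::graphBuilder()
  t1 <- SchemeMineR:::placeTable(SchemeMineR:::smilesToTable("CCO"), 100, 100)
  t2 <- SchemeMineR:::placeTable(SchemeMineR:::smilesToTable("CC=O"), 300, 100)
  gb$addTable(t1); gb$addTable(t2)
  gb$addArrow(150, 100, 250, 100)
  gb$addArrow(250, 120, 150, 120)
  expect_error(scanScheme(gb$graph(), testLibs), "cyclic scheme")
})

test_that("extraction is invariant under translation and scaling", {
  for (seed in c(3, 14, 28)) {
    fx <- generateScheme(randomSpec(seed), testLibs)
    g <- parseCdxml(fx$cdxml)
    base <- sigSteps(suppressWarnings(scanScheme(g, testLibs))$steps)
    for (tr in list(c(1000, 1000, 1), c(-1000, -1000, 1),
                    c(0, 0, 0.5), c(0, 0, 2))) {
      got <- sigSteps(suppressWarnings(scanScheme(
        transformGraph(g, tr[1], tr[2], tr[3]), testLibs))$steps)
      expect_identical(got, base)
    }
  }
})

test_that("no fragment is silently dropped", {
  for (seed in c(5, 21)) {
    fx <- generateScheme(randomSpec(seed), testLibs)
    res <- suppressWarnings(scanScheme(parseCdxml(fx$cdxml), testLibs))
    inSteps <- length(unlist(lapply(res$steps, function(s)
      c(s@reactants, s@reagents, s@products))))
    total <- length(res$allMolecules)
    # shared chain intermediates appear twice in steps
    expect_gte(inSteps + length(res$molecules), total)
  }
})
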
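test_that("drawn structures canonicalize like their SMILES", {
  g <- drawnGraph("C1=CC=CC=C1")
  m <- buildMolecule(g@fragments[[1]], testLibs)
  expect_equal(canoSmiles(m), SchemeMineR:::canonicalizeSmiles("c1ccccc1"))
  g2 <- drawnGraph("CCO")
  expect_equal(canoSmiles(buildMolecule(g2@fragments[[1]], testLibs)),
               SchemeMineR:::canonicalizeSmiles("CCO"))
})

test_that("canonical SMILES is invariant under atom renumbering", {
  tab <- SchemeMineR:::smilesToTable("CC(=O)Oc1ccccc1C(=O)O")
  set.seed(7)
  for (i in 1:5) {
    p <- sample(nrow(tab$atoms))
    tab2 <- tab
    tab2$atoms <- tab$atoms[p, ]
    rownames(tab2$atoms) <- NULL
    inv <- order(p)
    tab2$bonds$begin <- inv[tab$bonds$begin]
    tab2$bonds$end <- inv[tab$bonds$end]
    expect_equal(canonicalSmiles(tab2), canonicalSmiles(tab))
  }
})

test_that("abbreviations expand through the library", {
  g <- drawnGraph("Cc1ccccc1", abbrevs = data.frame(atom = 1, label = "OMe"))
  m <- buildMolecule(g@fragments[[1]], testLibs)
  expect_equal(canoSmiles(m),
               SchemeMineR:::canonicalizeSmiles("COc1ccccc1"))
  # Ts on nitrogen: N-methyl tosylamide drawn as C-N-<Ts>
  atoms <- data.frame(symbol = c("C", "N", "Q"), x = c(0, 40, 80), y = 0,
                      charge = 0L, isotope = NA_integer_)
  bonds <- data.frame(begin = c(1, 2), end = c(2, 3), order = 1,
                      display = "plain", coordinative = FALSE)
  gb <- SchemeMineR:::graphBuilder()
  gb$addTable(SchemeMineR:::chemTable(atoms, bonds),
              abbrevs = data.frame(atom = 3, label = "Ts"))
  m2 <- buildMolecule(gb$graph()@fragments[[1]], testLibs)
  expect_equal(canoSmiles(m2), SchemeMineR:::canonicalizeSmiles(
    "CNS(=O)(=O)c1ccc(C)cc1"))
})

test_that("every seed superatom passes the drawn-vs-expanded oracle", {
  sa <- testLibs@superatoms
  for (i in seq_len(nrow(sa))) {
    # reference: every attachment marker capped with a methyl group,
    # canonicalized independently of the grafting code
    oracle <- SchemeMineR:::canonicalizeSmiles(
      gsub("\\[\\*\\]", "C", sa$smiles[i]))
    n <- sa$nattach[i]
    atoms <- data.frame(symbol = c(rep("C", n), "Q"),
                        x = c(seq_len(n) * 40, 0), y = c(rep(0, n), 40),
                        charge = 0L, isotope = NA_integer_)
    bonds <- data.frame(begin = seq_len(n), end = n + 1L, order = 1,
                        display = "plain", coordinative = FALSE)
    gb <- SchemeMineR:::graphBuilder()
    gb$addTable(SchemeMineR:::chemTable(atoms, bonds),
                abbrevs = data.frame(atom = n + 1L, label = sa$key[i]))
    m <- buildMolecule(gb$graph()@fragments[[1]], testLibs)
    expect_equal(canoSmiles(m), oracle, label = sa$key[i])
  }
})

test_that("unknown and degree-mismatched abbreviations become wildcards", {
  g <- drawnGraph("Cc1ccccc1",
                  abbrevs = data.frame(atom = 1, label = "Zzz9"))
  expect_warning(m <- buildMolecule(g@fragments[[1]], testLibs),
                 "no superatom entry")
  expect_match(canoSmiles(m), "\\*")
  # OMe drawn with two bonds cannot take a 1-attachment expansion
  atoms <- data.frame(symbol = c("C", "Q", "C"), x = c(0, 40, 80),
                      y = 0, charge = 0L, isotope = NA_integer_)
  bonds <- data.frame(begin = c(1, 2), end = c(2, 3), order = 1,
                      display = "plain", coordinative = FALSE)
  gb <- SchemeMineR:::graphBuilder()
  gb$addTable(SchemeMineR:::chemTable(atoms, bonds),
              abbrevs = data.frame(atom = 2, label = "OMe"))
  expect_warning(m2 <- buildMolecule(gb$graph()@fragments[[1]], testLibs),
                 "attachment")
  expect_match(canoSmiles(m2), "\\*")
})

test_that("an undefined R-group renders as exactly one asterisk", {
  g <- drawnGraph("*c1ccccc1")
  m <- buildMolecule(g@fragments[[1]], testLibs)
  expect_equal(lengths(regmatches(canoSmiles(m),
                                  gregexpr("\\*", canoSmiles(m)))), 1L)
})

test_that("a well-defined R = Me text substitutes the residue", {
  g <- drawnGraph("*c1ccccc1",
                  texts = list(list(value = "R = Me", x = 100, y = 170)))
  res <- scanScheme(g, testLibs)
  expect_equal(canoSmiles(res$allMolecules[[1]]),
               SchemeMineR:::canonicalizeSmiles("Cc1ccccc1"))
})

test_that("wedge bonds encode stereo; plain drawings leave it undefined", {
  tab <- SchemeMineR:::smilesToTable("C[C@H](N)C(=O)O")
  gb <- SchemeMineR:::graphBuilder()
  gb$addTable(SchemeMineR:::placeTable(tab, 100, 100))
  m <- buildMolecule(gb$graph()@fragments[[1]], testLibs)
  expect_match(canoSmiles(m), "@")
  tab$bonds$display <- "plain"
  gb2 <- SchemeMineR:::graphBuilder()
  gb2$addTable(SchemeMineR:::placeTable(tab, 100, 100))
  m2 <- buildMolecule(gb2$graph()@fragments[[1]], testLibs)
  expect_false(grepl("@", canoSmiles(m2)))
})

test_that("the Molfile rendering is V2000 with coordinative bonds as type 9", {
  g <- drawnGraph("C1=CC=CC=C1")
  m <- buildMolecule(g@fragments[[1]], testLibs)
  counts <- strsplit(mdl(m), "\n")[[1]][4]
  expect_match(counts, "^  6  6")
  expect_match(counts, "V2000")
  # dative N -> Pd
  tab <- SchemeMineR:::placeTable(SchemeMineR:::smilesToTable("c1ccncc1"),
                                  100, 100)
  tab$atoms <- rbind(tab$atoms, data.frame(symbol = "Pd", x = 170, y = 100,
                                           charge = 0L,
                                           isotope = NA_integer_))
  tab$bonds <- rbind(tab$bonds, data.frame(
    begin = which(tab$atoms$symbol == "N"), end = nrow(tab$atoms),
    order = 1, display = "plain", coordinative = TRUE))
  gb <- SchemeMineR:::graphBuilder(); gb$addTable(tab)
  m2 <- buildMolecule(gb$graph()@fragments[[1]], testLibs)
  bondLines <- strsplit(mdl(m2), "\n")[[1]]
  bondLines <- bondLines[5:(4 + nrow(m2@bonds)) + nrow(m2@atoms)]
  expect_true(any(grepl("^\\s*\\d+\\s+\\d+\\s+9\\s", bondLines)))
  # and the coordinative bond never reaches the SMILES rendering
  expect_false(grepl("9", gsub("c1|1c", "", canoSmiles(m2))))
  expect_error(tableToMolfile(SchemeMineR:::chemTable(
    SchemeMineR:::emptyChemAtoms(),
    SchemeMineR:::emptyBonds()[, c("begin", "end", "order", "display",
                                   "coordinative")])), "empty molecule")
})

test_that("emitted Molfiles re-parse to the same canonical SMILES", {
  for (sm in c("CCO", "C[C@H](N)C(=O)O", "c1ccc2c(c1)cccc2",
               "CC(=O)Oc1ccccc1C(=O)O")) {
    g <- drawnGraph(sm)
    m <- buildMolecule(g@fragments[[1]], testLibs)
    expect_equal(obabelCan(mdl(m), "mol"), canoSmiles(m), label = sm)
  }
})
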
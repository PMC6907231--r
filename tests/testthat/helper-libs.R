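# Shared fixtures: the seed libraries (loaded once) and small builders.

testLibs <- loadLibraries()

# Canonical signature of extracted steps, for identity comparisons.
sigSteps <- function(steps) lapply(steps, function(s) list(
  reactants = sort(vapply(s@reactants, canoSmiles, "")),
  reagents = sort(c(vapply(s@reagents, canoSmiles, ""), s@reagentsSmiles)),
  solvents = sort(s@solventsSmiles),
  products = sort(vapply(s@products, canoSmiles, "")),
  time = s@time, temperature = s@temperature, yield = s@yield,
  status = s@status, stepIndex = s@stepIndex))

# Rigid translation + uniform scaling of a SchemeGraph.
transformGraph <- function(g, dx = 0, dy = 0, sc = 1) {
  g@fragments <- lapply(g@fragments, function(f) {
    f$atoms$x <- f$atoms$x * sc + dx
    f$atoms$y <- f$atoms$y * sc + dy
    f
  })
  for (cc in c("x", "xmin", "xmax")) g@texts[[cc]] <- g@texts[[cc]] * sc + dx
  for (cc in c("y", "ymin", "ymax")) g@texts[[cc]] <- g@texts[[cc]] * sc + dy
  for (cc in c("tailx", "headx")) g@arrows[[cc]] <- g@arrows[[cc]] * sc + dx
  for (cc in c("taily", "heady")) g@arrows[[cc]] <- g@arrows[[cc]] * sc + dy
  g
}

# A one-fragment graph drawn from SMILES, optionally turning atom rows
# into abbreviation nodes.
drawnGraph <- function(smiles, abbrevs = NULL, texts = NULL) {
  gb <- SchemeMineR:::graphBuilder()
  tab <- SchemeMineR:::placeTable(SchemeMineR:::smilesToTable(smiles),
                                  100, 100)
  gb$addTable(tab, abbrevs = abbrevs)
  if (!is.null(texts))
    for (t in texts) gb$addText(t$value, t$x, t$y)
  gb$graph()
}

# A simple one-step scheme graph: left SMILES -> right SMILES with band
# texts above/below the arrow.
simpleScheme <- function(left, right, bandAbove = NULL, bandBelow = NULL,
                         style = "plain") {
  gb <- SchemeMineR:::graphBuilder()
  x <- 60
  for (sm in left) {
    tab <- SchemeMineR:::placeTable(SchemeMineR:::smilesToTable(sm), 0, 0)
    w <- max(SchemeMineR:::tableWidth(tab), 30)
    gb$addTable(SchemeMineR:::placeTable(tab, x + w / 2, 200))
    x <- x + w + 26
  }
  tailx <- x; headx <- x + 120
  gb$addArrow(tailx, 200, headx, 200, style)
  mid <- (tailx + headx) / 2
  if (!is.null(bandAbove)) gb$addText(bandAbove, mid, 172)
  if (!is.null(bandBelow)) gb$addText(bandBelow, mid, 228)
  x <- headx + 26
  for (sm in right) {
    tab <- SchemeMineR:::placeTable(SchemeMineR:::smilesToTable(sm), 0, 0)
    w <- max(SchemeMineR:::tableWidth(tab), 30)
    gb$addTable(SchemeMineR:::placeTable(tab, x + w / 2, 200))
    x <- x + w + 26
  }
  gb$graph()
}

obabelCan <- function(input, informat) {
  tf <- tempfile(fileext = paste0(".", informat))
  if (is.raw(input)) writeBin(input, tf) else writeLines(input, tf)
  out <- system2("obabel", c(tf, "-ocan"), stdout = TRUE, stderr = FALSE)
  unlink(tf)
  trimws(sub("\t.*$", "", out[nzchar(trimws(out))]))
}

# Memoized fixture generation shared across test files.
.fixtureCache <- new.env(parent = emptyenv())
getFixture <- function(seed) {
  key <- as.character(seed)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- generateScheme(randomSpec(seed), testLibs)
  .fixtureCache[[key]]
}
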
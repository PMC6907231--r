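test_that("parseCoordinate reads decimal pairs including scientific notation", {
  expect_equal(unname(parseCoordinate("0 0")), c(0, 0))
  expect_equal(unname(parseCoordinate("12.5 -3")), c(12.5, -3))
  expect_equal(unname(parseCoordinate("1e2 4")), c(100, 4))
  expect_error(parseCoordinate("7"), "two tokens")
})

test_that("a minimal ring document parses into one fragment", {
  g <- drawnGraph("C1=CC=CC=C1")
  xml <- graphToCdxml(g)
  g2 <- parseCdxml(xml)
  expect_length(g2@fragments, 1)
  expect_equal(nrow(g2@fragments[[1]]$atoms), 6)
  expect_equal(nrow(g2@fragments[[1]]$bonds), 6)
  expect_equal(nrow(g2@arrows), 0)
})

test_that("empty and text-only documents parse", {
  g <- parseCdxml('<?xml version="1.0"?><CDXML><page/></CDXML>')
  expect_length(g@fragments, 0)
  expect_equal(nrow(g@arrows), 0)
  g2 <- parseCdxml(paste0('<CDXML><page><t id="1" p="100 50">',
                          "<s>NEt3</s></t></page></CDXML>"))
  expect_equal(nrow(g2@texts), 1)
  expect_equal(g2@texts$value, "NEt3")
})

test_that("malformed input and foreign XML are rejected", {
  expect_error(parseCdxml("this is not xml at all <"), "format error")
  expect_error(parseCdxml("<notCdxml/>"), "not CDXML")
})

test_that("node element defaults and kinds follow the dialect", {
  xml <- paste0('<CDXML><page><fragment id="1">',
                '<n id="2" p="0 0"/>',
                '<n id="3" p="30 0" Element="8"/>',
                '<n id="4" p="60 0"><t><s>OMe</s></t></n>',
                '<n id="5" p="90 0"><t><s>R</s></t></n>',
                '<b B="2" E="3"/><b B="3" E="4"/><b B="4" E="5"/>',
                "</fragment></page></CDXML>")
  f <- parseCdxml(xml)@fragments[[1]]
  expect_equal(f$atoms$element[1], 6L)  # no Element attribute -> carbon
  expect_equal(f$atoms$element[2], 8L)
  expect_equal(f$atoms$kind, c("element", "element", "abbreviation",
                               "r_group"))
  expect_equal(f$atoms$label[3], "OMe")
})

test_that("sibling order does not change the parsed graph", {
  xml1 <- paste0('<CDXML><page><fragment id="1">',
                 '<n id="2" p="0 0"/><n id="3" p="30 0" Element="8"/>',
                 '<b B="2" E="3" Order="2"/></fragment></page></CDXML>')
  xml2 <- paste0('<CDXML><page><fragment id="1">',
                 '<n id="3" p="30 0" Element="8"/><n id="2" p="0 0"/>',
                 '<b B="2" E="3" Order="2"/></fragment></page></CDXML>')
  f1 <- parseCdxml(xml1)@fragments[[1]]
  f2 <- parseCdxml(xml2)@fragments[[1]]
  key <- function(f) {
    o <- order(f$atoms$x)
    list(el = f$atoms$element[o], n = nrow(f$bonds), ord = sort(f$bonds$order))
  }
  expect_equal(key(f1), key(f2))
})

test_that("legacy graphic arrows and overlapping cross marks are understood", {
  xml <- paste0('<CDXML><page>',
                '<graphic GraphicType="Line" ArrowType="FullHead" ',
                'BoundingBox="100 50 200 60"/>',
                "</page></CDXML>")
  g <- parseCdxml(xml)
  expect_equal(nrow(g@arrows), 1)
  # tail at (right, bottom), head at (left, top)
  expect_equal(g@arrows$tailx, 200)
  expect_equal(g@arrows$headx, 100)
  xml2 <- paste0('<CDXML><page>',
                 '<arrow id="1" Tail3D="0 0 0" Head3D="100 0 0"/>',
                 '<graphic GraphicType="Symbol" SymbolType="Cross" ',
                 'BoundingBox="40 -10 60 10"/>',
                 "</page></CDXML>")
  expect_equal(parseCdxml(xml2)@arrows$style, "crossed")
})

test_that("serialization round-trips every fixture graph", {
  for (seed in c(2, 9, 17)) {
    fx <- generateScheme(randomSpec(seed), testLibs)
    g2 <- parseCdxml(graphToCdxml(fx$graph))
    r1 <- suppressWarnings(scanScheme(fx$graph, testLibs))
    r2 <- suppressWarnings(scanScheme(g2, testLibs))
    expect_identical(sigSteps(r1$steps), sigSteps(r2$steps))
  }
})
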
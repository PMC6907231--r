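test_that("magic-only and malformed CDX files are handled", {
  expect_length(parseCdx(charToRaw("VjCD0100"))@fragments, 0)
  expect_error(parseCdx(charToRaw("NOTCDX00")), "not CDX")
  # declared property length larger than the remaining bytes
  bad <- c(charToRaw("VjCD0100"), as.raw(c(1, 2, 3, 4)), raw(16),
           as.raw(c(0x00, 0x02, 0xFF, 0x00)))
  expect_error(parseCdx(bad), "truncated record at offset")
})

test_that("the record walker reads objects, properties and siblings", {
  u16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                              endian = "little")
  u32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                              endian = "little")
  # empty object: tag, id, terminator
  data <- c(u16(0x8004), u32(7), u16(0))
  tr <- SchemeMineR:::readRecordTree(data, 1L, length(data))
  expect_length(tr$records, 1)
  expect_equal(tr$records[[1]]$kind, "obj")
  expect_equal(tr$records[[1]]$id, 7)
  # property of declared length 4 consumes 4 + payload bytes
  data <- c(u16(0x0200), u16(4), as.raw(1:4))
  tr <- SchemeMineR:::readRecordTree(data, 1L, length(data))
  expect_equal(tr$records[[1]]$payload, as.raw(1:4))
  expect_equal(tr$pos, length(data) + 1L)
  # two sibling objects
  data <- c(u16(0x8004), u32(1), u16(0), u16(0x8005), u32(2), u16(0))
  tr <- SchemeMineR:::readRecordTree(data, 1L, length(data))
  expect_length(tr$records, 2)
})

test_that("typed properties decode per the binary layout", {
  u32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                              endian = "little")
  dp <- SchemeMineR:::decodeProperty
  # fixed point, y stored before x
  pos <- dp(0x0200, c(u32(131072), u32(65536)))
  expect_equal(unname(pos), c(1, 2))
  expect_equal(dp(0x0421, as.raw(0xFF)), -1)  # two's complement charge
  txt <- c(writeBin(1L, raw(), size = 2, endian = "little"), raw(10),
           charToRaw("Pd/C"))
  expect_equal(dp(0x0700, txt), "Pd/C")
  expect_error(dp(0x0200, raw(4)), "8 bytes")
})

test_that("CDX and CDXML serializations of a scheme extract identically", {
  for (seed in c(1, 6, 11, 23)) {
    fx <- generateScheme(randomSpec(seed), testLibs)
    a <- suppressWarnings(scanScheme(parseCdxml(fx$cdxml), testLibs))
    b <- suppressWarnings(scanScheme(parseCdx(fx$cdx), testLibs))
    expect_identical(sigSteps(a$steps), sigSteps(b$steps))
  }
})

test_that("every byte of a CDX file is consumed or skipped", {
  fx <- generateScheme(randomSpec(4), testLibs)
  data <- fx$cdx
  tr <- SchemeMineR:::readRecordTree(data, 29L, length(data))
  expect_equal(tr$pos, length(data) + 1L)
})
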
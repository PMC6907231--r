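# Minimal ZIP (PKZIP) serializer with stored (uncompressed) entries, used
# to build DOCX and XLSX containers deterministically. Reading goes
# through utils::unzip.

.crc32Table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- numeric(256)
      for (n in 0:255) {
        c <- n
        for (k in 1:8) {
          odd <- c %% 2
          c <- (c - odd) / 2
          if (odd) c <- .xor32(c, 3988292384)  # 0xEDB88320
        }
        t[n + 1] <- c
      }
      tab <<- t
    }
    tab
  }
})

.xor32 <- function(a, b) {
  al <- a %% 65536; ah <- (a - al) / 65536
  bl <- b %% 65536; bh <- (b - bl) / 65536
  bitwXor(as.integer(al), as.integer(bl)) +
    65536 * bitwXor(as.integer(ah), as.integer(bh))
}

crc32 <- function(data) {
  tab <- .crc32Table()
  crc <- 4294967295
  bytes <- as.integer(data)
  for (b in bytes) {
    idx <- bitwXor(as.integer(crc %% 256), b)
    crc <- .xor32((crc - crc %% 256) / 256, tab[idx + 1])
  }
  .xor32(crc, 4294967295)
}

.le16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                              endian = "little")
.le32 <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

# members: named list of raw vectors (names are archive paths, '/'
# separated). Returns the archive as a raw vector. Fixed DOS timestamp so
# output bytes are deterministic.
zipWrite <- function(members) {
  dosTime <- .le16(0); dosDate <- .le16(0x2821)  # 1 Jan 2000
  locals <- list(); centrals <- list(); offset <- 0
  for (nm in names(members)) {
    data <- members[[nm]]
    nameRaw <- charToRaw(nm)
    crc <- crc32(data)
    lh <- c(.le32(0x04034b50), .le16(20), .le16(0), .le16(0), dosTime,
            dosDate, .le32(crc), .le32(length(data)), .le32(length(data)),
            .le16(length(nameRaw)), .le16(0), nameRaw, data)
    ch <- c(.le32(0x02014b50), .le16(20), .le16(20), .le16(0), .le16(0),
            dosTime, dosDate, .le32(crc), .le32(length(data)),
            .le32(length(data)), .le16(length(nameRaw)), .le16(0), .le16(0),
            .le16(0), .le16(0), .le32(0), .le32(offset), nameRaw)
    locals[[length(locals) + 1L]] <- lh
    centrals[[length(centrals) + 1L]] <- ch
    offset <- offset + length(lh)
  }
  central <- do.call(c, centrals)
  eocd <- c(.le32(0x06054b50), .le16(0), .le16(0),
            .le16(length(members)), .le16(length(members)),
            .le32(length(central)), .le32(offset), .le16(0))
  c(do.call(c, locals), central, eocd)
}

# Read a ZIP archive from raw bytes; returns a named list of raw vectors
# in archive order.
zipRead <- function(data) {
  tf <- tempfile(fileext = ".zip")
  on.exit(unlink(tf))
  writeBin(data, tf)
  info <- tryCatch(utils::unzip(tf, list = TRUE), error = function(e) NULL)
  if (is.null(info)) stop("not a zip archive")
  exdir <- tempfile("zipx")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE), add = TRUE)
  utils::unzip(tf, exdir = exdir)
  out <- list()
  for (nm in info$Name) {
    p <- file.path(exdir, nm)
    if (dir.exists(p) || !file.exists(p)) next
    out[[nm]] <- readBin(p, "raw", n = file.size(p))
  }
  out
}

isZip <- function(data)
  length(data) >= 4 && identical(as.integer(data[1:4]),
                                 c(0x50L, 0x4bL, 0x03L, 0x04L))
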
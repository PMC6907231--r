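# Minimal OLE compound-file (CFB v3) reader and writer: 512-byte sectors,
# FAT/miniFAT, directory tree, ministream. This is the container format of
# DOC files and of the embedded-object members inside DOCX archives; no R
# package on the stack reads it, so the subset needed for embedded-object
# extraction is implemented here.

CFB_MAGIC <- as.raw(c(0xd0, 0xcf, 0x11, 0xe0, 0xa1, 0xb1, 0x1a, 0xe1))
.ENDOFCHAIN <- 4294967294  # 0xFFFFFFFE
.FATSECT <- 4294967293     # 0xFFFFFFFD
.FREESECT <- 4294967295    # 0xFFFFFFFF
.NOSTREAM <- 4294967295

isCfb <- function(data)
  length(data) >= 8 && identical(data[1:8], CFB_MAGIC)

.cfbU32 <- function(data, pos)  # 1-based offset, little-endian
  sum(as.numeric(data[pos:(pos + 3L)]) * c(1, 256, 65536, 16777216))

.cfbU16 <- function(data, pos)
  sum(as.integer(data[pos:(pos + 1L)]) * c(1, 256))

# Parse a CFB container. Returns list(entries = data.frame(path, name,
# type, size), streams = named list of raw vectors keyed by path, in
# directory-tree (document) order).
cfbRead <- function(data) {
  if (!isCfb(data)) stop("not an OLE compound file")
  ss <- 2^.cfbU16(data, 31)
  nFat <- .cfbU32(data, 45)
  firstDir <- .cfbU32(data, 49)
  miniCutoff <- .cfbU32(data, 57)
  firstMiniFat <- .cfbU32(data, 61)
  firstDifat <- .cfbU32(data, 69)
  sector <- function(n) data[(ss + n * ss + 1):(ss + n * ss + ss)]
  u32s <- function(raw) vapply(seq_len(length(raw) / 4), function(i)
    .cfbU32(raw, (i - 1) * 4 + 1), 0)
  difat <- vapply(0:108, function(i) .cfbU32(data, 77 + i * 4), 0)
  dn <- firstDifat
  while (dn < .FATSECT) {
    s <- u32s(sector(dn))
    difat <- c(difat, s[-length(s)])
    dn <- s[length(s)]
  }
  fat <- numeric(0)
  for (fs in difat[difat != .FREESECT]) fat <- c(fat, u32s(sector(fs)))
  chain <- function(start) {
    out <- raw(0); cur <- start; guard <- 0
    while (cur < .FATSECT) {
      out <- c(out, sector(cur))
      cur <- fat[cur + 1]
      guard <- guard + 1
      if (guard > length(fat) + 8) stop("corrupt FAT chain")
    }
    out
  }
  dirRaw <- chain(firstDir)
  nEntries <- length(dirRaw) / 128
  entries <- do.call(rbind, lapply(seq_len(nEntries), function(i) {
    off <- (i - 1) * 128
    nameLen <- .cfbU16(dirRaw, off + 65)
    name <- if (nameLen > 2)
      iconv(list(dirRaw[(off + 1):(off + nameLen - 2)]),
            from = "UTF-16LE", to = "UTF-8") else ""
    data.frame(name = name, type = as.integer(dirRaw[off + 67]),
               left = .cfbU32(dirRaw, off + 69),
               right = .cfbU32(dirRaw, off + 73),
               child = .cfbU32(dirRaw, off + 77),
               start = .cfbU32(dirRaw, off + 117),
               size = .cfbU32(dirRaw, off + 121),
               stringsAsFactors = FALSE)
  }))
  root <- which(entries$type == 5L)[1]
  miniFat <- if (firstMiniFat < .FATSECT) u32s(chain(firstMiniFat))
             else numeric(0)
  miniStream <- if (!is.na(root) && entries$start[root] < .FATSECT)
    chain(entries$start[root]) else raw(0)
  readStream <- function(i) {
    sz <- entries$size[i]
    if (sz == 0) return(raw(0))
    if (sz < miniCutoff && entries$type[i] == 2L) {
      out <- raw(0); cur <- entries$start[i]; guard <- 0
      while (cur < .FATSECT) {
        out <- c(out, miniStream[(cur * 64 + 1):(cur * 64 + 64)])
        cur <- miniFat[cur + 1]
        guard <- guard + 1
        if (guard > length(miniFat) + 8) stop("corrupt miniFAT chain")
      }
      out[seq_len(sz)]
    } else chain(entries$start[i])[seq_len(sz)]
  }
  paths <- character(0); streams <- list()
  visit <- function(i, prefix) {
    if (is.na(i) || i == .NOSTREAM || i + 1 > nEntries) return()
    i <- i + 1  # entries are 0-based in pointers
    visit(entries$left[i] , prefix)
    path <- if (nzchar(prefix)) paste0(prefix, "/", entries$name[i])
            else entries$name[i]
    if (entries$type[i] == 2L) {
      streams[[path]] <<- readStream(i)
    }
    if (entries$type[i] %in% c(1L, 5L)) visit(entries$child[i], path)
    visit(entries$right[i], prefix)
  }
  visit(entries$child[root], "")
  list(entries = entries, streams = streams)
}

# Write a CFB container from a named list of raw vectors; names are
# '/'-separated paths, intermediate storages are created. Deterministic
# output (zero timestamps).
cfbWrite <- function(streams) {
  # directory tree: root + storages + streams, depth-first document order
  nodes <- list(list(name = "Root Entry", type = 5L, parent = 0L,
                     data = NULL))
  findChild <- function(parent, name) {
    for (k in seq_along(nodes))
      if (nodes[[k]]$parent == parent && nodes[[k]]$name == name) return(k)
    0L
  }
  for (path in names(streams)) {
    parts <- strsplit(path, "/", fixed = TRUE)[[1]]
    parent <- 1L
    for (d in seq_along(parts)) {
      k <- findChild(parent, parts[d])
      if (k == 0L) {
        nodes[[length(nodes) + 1L]] <- list(
          name = parts[d], type = if (d == length(parts)) 2L else 1L,
          parent = parent,
          data = if (d == length(parts)) streams[[path]] else NULL)
        k <- length(nodes)
      }
      parent <- k
    }
  }
  n <- length(nodes)
  # sibling chains via right pointers; child -> first child
  childOf <- rep(.NOSTREAM, n); rightOf <- rep(.NOSTREAM, n)
  for (p in seq_len(n)) {
    kids <- which(vapply(nodes, function(x) x$parent, 0L) == p)
    if (p == 1L) kids <- setdiff(kids, 1L)
    if (length(kids)) {
      childOf[p] <- kids[1] - 1L
      for (j in seq_along(kids)[-1]) rightOf[kids[j - 1]] <- kids[j] - 1L
    }
  }
  # partition stream payloads: small -> ministream, large -> FAT
  sizes <- vapply(nodes, function(x) length(x$data), 0L)
  isStream <- vapply(nodes, function(x) x$type == 2L, TRUE)
  small <- which(isStream & sizes < 4096 & sizes > 0)
  large <- which(isStream & sizes >= 4096)
  pad <- function(x, m) c(x, raw((m - length(x) %% m) %% m))
  miniStart <- rep(.ENDOFCHAIN, n); bigStart <- rep(.ENDOFCHAIN, n)
  mini <- raw(0); miniFat <- numeric(0)
  for (i in small) {
    nsec <- ceiling(sizes[i] / 64)
    miniStart[i] <- length(miniFat)
    miniFat <- c(miniFat, length(miniFat) + seq_len(nsec - 1), .ENDOFCHAIN)
    mini <- c(mini, pad(nodes[[i]]$data, 64))
  }
  miniBytes <- length(mini)
  nDirSect <- ceiling(max(n, 4) * 128 / 512)
  nMiniFatSect <- if (length(miniFat)) ceiling(length(miniFat) * 4 / 512) else 0
  nMiniSect <- ceiling(miniBytes / 512)
  nBigSect <- sum(ceiling(sizes[large] / 512))
  nonFat <- nDirSect + nMiniFatSect + nMiniSect + nBigSect
  nFat <- 0
  repeat {
    nf <- ceiling((nonFat + nFat) * 4 / 512)
    if (nf == nFat) break
    nFat <- nf
  }
  if (nFat > 109) stop("container too large for the minimal CFB writer")
  dirStart <- nFat
  miniFatStart <- if (nMiniFatSect) dirStart + nDirSect else .ENDOFCHAIN
  miniStreamStart <- if (nMiniSect) dirStart + nDirSect + nMiniFatSect
                     else .ENDOFCHAIN
  bigBase <- dirStart + nDirSect + nMiniFatSect + nMiniSect
  cur <- bigBase
  for (i in large) { bigStart[i] <- cur; cur <- cur + ceiling(sizes[i] / 512) }
  totalSect <- nFat + nonFat
  fat <- rep(.FREESECT, nFat * 128)
  seqChain <- function(from, len) {
    if (len == 0) return()
    if (len > 1)
      fat[(from + 1):(from + len - 1)] <<- from + seq_len(len - 1)
    fat[from + len] <<- .ENDOFCHAIN
  }
  if (nFat) fat[seq_len(nFat)] <- .FATSECT
  seqChain(dirStart, nDirSect)
  if (nMiniFatSect) seqChain(miniFatStart, nMiniFatSect)
  if (nMiniSect) seqChain(miniStreamStart, nMiniSect)
  for (i in large) seqChain(bigStart[i], ceiling(sizes[i] / 512))

  dirEntry <- function(i) {
    nm <- nodes[[i]]$name
    nameU <- iconv(nm, from = "UTF-8", to = "UTF-16LE", toRaw = TRUE)[[1]]
    nameU <- c(nameU, raw(2))
    if (length(nameU) > 64) stop("directory name too long")
    start <- if (nodes[[i]]$type == 5L) {
      if (nMiniSect) miniStreamStart else .ENDOFCHAIN
    } else if (nodes[[i]]$type == 2L) {
      if (sizes[i] == 0) .ENDOFCHAIN
      else if (sizes[i] < 4096) miniStart[i] else bigStart[i]
    } else .ENDOFCHAIN
    size <- if (nodes[[i]]$type == 5L) miniBytes else sizes[i]
    c(nameU, raw(64 - length(nameU)),
      .le16(length(nameU)), as.raw(nodes[[i]]$type), as.raw(1),  # black
      .le32(.NOSTREAM), .le32(rightOf[i]), .le32(childOf[i]),
      raw(16), .le32(0), raw(16),  # clsid, state, times
      .le32(start), .le32(size), .le32(0))
  }
  dirRaw <- do.call(c, lapply(seq_len(n), dirEntry))
  emptyEntry <- c(raw(64), .le16(0), as.raw(0), as.raw(0),
                  .le32(.NOSTREAM), .le32(.NOSTREAM), .le32(.NOSTREAM),
                  raw(16), .le32(0), raw(16), .le32(.ENDOFCHAIN), .le32(0),
                  .le32(0))
  while (length(dirRaw) < nDirSect * 512) dirRaw <- c(dirRaw, emptyEntry)

  difat <- rep(.FREESECT, 109)
  if (nFat) difat[seq_len(nFat)] <- seq_len(nFat) - 1
  header <- c(CFB_MAGIC, raw(16), .le16(0x3E), .le16(3), .le16(0xFFFE),
              .le16(9), .le16(6), raw(6), .le32(0), .le32(nFat),
              .le32(dirStart), .le32(0), .le32(4096),
              .le32(if (nMiniFatSect) miniFatStart else .ENDOFCHAIN),
              .le32(nMiniFatSect), .le32(.ENDOFCHAIN), .le32(0),
              do.call(c, lapply(difat, .le32)))
  stopifnot(length(header) == 512)
  body <- c(do.call(c, lapply(fat, .le32)), dirRaw)
  if (nMiniFatSect) {
    mfRaw <- do.call(c, lapply(miniFat, .le32))
    body <- c(body, pad(mfRaw, 512))
  }
  if (nMiniSect) body <- c(body, pad(mini, 512))
  for (i in large) body <- c(body, pad(nodes[[i]]$data, 512))
  c(header, body)
}
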
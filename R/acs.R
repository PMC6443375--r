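# Minimal ZIP container support for ACS (Archival Cytometry Standard)
# bundles: a writer emitting stored (uncompressed) entries with
# table-driven CRC-32, and extraction via utils::unzip. The TOC
# manifest is optional: member discovery is by file extension.

.crc32Table <- local({
  tab <- integer(256)
  poly <- -306674912L            # 0xEDB88320 as a signed 32-bit int
  for (n in 0:255) {
    cc <- n
    for (k in 1:8)
      cc <- if (bitwAnd(cc, 1L) != 0L) bitwXor(poly, bitwShiftR(cc, 1L))
            else bitwShiftR(cc, 1L)
    tab[n + 1L] <- cc
  }
  tab
})

.crc32 <- function(bytes) {
  crc <- -1L                      # 0xFFFFFFFF
  b <- as.integer(bytes)
  for (i in seq_along(b))
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   .crc32Table[bitwAnd(bitwXor(crc, b[i]), 255L) + 1L])
  bitwXor(crc, -1L)
}

.wU16 <- function(con, x) writeBin(as.integer(x), con, size = 2, endian = "little")
.wU32 <- function(con, x) writeBin(as.integer(x), con, size = 4, endian = "little")

#' Pack files into a ZIP (ACS) container
#'
#' Entries are stored uncompressed; ACS payloads (FCS binaries, XML)
#' are small at desk scale and the container stays readable by any
#' unzip implementation.
#'
#' @param zipPath output container path.
#' @param files named character vector: names are member names inside
#'   the container, values are paths of existing files.
#' @return `zipPath`, invisibly.
#' @export
packZip <- function(zipPath, files) {
  if (is.null(names(files)) || any(!nzchar(names(files))))
    cytoStop("MALFORMED_CONTAINER", "zip members must be named")
  con <- file(zipPath, "wb")
  on.exit(close(con))
  offsets <- integer(0); crcs <- integer(0); sizes <- integer(0)
  for (i in seq_along(files)) {
    data <- readBin(files[[i]], "raw", n = file.size(files[[i]]))
    nameRaw <- charToRaw(names(files)[i])
    offsets[i] <- seek(con)
    crcs[i] <- .crc32(data); sizes[i] <- length(data)
    .wU32(con, 0x04034b50); .wU16(con, 20L); .wU16(con, 0L)
    .wU16(con, 0L)                               # method: stored
    .wU16(con, 0L); .wU16(con, 0x21L)            # mod time / date
    .wU32(con, crcs[i]); .wU32(con, sizes[i]); .wU32(con, sizes[i])
    .wU16(con, length(nameRaw)); .wU16(con, 0L)
    writeBin(nameRaw, con); writeBin(data, con)
  }
  cdStart <- seek(con)
  for (i in seq_along(files)) {
    nameRaw <- charToRaw(names(files)[i])
    .wU32(con, 0x02014b50); .wU16(con, 20L); .wU16(con, 20L)
    .wU16(con, 0L); .wU16(con, 0L)
    .wU16(con, 0L); .wU16(con, 0x21L)
    .wU32(con, crcs[i]); .wU32(con, sizes[i]); .wU32(con, sizes[i])
    .wU16(con, length(nameRaw)); .wU16(con, 0L); .wU16(con, 0L)
    .wU16(con, 0L); .wU16(con, 0L)
    .wU32(con, 0L); .wU32(con, offsets[i])
    writeBin(nameRaw, con)
  }
  cdEnd <- seek(con)
  .wU32(con, 0x06054b50); .wU16(con, 0L); .wU16(con, 0L)
  .wU16(con, length(files)); .wU16(con, length(files))
  .wU32(con, cdEnd - cdStart); .wU32(con, cdStart)
  .wU16(con, 0L)
  invisible(zipPath)
}

#' Extract a ZIP (ACS) container
#' @param zipPath container path.
#' @param exdir extraction directory (created if needed).
#' @return Character vector of extracted file paths.
#' @export
unpackZip <- function(zipPath, exdir = tempfile("acs")) {
  if (!file.exists(zipPath))
    cytoStop("MISSING_FILE", paste0("no such file: ", zipPath))
  dir.create(exdir, recursive = TRUE, showWarnings = FALSE)
  utils::unzip(zipPath, exdir = exdir)
}

isZipFile <- function(path) {
  if (!file.exists(path) || file.size(path) < 4) return(FALSE)
  identical(readBin(path, "raw", n = 2), as.raw(c(0x50, 0x4b)))
}
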
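# FCS 3.0/3.1 binary I/O. Reader accepts $DATATYPE F (32-bit float)
# and I (unsigned integer, uniform $PnB of 8/16/32), $MODE L, both byte
# orders. Writer always emits FCS 3.1 little-endian float with linear
# $PnE, the single canonical output dialect. ANALYSIS and supplemental
# TEXT segments are ignored; the CRC field is written as zeros.

.fcsDelim <- "/"

.fcsStructuralKeys <- function() c(
  "$BEGINANALYSIS", "$ENDANALYSIS", "$BEGINDATA", "$ENDDATA",
  "$BEGINSTEXT", "$ENDSTEXT", "$NEXTDATA", "$TOT", "$PAR", "$MODE",
  "$DATATYPE", "$BYTEORD")

# TEXT segment parser with the doubled-delimiter escaping convention.
.parseFcsText <- function(txt, delim) {
  body <- sub(paste0("^\\", delim), "", txt)
  body <- sub(paste0("\\", delim, "$"), "", body)
  parts <- strsplit(body, delim, fixed = TRUE)[[1]]
  toks <- character(0)
  if (length(parts)) {
    cur <- parts[1]; k <- 2L
    while (k <= length(parts)) {
      if (parts[k] == "" && k < length(parts)) {
        cur <- paste0(cur, delim, parts[k + 1L]); k <- k + 2L
      } else {
        toks <- c(toks, cur); cur <- parts[k]; k <- k + 1L
      }
    }
    toks <- c(toks, cur)
  }
  if (length(toks) %% 2L == 1L) toks <- toks[-length(toks)]
  keys <- toks[c(TRUE, FALSE)]
  vals <- toks[c(FALSE, TRUE)]
  keys <- ifelse(startsWith(keys, "$"), toupper(keys), keys)
  names(vals) <- keys
  vals
}

.fcsEndian <- function(byteord) {
  b <- trimws(strsplit(byteord, ",", fixed = TRUE)[[1]])
  if (identical(b[1], "1")) "little"
  else if (b[1] %in% c("4", "2") && b[length(b)] == "1") "big"
  else cytoStop("MALFORMED_FILE",
                paste0("unsupported $BYTEORD '", byteord, "'"))
}

.requireKeyword <- function(kw, key) {
  if (is.null(kw[[key]]) || !nzchar(kw[[key]]))
    cytoStop("MALFORMED_FILE", paste0("missing required keyword ", key))
  kw[[key]]
}

#' Read an FCS 3.0/3.1 file
#'
#' Returns the linearized event matrix with channel metadata and the
#' full TEXT-segment keyword map. Log-amplified integer channels
#' ($PnE = "f1,f2" with f1 > 0) are linearized as
#' `value = f2 * 10^(f1 * x / $PnR)` (f2 = 0 treated as 1); the
#' conversion is logged at INFO. A $SPILLOVER/$SPILL keyword is kept
#' verbatim for the compensation machinery.
#'
#' @param path path to the FCS file.
#' @return A [CytoSample-class].
#' @export
readFCS <- function(path) {
  if (!file.exists(path))
    cytoStop("MISSING_FILE", paste0("no such file: ", path))
  raw <- readBin(path, what = "raw", n = file.size(path))
  if (length(raw) < 58)
    cytoStop("MALFORMED_FILE", "file shorter than an FCS header")
  version <- rawToChar(raw[1:6])
  if (!version %in% c("FCS3.0", "FCS3.1"))
    cytoStop("MALFORMED_FILE",
             paste0("unsupported FCS version '", version, "'"))
  off <- function(i) {
    s <- trimws(rawToChar(raw[(10 + 8 * (i - 1) + 1):(10 + 8 * i)]))
    if (!nzchar(s)) 0 else suppressWarnings(as.numeric(s))
  }
  tb <- off(1); te <- off(2); db <- off(3); de <- off(4)
  if (is.na(tb) || is.na(te) || tb <= 0 || te <= tb)
    cytoStop("MALFORMED_FILE", "invalid TEXT segment offsets")
  delim <- rawToChar(raw[tb + 1])
  kwvec <- .parseFcsText(rawToChar(raw[(tb + 1):(te + 1)]), delim)
  kw <- as.list(kwvec)

  mode <- .requireKeyword(kw, "$MODE")
  if (mode != "L")
    cytoStop("UNSUPPORTED_MODE",
             paste0("$MODE '", mode, "' not supported (only L)"))
  tot <- as.integer(.requireKeyword(kw, "$TOT"))
  par <- as.integer(.requireKeyword(kw, "$PAR"))
  dtype <- .requireKeyword(kw, "$DATATYPE")
  endian <- .fcsEndian(.requireKeyword(kw, "$BYTEORD"))
  if (!dtype %in% c("F", "I"))
    cytoStop("MALFORMED_FILE",
             paste0("unsupported $DATATYPE '", dtype, "'"))
  if (is.na(db) || db == 0) db <- as.numeric(kw[["$BEGINDATA"]])
  if (is.na(de) || de == 0) de <- as.numeric(kw[["$ENDDATA"]])

  chanKey <- function(key, n, default) {
    vapply(seq_len(n), function(i) {
      v <- kw[[paste0("$P", i, key)]]
      if (is.null(v)) default else v
    }, character(1))
  }
  nm <- chanKey("N", par, "")
  nm[!nzchar(nm)] <- paste0("P", which(!nzchar(nm)))
  mk <- chanKey("S", par, "")
  rg <- as.numeric(chanKey("R", par, "262144"))

  nvals <- tot * par
  mat <- if (nvals == 0) {
    matrix(numeric(0), nrow = 0, ncol = par)
  } else {
    if (is.na(db) || db <= 0)
      cytoStop("MALFORMED_FILE", "cannot locate DATA segment")
    if (dtype == "F") {
      vals <- readBin(raw[(db + 1):(db + 4 * nvals)], what = "numeric",
                      size = 4, n = nvals, endian = endian)
    } else {
      bits <- unique(as.integer(chanKey("B", par, "16")))
      if (length(bits) != 1L || !bits %in% c(8L, 16L, 32L))
        cytoStop("MALFORMED_FILE",
                 "integer data requires a uniform $PnB of 8, 16 or 32")
      size <- bits / 8L
      if (size == 4L) {
        vals <- readBin(raw[(db + 1):(db + 4 * nvals)], what = "integer",
                        size = 4, n = nvals, endian = endian)
        vals <- as.numeric(vals)
        vals[vals < 0] <- vals[vals < 0] + 2^32
      } else {
        vals <- as.numeric(readBin(raw[(db + 1):(db + size * nvals)],
                                   what = "integer", size = size,
                                   n = nvals, signed = FALSE,
                                   endian = endian))
      }
    }
    matrix(vals, nrow = tot, ncol = par, byrow = TRUE)
  }

  # $PnE log-amplifier linearization (integer-era channels)
  for (i in seq_len(par)) {
    pe <- kw[[paste0("$P", i, "E")]]
    if (is.null(pe)) next
    f <- suppressWarnings(as.numeric(strsplit(pe, ",")[[1]]))
    if (length(f) == 2 && !anyNA(f) && f[1] > 0) {
      f2 <- if (f[2] == 0) 1 else f[2]
      cytoLog("INFO", "channel ", nm[i], ": linearizing $PnE = '", pe, "'")
      mat[, i] <- f2 * 10^(f[1] * mat[, i] / rg[i])
    }
  }
  if (anyNA(mat))
    cytoStop("MALFORMED_FILE", "event data contain NaN values")

  sid <- if (!is.null(kw[["$FIL"]]) && nzchar(kw[["$FIL"]])) kw[["$FIL"]]
         else basename(path)
  cytoSample(sid, mat, channels = nm, markers = mk, range = rg,
             keywords = kwvec)
}

#' Write a sample as an FCS 3.1 file
#'
#' Emits $DATATYPE F, $MODE L, $BYTEORD 1,2,3,4 (little endian), linear
#' $PnE "0,0" and $PnR = max(1, ceiling of the column maximum). Reading
#' the result back reproduces the event matrix at 32-bit float
#' precision and preserves $PnN/$PnS plus all non-structural keywords.
#'
#' @param sample a [CytoSample-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeFCS <- function(sample, path) {
  v <- validObject(sample, test = TRUE)
  if (!isTRUE(v))
    cytoStop("INVALID_SAMPLE", paste(v, collapse = "; "))
  mat <- sample@exprs
  k <- ncol(mat)
  if (k == 0L) cytoStop("INVALID_SAMPLE", "sample has zero channels")
  n <- nrow(mat)
  d <- .fcsDelim
  esc <- function(x) gsub(d, paste0(d, d), x, fixed = TRUE)

  rng <- if (n > 0) pmax(1, ceiling(apply(mat, 2, max))) else
    pmax(1, ceiling(sample@channels$range))
  kv <- c("$TOT" = as.character(n), "$PAR" = as.character(k),
          "$MODE" = "L", "$DATATYPE" = "F", "$BYTEORD" = "1,2,3,4",
          "$NEXTDATA" = "0", "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
          "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0")
  for (i in seq_len(k)) {
    kv[paste0("$P", i, "N")] <- sample@channels$name[i]
    if (nzchar(sample@channels$marker[i]))
      kv[paste0("$P", i, "S")] <- sample@channels$marker[i]
    kv[paste0("$P", i, "B")] <- "32"
    kv[paste0("$P", i, "E")] <- "0,0"
    kv[paste0("$P", i, "R")] <- fmtNum(rng[i])
  }
  drop <- c(.fcsStructuralKeys(),
            paste0("$P", rep(seq_len(k), each = 5),
                   rep(c("N", "S", "B", "E", "R"), k)))
  extra <- sample@keywords[!names(sample@keywords) %in% drop &
                             nzchar(sample@keywords)]
  if (!"$FIL" %in% names(extra)) extra["$FIL"] <- sample@sampleId
  kv <- c(kv, extra)

  textStart <- 58L
  buildText <- function(begin, end) {
    all <- c(kv, "$BEGINDATA" = sprintf("%010d", begin),
             "$ENDDATA" = sprintf("%010d", end))
    paste0(d, paste0(esc(names(all)), d, esc(unname(all)), d,
                     collapse = ""))
  }
  txtLen <- nchar(buildText(0L, 0L), type = "bytes")
  dataStart <- if (n > 0) textStart + txtLen else 0L
  dataEnd <- if (n > 0) dataStart + 4L * n * k - 1L else 0L
  txt <- buildText(dataStart, dataEnd)
  stopifnot(nchar(txt, type = "bytes") == txtLen)

  hdrOff <- function(x) formatC(x, width = 8, flag = " ")
  header <- paste0("FCS3.1    ",
                   hdrOff(textStart), hdrOff(textStart + txtLen - 1L),
                   hdrOff(dataStart), hdrOff(dataEnd),
                   hdrOff(0), hdrOff(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(txt), con)
  if (n > 0)
    writeBin(as.vector(t(mat)), con, size = 4, endian = "little")
  writeBin(charToRaw("00000000"), con)
  invisible(path)
}

#' Cast a numeric matrix through 32-bit float precision
#'
#' The representable value each matrix entry takes after an FCS
#' write/read cycle ($DATATYPE F stores 32-bit floats).
#'
#' @param mat numeric matrix.
#' @return The matrix with every entry rounded to float32.
#' @export
asFloat32 <- function(mat) {
  v <- readBin(writeBin(as.vector(mat), raw(), size = 4),
               what = "numeric", size = 4, n = length(mat))
  matrix(v, nrow = nrow(mat), ncol = ncol(mat), dimnames = dimnames(mat))
}
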
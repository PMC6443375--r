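# Independent oracles and fixture builders shared across tests. Each
# oracle is a deliberately naive re-implementation kept separate from
# the code paths it checks.

# Even-odd ray-casting point-in-polygon, boundary inclusive; loops over
# points with edge-wise arithmetic (the package loops over edges).
oraclePointInPolygon <- function(points, vertices) {
  nv <- nrow(vertices)
  x1 <- vertices[, 1]; y1 <- vertices[, 2]
  x2 <- vertices[c(2:nv, 1), 1]; y2 <- vertices[c(2:nv, 1), 2]
  apply(points, 1, function(p) {
    px <- p[1]; py <- p[2]
    # boundary
    s <- pmax(1, abs(x1), abs(y1), abs(x2), abs(y2))
    cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    onb <- abs(cross) <= 1e-12 * s * s &
      px >= pmin(x1, x2) - 1e-12 * s & px <= pmax(x1, x2) + 1e-12 * s &
      py >= pmin(y1, y2) - 1e-12 * s & py <= pmax(y1, y2) + 1e-12 * s
    if (any(onb)) return(TRUE)
    crosses <- ((y1 > py) != (y2 > py)) &
      px < x1 + (py - y1) * (x2 - x1) / (y2 - y1)
    sum(crosses, na.rm = TRUE) %% 2 == 1
  })
}

# Half-plane intersection membership for convex, counter-clockwise
# polygons (boundary inclusive).
oracleConvexPolygon <- function(points, vertices) {
  nv <- nrow(vertices)
  keep <- rep(TRUE, nrow(points))
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    ex <- vertices[j, 1] - vertices[i, 1]
    ey <- vertices[j, 2] - vertices[i, 2]
    cross <- ex * (points[, 2] - vertices[i, 2]) -
      ey * (points[, 1] - vertices[i, 1])
    keep <- keep & cross >= -1e-12
  }
  keep
}

# Plain bisection solver for the logicle forward map on the closed-form
# biexponential, independent of the package's Newton iteration.
oracleLogicleForward <- function(x, T, W, M, A = 0, iters = 120L) {
  B <- function(y) logicleInverse(y, T, W, M, A)
  lo <- rep(-2, length(x)); hi <- rep(3, length(x))
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    below <- B(mid) < x
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  (lo + hi) / 2
}

# Naive per-event recursive tree evaluator: no caching, no vectorized
# predicates, explicit matrix inversion for ellipsoids.
oracleResolve <- function(ws, sid) {
  sample <- ws@samples[[sid]]
  tree <- gatingTreeFor(ws, sid)
  chans <- channelNames(sample)
  prepared <- function(dim) {
    sm <- selectCompensation(sample, ws, dim@compensationRef)
    mat <- eventMatrix(sample)
    if (!all(sm@S == diag(nrow(sm@S))))
      mat[, match(sm@detectors, chans)] <-
        mat[, match(sm@detectors, chans), drop = FALSE] %*% solve(sm@S)
    x <- mat[, dim@channel]
    if (dim@transformRef != "identity")
      x <- makeTransform(ws@transforms[[dim@transformRef]])$forward(x)
    x
  }
  cols <- list()
  colFor <- function(dim) {
    key <- paste(dim@channel, dim@transformRef, dim@compensationRef)
    if (is.null(cols[[key]])) cols[[key]] <<- prepared(dim)
    cols[[key]]
  }
  inGateEvent <- function(g, i, memb) {
    if (is(g, "RectangleGate")) {
      for (j in seq_along(g@dims)) {
        v <- colFor(g@dims[[j]])[i]
        if (!is.na(g@min[j]) && v < g@min[j]) return(FALSE)
        if (!is.na(g@max[j]) && v > g@max[j]) return(FALSE)
      }
      TRUE
    } else if (is(g, "PolygonGate")) {
      p <- cbind(colFor(g@dims[[1]])[i], colFor(g@dims[[2]])[i])
      oraclePointInPolygon(p, g@vertices)
    } else if (is(g, "EllipsoidGate")) {
      v <- vapply(g@dims, function(d) colFor(d)[i], numeric(1)) - g@mu
      drop(t(v) %*% solve(g@cov) %*% v) <= g@distSq
    } else if (is(g, "QuadrantGate")) {
      sel <- strsplit(g@selector, "")[[1]]
      ok <- TRUE
      for (j in 1:2) {
        v <- colFor(g@dims[[j]])[i]
        side <- if (sel[j] == "+") v >= g@dividers[j] else v < g@dividers[j]
        ok <- ok && side
      }
      ok
    } else stop("unexpected gate class in oracle")
  }
  n <- nEvents(sample)
  paths <- populationPaths(tree)
  out <- lapply(paths, function(p) rep(NA, n))
  names(out) <- paths
  membEvent <- function(path, i) {
    if (!is.na(out[[path]][i])) return(out[[path]][i])
    r <- if (path == "root") TRUE else {
      node <- tree@nodes[[path]]
      par <- membEvent(node@parentPath, i)
      g <- node@gate
      if (!par) FALSE
      else if (is(g, "BooleanGate")) {
        vals <- vapply(g@operands, membEvent, logical(1), i = i)
        switch(g@operator, NOT = !vals[1], AND = all(vals), OR = any(vals))
      } else inGateEvent(g, i, out)
    }
    out[[path]][i] <<- r
    r
  }
  for (i in seq_len(n)) for (p in paths) membEvent(p, i)
  lapply(out, as.logical)
}

# Hand-construct a minimal FCS 3.1 file with explicit byte order.
makeHandFcs <- function(path, values, channels, byteord = "1,2,3,4",
                        extraKeywords = character(0)) {
  n <- nrow(values); k <- ncol(values)
  kv <- c("$TOT" = as.character(n), "$PAR" = as.character(k),
          "$MODE" = "L", "$DATATYPE" = "F", "$BYTEORD" = byteord,
          "$NEXTDATA" = "0")
  for (i in seq_len(k)) {
    kv[paste0("$P", i, "N")] <- channels[i]
    kv[paste0("$P", i, "B")] <- "32"
    kv[paste0("$P", i, "E")] <- "0,0"
    kv[paste0("$P", i, "R")] <- "262144"
  }
  kv <- c(kv, extraKeywords)
  textStart <- 58L
  build <- function(b, e) paste0("/", paste0(names(kv), "/", unname(kv),
                                             "/", collapse = ""),
                                 "$BEGINDATA/", sprintf("%010d", b),
                                 "/$ENDDATA/", sprintf("%010d", e), "/")
  tl <- nchar(build(0L, 0L))
  db <- textStart + tl
  de <- db + 4L * n * k - 1L
  txt <- build(db, de)
  endian <- if (startsWith(byteord, "1")) "little" else "big"
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0("FCS3.1    ",
                            formatC(textStart, width = 8),
                            formatC(textStart + tl - 1L, width = 8),
                            formatC(db, width = 8), formatC(de, width = 8),
                            formatC(0L, width = 8), formatC(0L, width = 8))),
           con)
  writeBin(charToRaw(txt), con)
  writeBin(as.vector(t(values)), con, size = 4, endian = endian)
  path
}

# Binary-safe byte patching: replace the first occurrence of an ASCII
# pattern inside a (binary) file, preserving total length.
patchFileBytes <- function(path, old, new) {
  stopifnot(nchar(old) == nchar(new))
  raw <- readBin(path, "raw", file.size(path))
  pat <- charToRaw(old)
  hits <- which(raw == pat[1])
  for (h in hits) {
    if (h + length(pat) - 1L > length(raw)) next
    if (all(raw[h:(h + length(pat) - 1L)] == pat)) {
      raw[h:(h + length(pat) - 1L)] <- charToRaw(new)
      writeBin(raw, path)
      return(invisible(path))
    }
  }
  stop("pattern not found: ", old)
}

# A tiny fully-featured workspace used by structural tests.
tinyWorkspace <- function(nEvents = 50, seed = 7) {
  set.seed(seed)
  chans <- c("FSC-A", "FL1-A", "FL2-A")
  mat <- asFloat32(matrix(runif(nEvents * 3, 0, 1000), ncol = 3))
  s <- cytoSample("tiny.fcs", mat, chans, markers = c("", "CD4", "CD8"))
  tf <- transformDef("lin1", "linear", T = 1000, A = 0)
  g1 <- rectangleGate(list(gateDimension("FSC-A", "lin1")), 0.2, 0.8)
  g2 <- polygonGate(list(gateDimension("FL1-A", "lin1"),
                         gateDimension("FL2-A", "lin1")),
                    rbind(c(0.1, 0.1), c(0.9, 0.1), c(0.5, 0.9)))
  tree <- gatingTree()
  tree <- addPopulation(tree, "root", "cells", g1)
  tree <- addPopulation(tree, "root/cells", "lymph", g2)
  workspace(samples = list(s), template = tree,
            transforms = list(lin1 = tf), dialect = "gatingml")
}
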
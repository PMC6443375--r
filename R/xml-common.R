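# Shared Gating-ML 2.0 XML vocabulary used by all three dialect
# readers/writers. Gate coordinates are ALWAYS stored on the
# transformed scale in memory; a dialect supplies a per-dimension
# coordinate codec (identity for Gating-ML/Cytobank, the declared
# transform's inverse/forward pair for the raw-scale FlowJo dialect).

.NS_GATING <- "http://www.isac-net.org/std/Gating-ML/v2.0/gating"
.NS_TRANSF <- "http://www.isac-net.org/std/Gating-ML/v2.0/transformations"
.NS_DATA <- "http://www.isac-net.org/std/Gating-ML/v2.0/datatypes"

.nsDecls <- function() c(
  "xmlns:gating" = .NS_GATING,
  "xmlns:transforms" = .NS_TRANSF,
  "xmlns:data-type" = .NS_DATA)

# identity codec: serialize coordinates as stored (transformed scale)
.identityCodec <- function(dim) list(out = identity, into = identity)

# ---- transforms -------------------------------------------------------

.writeTransformEl <- function(parent, def, channel = NULL) {
  el <- xml2::xml_add_child(parent, "transforms:transformation",
                            "transforms:id" = def@transformId)
  attrs <- switch(def@family,
    linear = c("transforms:T" = fmtNum(def@T), "transforms:A" = fmtNum(def@A)),
    log = c("transforms:T" = fmtNum(def@T), "transforms:M" = fmtNum(def@M)),
    asinh = c("transforms:T" = fmtNum(def@T), "transforms:M" = fmtNum(def@M),
              "transforms:A" = fmtNum(def@A)),
    logicle = c("transforms:T" = fmtNum(def@T), "transforms:W" = fmtNum(def@W),
                "transforms:M" = fmtNum(def@M), "transforms:A" = fmtNum(def@A)))
  elName <- switch(def@family, linear = "transforms:flin",
                   log = "transforms:flog", asinh = "transforms:fasinh",
                   logicle = "transforms:logicle")
  fn <- xml2::xml_add_child(el, elName)
  for (a in names(attrs)) xml2::xml_set_attr(fn, a, attrs[[a]])
  if (!is.null(channel))
    xml2::xml_add_child(fn, "data-type:parameter",
                        "data-type:name" = channel)
  el
}

.parseTransformFn <- function(fn, transformId) {
  fam <- switch(xml2::xml_name(fn),
                flin = "linear", flog = "log", fasinh = "asinh",
                logicle = "logicle",
                cytoStop("UNSUPPORTED_TRANSFORM", paste0(
                  "unknown transform element '", xml2::xml_name(fn), "'")))
  num <- function(a, default) {
    v <- xml2::xml_attr(fn, a)
    if (is.na(v)) default else parseNum(v)
  }
  transformDef(transformId, fam, T = num("T", 262144),
               M = num("M", 4.5), A = num("A", 0), W = num("W", 0.5))
}

.readTransformEls <- function(root, ns) {
  out <- list()
  if (!.NS_TRANSF %in% ns) return(out)   # namespace never declared
  for (el in xml2::xml_find_all(root, "./transforms:transformation", ns)) {
    tid <- xml2::xml_attr(el, "id")
    fn <- xml2::xml_find_first(el, "./transforms:*", ns)
    out[[tid]] <- .parseTransformFn(fn, tid)
  }
  out
}

# ---- spillover matrices -----------------------------------------------

.writeSpillEl <- function(parent, id, sm) {
  el <- xml2::xml_add_child(parent, "transforms:spilloverMatrix",
                            "transforms:id" = id)
  dets <- xml2::xml_add_child(el, "transforms:detectors")
  for (d in sm@detectors)
    xml2::xml_add_child(dets, "data-type:fcs-dimension",
                        "data-type:name" = d)
  for (i in seq_len(nrow(sm@S))) {
    row <- xml2::xml_add_child(el, "transforms:spectrum")
    for (j in seq_len(ncol(sm@S)))
      xml2::xml_add_child(row, "transforms:coefficient",
                          "transforms:value" = fmtNum(sm@S[i, j]))
  }
  el
}

.readSpillEls <- function(root, ns) {
  out <- list()
  if (!.NS_TRANSF %in% ns) return(out)   # namespace never declared
  for (el in xml2::xml_find_all(root, "./transforms:spilloverMatrix", ns)) {
    id <- xml2::xml_attr(el, "id")
    dets <- xml2::xml_attr(
      xml2::xml_find_all(el, "./transforms:detectors/data-type:fcs-dimension", ns),
      "name")
    rows <- xml2::xml_find_all(el, "./transforms:spectrum", ns)
    S <- do.call(rbind, lapply(rows, function(r)
      parseNum(xml2::xml_attr(
        xml2::xml_find_all(r, "./transforms:coefficient", ns), "value"))))
    out[[id]] <- spilloverMatrix(dets, S)
  }
  out
}

# ---- gate dimensions --------------------------------------------------

.writeDimEl <- function(parent, dim, min = NA, max = NA,
                        writeTransformRef = TRUE) {
  el <- xml2::xml_add_child(parent, "gating:dimension")
  compRef <- if (dim@compensationRef == "auto") "FCS" else dim@compensationRef
  xml2::xml_set_attr(el, "gating:compensation-ref", compRef)
  if (writeTransformRef && dim@transformRef != "identity")
    xml2::xml_set_attr(el, "gating:transformation-ref", dim@transformRef)
  if (!is.na(min)) xml2::xml_set_attr(el, "gating:min", fmtNum(min))
  if (!is.na(max)) xml2::xml_set_attr(el, "gating:max", fmtNum(max))
  xml2::xml_add_child(el, "data-type:fcs-dimension",
                      "data-type:name" = dim@channel)
  el
}

.readDimEl <- function(el, ns, transformForChannel = NULL) {
  chan <- xml2::xml_attr(
    xml2::xml_find_first(el, "./data-type:fcs-dimension", ns), "name")
  compRef <- xml2::xml_attr(el, "compensation-ref")
  if (is.na(compRef)) compRef <- "auto"
  if (compRef == "FCS") compRef <- "auto"
  tfRef <- xml2::xml_attr(el, "transformation-ref")
  if (is.na(tfRef)) {
    tfRef <- if (is.null(transformForChannel)) "identity"
             else transformForChannel(chan)
  }
  list(dim = gateDimension(chan, tfRef, compRef),
       min = parseNum(xml2::xml_attr(el, "min")),
       max = parseNum(xml2::xml_attr(el, "max")))
}

# ---- gates ------------------------------------------------------------

# codecFor(dim) -> list(out = f, into = g): f maps internal
# (transformed-scale) coordinates to the serialized scale, g the
# reverse. refOut(path) serializes a boolean operand reference.
.writeGateEl <- function(container, gate, id, parentId, name,
                         codecFor = .identityCodec, refOut = identity,
                         writeTransformRef = TRUE, nativeEllipse = TRUE) {
  addGate <- function(elName) {
    el <- xml2::xml_add_child(container, elName, "gating:id" = id)
    if (!is.na(parentId) && nzchar(parentId))
      xml2::xml_set_attr(el, "gating:parent_id", parentId)
    info <- xml2::xml_add_child(el, "data-type:custom_info")
    xml2::xml_add_child(info, "population_name", name)
    el
  }
  if (is(gate, "EllipsoidGate") && !nativeEllipse) {
    # target dialect lacks a native ellipse: ship an inscribed
    # 100-vertex polygon (2-D) or the bounding box (higher dimensions,
    # which the target cannot display anyway), keeping the exact
    # quadratic form alongside so a round-trip through our own reader
    # is lossless.
    carrier <- if (length(gate@dims) == 2L) polygonizeEllipsoid(gate, 100L)
    else {
      half <- sqrt(gate@distSq * diag(gate@cov))
      rectangleGate(gate@dims, gate@mu - half, gate@mu + half)
    }
    el <- .writeGateEl(container, carrier, id, parentId, name, codecFor,
                       refOut, writeTransformRef, nativeEllipse)
    info <- xml2::xml_find_first(el, "./*[local-name()='custom_info']")
    ex <- xml2::xml_add_child(info, "ellipsoid")
    xml2::xml_add_child(ex, "mean", paste(fmtNum(gate@mu), collapse = " "))
    xml2::xml_add_child(ex, "cov", paste(fmtNum(as.vector(t(gate@cov))),
                                         collapse = " "))
    xml2::xml_add_child(ex, "distSq", fmtNum(gate@distSq))
    return(el)
  }
  if (is(gate, "RectangleGate")) {
    el <- addGate("gating:RectangleGate")
    for (j in seq_along(gate@dims)) {
      cd <- codecFor(gate@dims[[j]])
      .writeDimEl(el, gate@dims[[j]],
                  min = if (is.na(gate@min[j])) NA else cd$out(gate@min[j]),
                  max = if (is.na(gate@max[j])) NA else cd$out(gate@max[j]),
                  writeTransformRef = writeTransformRef)
    }
  } else if (is(gate, "PolygonGate")) {
    el <- addGate("gating:PolygonGate")
    for (d in gate@dims)
      .writeDimEl(el, d, writeTransformRef = writeTransformRef)
    cdx <- codecFor(gate@dims[[1]]); cdy <- codecFor(gate@dims[[2]])
    vx <- cdx$out(gate@vertices[, 1]); vy <- cdy$out(gate@vertices[, 2])
    for (i in seq_len(nrow(gate@vertices))) {
      v <- xml2::xml_add_child(el, "gating:vertex")
      xml2::xml_add_child(v, "gating:coordinate",
                          "data-type:value" = fmtNum(vx[i]))
      xml2::xml_add_child(v, "gating:coordinate",
                          "data-type:value" = fmtNum(vy[i]))
    }
  } else if (is(gate, "EllipsoidGate")) {
    el <- addGate("gating:EllipsoidGate")
    for (d in gate@dims)
      .writeDimEl(el, d, writeTransformRef = writeTransformRef)
    mean <- xml2::xml_add_child(el, "gating:mean")
    for (m in gate@mu)
      xml2::xml_add_child(mean, "gating:coordinate",
                          "data-type:value" = fmtNum(m))
    cm <- xml2::xml_add_child(el, "gating:covarianceMatrix")
    for (i in seq_len(nrow(gate@cov))) {
      row <- xml2::xml_add_child(cm, "gating:row")
      for (j in seq_len(ncol(gate@cov)))
        xml2::xml_add_child(row, "gating:entry",
                            "data-type:value" = fmtNum(gate@cov[i, j]))
    }
    xml2::xml_add_child(el, "gating:distanceSquare",
                        "data-type:value" = fmtNum(gate@distSq))
  } else if (is(gate, "QuadrantGate")) {
    el <- addGate("gating:QuadrantGate")
    locs <- strsplit(gate@selector, "")[[1]]
    for (j in 1:2) {
      cd <- codecFor(gate@dims[[j]])
      dv <- xml2::xml_add_child(el, "gating:divider",
                                "gating:id" = paste0(id, "_d", j))
      compRef <- if (gate@dims[[j]]@compensationRef == "auto") "FCS"
                 else gate@dims[[j]]@compensationRef
      xml2::xml_set_attr(dv, "gating:compensation-ref", compRef)
      if (writeTransformRef && gate@dims[[j]]@transformRef != "identity")
        xml2::xml_set_attr(dv, "gating:transformation-ref",
                           gate@dims[[j]]@transformRef)
      xml2::xml_add_child(dv, "data-type:fcs-dimension",
                          "data-type:name" = gate@dims[[j]]@channel)
      xml2::xml_add_child(dv, "gating:value",
                          fmtNum(cd$out(gate@dividers[j])))
    }
    q <- xml2::xml_add_child(el, "gating:Quadrant",
                             "gating:id" = paste0(id, "_Q"))
    for (j in 1:2)
      xml2::xml_add_child(q, "gating:position",
                          "gating:divider_ref" = paste0(id, "_d", j),
                          "gating:location" = if (locs[j] == "+") "plus"
                                              else "minus")
  } else if (is(gate, "BooleanGate")) {
    el <- addGate("gating:BooleanGate")
    op <- xml2::xml_add_child(el, paste0("gating:", tolower(gate@operator)))
    for (o in gate@operands)
      xml2::xml_add_child(op, "gating:gateReference",
                          "gating:ref" = refOut(o))
  } else {
    cytoStop("UNSUPPORTED_EXPORT",
             paste0("gate class ", class(gate),
                    " cannot be serialized in this dialect"))
  }
  el
}

# refIn(refString) -> population path; transformForChannel(chan) -> ref
# (FlowJo-style per-channel transform lookup when dims carry no ref).
.readGateEl <- function(el, ns, codecFor = .identityCodec,
                        refIn = identity, transformForChannel = NULL) {
  type <- xml2::xml_name(el)
  readDims <- function() {
    lapply(xml2::xml_find_all(el, "./gating:dimension", ns),
           .readDimEl, ns = ns, transformForChannel = transformForChannel)
  }
  # an exact ellipsoid stored alongside a polygon/box export wins over
  # the approximate carrier geometry
  if (type %in% c("RectangleGate", "PolygonGate")) {
    ex <- xml2::xml_find_first(
      el, "./*[local-name()='custom_info']/*[local-name()='ellipsoid']")
    if (!inherits(ex, "xml_missing")) {
      dims <- lapply(readDims(), `[[`, "dim")
      getv <- function(tag) parseNum(strsplit(xml2::xml_text(
        xml2::xml_find_first(ex, paste0("./*[local-name()='", tag, "']"))),
        " ", fixed = TRUE)[[1]])
      mu <- getv("mean"); cv <- getv("cov"); d2 <- getv("distSq")
      k <- length(mu)
      return(ellipsoidGate(dims, mu, matrix(cv, k, k, byrow = TRUE), d2))
    }
  }
  if (type == "RectangleGate") {
    ds <- readDims()
    dims <- lapply(ds, `[[`, "dim")
    lo <- vapply(seq_along(ds), function(j) {
      cd <- codecFor(dims[[j]])
      if (is.na(ds[[j]]$min)) NA_real_ else cd$into(ds[[j]]$min)
    }, numeric(1))
    hi <- vapply(seq_along(ds), function(j) {
      cd <- codecFor(dims[[j]])
      if (is.na(ds[[j]]$max)) NA_real_ else cd$into(ds[[j]]$max)
    }, numeric(1))
    rectangleGate(dims, lo, hi)
  } else if (type == "PolygonGate") {
    dims <- lapply(readDims(), `[[`, "dim")
    verts <- do.call(rbind, lapply(
      xml2::xml_find_all(el, "./gating:vertex", ns), function(v)
        parseNum(xml2::xml_attr(
          xml2::xml_find_all(v, "./gating:coordinate", ns), "value"))))
    cdx <- codecFor(dims[[1]]); cdy <- codecFor(dims[[2]])
    polygonGate(dims, cbind(cdx$into(verts[, 1]), cdy$into(verts[, 2])))
  } else if (type == "EllipsoidGate") {
    dims <- lapply(readDims(), `[[`, "dim")
    mu <- parseNum(xml2::xml_attr(xml2::xml_find_all(
      el, "./gating:mean/gating:coordinate", ns), "value"))
    rows <- xml2::xml_find_all(el, "./gating:covarianceMatrix/gating:row", ns)
    C <- do.call(rbind, lapply(rows, function(r)
      parseNum(xml2::xml_attr(
        xml2::xml_find_all(r, "./gating:entry", ns), "value"))))
    d2 <- parseNum(xml2::xml_attr(xml2::xml_find_first(
      el, "./gating:distanceSquare", ns), "value"))
    ellipsoidGate(dims, mu, C, d2)
  } else if (type == "QuadrantGate") {
    dvs <- xml2::xml_find_all(el, "./gating:divider", ns)
    if (length(dvs) != 2L)
      cytoStop("UNSUPPORTED_GATE", "quadrant gate needs exactly 2 dividers")
    parsed <- lapply(dvs, function(dv) {
      d <- .readDimEl(dv, ns, transformForChannel)
      v <- parseNum(xml2::xml_text(
        xml2::xml_find_first(dv, "./gating:value", ns)))
      list(dim = d$dim, value = v, id = xml2::xml_attr(dv, "id"))
    })
    q <- xml2::xml_find_first(el, "./gating:Quadrant", ns)
    pos <- xml2::xml_find_all(q, "./gating:position", ns)
    loc <- setNames(xml2::xml_attr(pos, "location"),
                    xml2::xml_attr(pos, "divider_ref"))
    sel <- paste0(vapply(parsed, function(p)
      if (identical(loc[[p$id]], "plus")) "+" else "-", character(1)),
      collapse = "")
    dims <- lapply(parsed, `[[`, "dim")
    divs <- vapply(seq_len(2), function(j)
      codecFor(dims[[j]])$into(parsed[[j]]$value), numeric(1))
    quadrantGate(dims, divs, sel)
  } else if (type == "BooleanGate") {
    opEl <- xml2::xml_find_first(el, "./gating:and|./gating:or|./gating:not", ns)
    if (inherits(opEl, "xml_missing"))
      cytoStop("UNSUPPORTED_GATE", "boolean gate without and/or/not operator")
    refs <- xml2::xml_attr(xml2::xml_find_all(
      opEl, "./gating:gateReference", ns), "ref")
    booleanGate(toupper(xml2::xml_name(opEl)),
                vapply(refs, refIn, character(1), USE.NAMES = FALSE))
  } else {
    cytoStop("UNSUPPORTED_GATE",
             paste0("unsupported gate element '", type, "'"))
  }
}

.gateName <- function(el, fallback) {
  nm <- xml2::xml_text(xml2::xml_find_first(
    el, "./*[local-name()='custom_info']/*[local-name()='population_name']"))
  if (is.na(nm) || !nzchar(nm)) fallback else nm
}
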
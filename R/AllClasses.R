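#' @import methods
NULL

# ---- CytoSample -------------------------------------------------------

#' Container for the event-level data of one FCS file
#'
#' Holds the linearized event matrix (events x channels, stored as
#' double; FCS data type F is 32-bit float, promoted for computation),
#' the per-channel metadata ($PnN short name, $PnS marker, $PnR range)
#' and the raw TEXT-segment keyword map.
#'
#' @slot sampleId sample identifier (usually the FCS file name).
#' @slot exprs numeric matrix, one row per event, one column per channel.
#' @slot channels data.frame with columns `name`, `marker`, `range`.
#' @slot keywords named character vector of FCS TEXT keywords.
#' @export
setClass("CytoSample", representation(
  sampleId = "character", exprs = "matrix",
  channels = "data.frame", keywords = "character"
))

setValidity("CytoSample", function(object) {
  ch <- object@channels
  msgs <- character(0)
  if (length(object@sampleId) != 1L || !nzchar(object@sampleId))
    msgs <- c(msgs, "sampleId must be a single non-empty string")
  if (!all(c("name", "marker", "range") %in% names(ch)))
    msgs <- c(msgs, "channels needs columns name, marker, range")
  else {
    if (any(!nzchar(ch$name))) msgs <- c(msgs, "channel names must be non-empty")
    if (anyDuplicated(ch$name)) msgs <- c(msgs, "channel names must be unique")
    if (ncol(object@exprs) != nrow(ch))
      msgs <- c(msgs, "event matrix column count must equal channel count")
  }
  if (anyNA(object@exprs)) msgs <- c(msgs, "event matrix contains NA/NaN")
  if (length(msgs)) msgs else TRUE
})

#' Construct a CytoSample
#'
#' @param sampleId sample identifier.
#' @param exprs numeric event matrix (events x channels).
#' @param channels character vector of channel names, or a data.frame
#'   with columns `name`, `marker`, `range`.
#' @param markers optional marker labels (recycled empty).
#' @param range optional instrument ranges (default: per-column ceiling).
#' @param keywords named character vector of FCS keywords.
#' @return A [CytoSample-class] object.
#' @examples
#' s <- cytoSample("s1", matrix(rnorm(20), 10, 2), c("FL1-A", "FL2-A"))
#' nEvents(s)
#' @export
cytoSample <- function(sampleId, exprs, channels, markers = NULL,
                       range = NULL, keywords = character(0)) {
  exprs <- as.matrix(exprs)
  storage.mode(exprs) <- "double"
  if (!is.data.frame(channels)) {
    if (is.null(markers)) markers <- rep("", length(channels))
    if (is.null(range)) {
      range <- if (nrow(exprs))
        pmax(1, ceiling(apply(exprs, 2, max))) else rep(262144, length(channels))
    }
    channels <- data.frame(name = as.character(channels),
                           marker = as.character(markers),
                           range = as.numeric(range),
                           stringsAsFactors = FALSE)
  }
  colnames(exprs) <- channels$name
  kw <- as.character(keywords)
  names(kw) <- names(keywords)
  new("CytoSample", sampleId = sampleId, exprs = exprs,
      channels = channels, keywords = kw)
}

# ---- SpilloverMatrix --------------------------------------------------

#' Spillover (compensation) matrix
#'
#' Convention: rows are true signals, columns are detectors, so that
#' observed = true %*% S and compensation is a right-multiplication by
#' solve(S) over the detector columns. Diagonal is 1 after row
#' normalization.
#'
#' @slot detectors ordered detector channel names.
#' @slot S square spillover coefficient matrix, unit diagonal.
#' @export
setClass("SpilloverMatrix",
         representation(detectors = "character", S = "matrix"))

setValidity("SpilloverMatrix", function(object) {
  k <- length(object@detectors)
  msgs <- character(0)
  if (k < 1) msgs <- c(msgs, "at least one detector required")
  if (!all(dim(object@S) == c(k, k)))
    msgs <- c(msgs, "S must be k x k for k detectors")
  else if (max(abs(diag(object@S) - 1)) > 1e-12)
    msgs <- c(msgs, "S diagonal must be 1.0")
  if (length(msgs)) msgs else TRUE
})

#' @rdname SpilloverMatrix-class
#' @param detectors detector channel names.
#' @param S square coefficient matrix (rows: true signal; columns:
#'   detectors). Rows are rescaled so the diagonal is 1.
#' @return A [SpilloverMatrix-class] object.
#' @export
spilloverMatrix <- function(detectors, S) {
  S <- as.matrix(S)
  storage.mode(S) <- "double"
  d <- diag(S)
  if (any(d == 0)) cytoStop("MALFORMED_SPILLOVER", "zero on spillover diagonal")
  S <- S / d   # row scaling
  dimnames(S) <- list(detectors, detectors)
  new("SpilloverMatrix", detectors = as.character(detectors), S = S)
}

# ---- TransformDef -----------------------------------------------------

.transformFamilies <- c("linear", "log", "asinh", "logicle")

#' Parametric axis transform definition
#'
#' Families follow the Gating-ML 2.0 vocabulary: `linear` (flin), `log`
#' (flog), `asinh` (fasinh) and `logicle`. Parameters: `T` top of scale,
#' `M` display decades, `A` additional negative decades, and for logicle
#' `W` the linearization width in decades (0 <= W <= M/2).
#'
#' @slot transformId identifier used by gate dimension references.
#' @slot family one of linear, log, asinh, logicle.
#' @slot T,M,A,W numeric parameters (W is ignored outside logicle).
#' @export
setClass("TransformDef", representation(
  transformId = "character", family = "character",
  T = "numeric", M = "numeric", A = "numeric", W = "numeric"
))

setValidity("TransformDef", function(object) {
  msgs <- character(0)
  if (!object@family %in% .transformFamilies)
    msgs <- c(msgs, paste0("unknown family '", object@family, "'"))
  if (object@T <= 0) msgs <- c(msgs, "T must be > 0")
  if (object@M <= 0) msgs <- c(msgs, "M must be > 0")
  if (object@A < 0) msgs <- c(msgs, "A must be >= 0")
  if (object@family == "logicle") {
    if (object@W < 0 || object@W > object@M / 2)
      msgs <- c(msgs, "logicle requires 0 <= W <= M/2")
    if (object@A + object@W > object@M)
      msgs <- c(msgs, "logicle requires A + W <= M")
  }
  if (length(msgs)) msgs else TRUE
})

#' @rdname TransformDef-class
#' @param transformId transform identifier.
#' @param family transform family.
#' @param T top-of-scale value (> 0).
#' @param M display decades (> 0).
#' @param A additional negative display decades (>= 0).
#' @param W logicle linearization width in decades.
#' @return A [TransformDef-class] object.
#' @export
transformDef <- function(transformId, family, T = 262144, M = 4.5,
                         A = 0, W = 0.5) {
  # canonicalize parameters a family does not use, so definitions
  # compare equal after a serialization round-trip
  if (family %in% "linear") { M <- 4.5; W <- 0.5 }
  if (family %in% "log") { A <- 0; W <- 0.5 }
  if (family %in% "asinh") W <- 0.5
  obj <- tryCatch(
    new("TransformDef", transformId = transformId, family = family,
        T = as.numeric(T), M = as.numeric(M), A = as.numeric(A),
        W = as.numeric(W)),
    error = function(e) cytoStop("INVALID_TRANSFORM", conditionMessage(e)))
  obj
}

# ---- Gates ------------------------------------------------------------

#' Gate dimension: binds one axis of a gate to a channel, a transform
#' and a compensation context
#'
#' `transformRef` is a transform id or `"identity"`. `compensationRef`
#' is `"uncompensated"` (no compensation), a registered matrix id, or
#' `"auto"` (platform-determined: per-sample custom matrix, else the
#' FCS $SPILLOVER keyword, else identity).
#'
#' @slot channel channel name ($PnN).
#' @slot transformRef transform id or "identity".
#' @slot compensationRef "uncompensated", "auto" or a matrix id.
#' @export
setClass("GateDimension", representation(
  channel = "character", transformRef = "character",
  compensationRef = "character"
))

#' @rdname GateDimension-class
#' @param channel channel name.
#' @param transformRef transform id or "identity".
#' @param compensationRef compensation reference.
#' @return A [GateDimension-class] object.
#' @export
gateDimension <- function(channel, transformRef = "identity",
                          compensationRef = "uncompensated") {
  new("GateDimension", channel = channel, transformRef = transformRef,
      compensationRef = compensationRef)
}

#' Virtual parent class of all gate geometries
#' @export
setClass("Gate", representation("VIRTUAL", dims = "list"))

#' Axis-aligned (hyper)rectangle gate; NA bounds are unbounded sides
#' @slot min,max per-dimension bounds on the transformed scale.
#' @export
setClass("RectangleGate", contains = "Gate",
         representation(min = "numeric", max = "numeric"))

#' @rdname RectangleGate-class
#' @param dims list of [GateDimension-class].
#' @param min,max numeric bounds per dimension (NA = unbounded).
#' @return A [RectangleGate-class] object.
#' @export
rectangleGate <- function(dims, min, max) {
  d <- length(dims)
  min <- rep_len(as.numeric(min), d); max <- rep_len(as.numeric(max), d)
  if (any(is.na(min) & is.na(max)))
    cytoStop("INVALID_GATE", "rectangle gate needs at least one bound per dimension")
  new("RectangleGate", dims = dims, min = min, max = max)
}

#' Two-dimensional polygon gate (even-odd rule, boundary inclusive)
#' @slot vertices n x 2 matrix of vertex coordinates (transformed scale).
#' @export
setClass("PolygonGate", contains = "Gate",
         representation(vertices = "matrix"))

#' @rdname PolygonGate-class
#' @param dims list of exactly two [GateDimension-class].
#' @param vertices matrix of at least three (x, y) vertices.
#' @return A [PolygonGate-class] object.
#' @export
polygonGate <- function(dims, vertices) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (length(dims) != 2L) cytoStop("INVALID_GATE", "polygon gate needs exactly 2 dimensions")
  if (nrow(vertices) < 3L) cytoStop("INVALID_GATE", "polygon gate needs >= 3 vertices")
  # all vertices collinear as a set => degenerate region
  v <- sweep(vertices, 2, vertices[1L, ])
  nz <- which(rowSums(abs(v)) > 0)
  collinear <- if (!length(nz)) TRUE else {
    ref <- v[nz[1L], ]
    cross <- v[, 1] * ref[2] - v[, 2] * ref[1]
    all(abs(cross) <= 1e-12 * max(1, max(abs(v)))^2)
  }
  if (collinear) cytoStop("INVALID_GATE", "polygon vertices are collinear")
  new("PolygonGate", dims = dims, vertices = vertices)
}

#' Ellipsoid gate: (x - mu)' C^-1 (x - mu) <= D2
#' @slot mu center vector; @slot cov SPD shape matrix; @slot distSq
#'   squared Mahalanobis threshold.
#' @export
setClass("EllipsoidGate", contains = "Gate", representation(
  mu = "numeric", cov = "matrix", distSq = "numeric"
))

#' @rdname EllipsoidGate-class
#' @param dims list of >= 2 [GateDimension-class].
#' @param mu center vector.
#' @param cov symmetric positive-definite shape matrix.
#' @param distSq squared-distance threshold (> 0).
#' @return An [EllipsoidGate-class] object.
#' @export
ellipsoidGate <- function(dims, mu, cov, distSq) {
  cov <- as.matrix(cov); storage.mode(cov) <- "double"
  if (length(dims) < 2L) cytoStop("INVALID_GATE", "ellipsoid gate needs >= 2 dimensions")
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov))))
    cytoStop("INVALID_GATE", "ellipsoid shape matrix is not symmetric")
  if (inherits(try(chol(cov), silent = TRUE), "try-error"))
    cytoStop("INVALID_GATE", "ellipsoid shape matrix is not positive definite")
  if (distSq <= 0) cytoStop("INVALID_GATE", "distSq must be > 0")
  new("EllipsoidGate", dims = dims, mu = as.numeric(mu), cov = cov,
      distSq = as.numeric(distSq))
}

.quadrantSelectors <- c("++", "+-", "-+", "--")

#' Quadrant gate: one of the four divider-defined regions
#'
#' "+" means >= divider (ties go to the "+" side), "-" means < divider,
#' so the four selectors partition the plane exactly.
#' @slot dividers the (dx, dy) divider values; @slot selector one of
#'   "++", "+-", "-+", "--".
#' @export
setClass("QuadrantGate", contains = "Gate",
         representation(dividers = "numeric", selector = "character"))

#' @rdname QuadrantGate-class
#' @param dims list of exactly two [GateDimension-class].
#' @param dividers numeric length-2 divider values.
#' @param selector one of "++", "+-", "-+", "--".
#' @return A [QuadrantGate-class] object.
#' @export
quadrantGate <- function(dims, dividers, selector) {
  if (length(dims) != 2L) cytoStop("INVALID_GATE", "quadrant gate needs exactly 2 dimensions")
  if (!selector %in% .quadrantSelectors)
    cytoStop("INVALID_GATE", paste0("invalid quadrant selector '", selector, "'"))
  new("QuadrantGate", dims = dims, dividers = as.numeric(dividers),
      selector = selector)
}

#' Boolean combination gate over other populations
#' @slot operator one of AND, OR, NOT; @slot operands population paths.
#' @export
setClass("BooleanGate", contains = "Gate",
         representation(operator = "character", operands = "character"))

#' @rdname BooleanGate-class
#' @param operator "AND", "OR" or "NOT".
#' @param operands population paths (NOT takes exactly one).
#' @return A [BooleanGate-class] object.
#' @export
booleanGate <- function(operator, operands) {
  if (!operator %in% c("AND", "OR", "NOT"))
    cytoStop("INVALID_GATE", paste0("invalid boolean operator '", operator, "'"))
  if (operator == "NOT" && length(operands) != 1L)
    cytoStop("INVALID_GATE", "NOT takes exactly one operand")
  if (operator != "NOT" && length(operands) < 1L)
    cytoStop("INVALID_GATE", "boolean gate needs at least one operand")
  new("BooleanGate", dims = list(), operator = operator,
      operands = normPopPath(operands))
}

#' Index-defined (cluster) gate: membership by explicit event positions
#' within the parent population
#' @slot indices 1-based positions among the parent's member events.
#' @export
setClass("ClusterGate", contains = "Gate",
         representation(indices = "integer"))

#' @rdname ClusterGate-class
#' @param indices 1-based positions within the parent's events.
#' @return A [ClusterGate-class] object.
#' @export
clusterGate <- function(indices) {
  indices <- as.integer(indices)
  if (any(indices < 1L)) cytoStop("INVALID_GATE", "cluster indices must be >= 1")
  new("ClusterGate", dims = list(), indices = indices)
}

# ---- Gating tree ------------------------------------------------------

#' One named population in a gating tree
#' @slot name population name (unique among siblings).
#' @slot parentPath canonical path of the parent ("" for the root).
#' @slot gate the gate object, or NULL for the root.
#' @slot children canonical paths of child populations, in insertion order.
#' @export
setClass("PopulationNode", representation(
  name = "character", parentPath = "character",
  gate = "ANY", children = "character"
))

#' Rooted hierarchy of gated populations
#'
#' Paths are "/"-separated names rooted at the reserved node `"root"`
#' (all events, no gate); e.g. `"root/lymph/CD3"`. Each node's
#' membership is its parent's membership AND its gate predicate.
#'
#' @slot nodes named list of [PopulationNode-class], keyed by path.
#' @export
setClass("GatingTree", representation(nodes = "list"))

#' @rdname GatingTree-class
#' @return An empty [GatingTree-class] (root only).
#' @export
gatingTree <- function() {
  root <- new("PopulationNode", name = "root", parentPath = "",
              gate = NULL, children = character(0))
  new("GatingTree", nodes = list(root = root))
}

#' Add a population under a parent
#'
#' @param tree a [GatingTree-class].
#' @param parentPath path of the parent population.
#' @param name new population name (no "/"; unique among siblings).
#' @param gate a [Gate-class] object.
#' @return The modified tree.
#' @examples
#' tr <- gatingTree()
#' g <- rectangleGate(list(gateDimension("FSC-A")), 0, 100)
#' tr <- addPopulation(tr, "root", "cells", g)
#' populationPaths(tr)
#' @export
addPopulation <- function(tree, parentPath, name, gate) {
  parentPath <- normPopPath(parentPath)
  if (is.null(tree@nodes[[parentPath]]))
    cytoStop("UNKNOWN_POPULATION", paste0("no population at '", parentPath, "'"))
  if (grepl("/", name, fixed = TRUE) || !nzchar(name))
    cytoStop("INVALID_GATE", "population names must be non-empty and contain no '/'")
  path <- paste0(parentPath, "/", name)
  if (!is.null(tree@nodes[[path]]))
    cytoStop("DUPLICATE_POPULATION",
             paste0("duplicate sibling name at '", path, "'"))
  tree@nodes[[path]] <- new("PopulationNode", name = name,
                            parentPath = parentPath, gate = gate,
                            children = character(0))
  tree@nodes[[parentPath]]@children <-
    c(tree@nodes[[parentPath]]@children, path)
  # canonical storage order (traversal order is kept by the children
  # vectors), so trees built in different insertion orders compare equal
  tree@nodes <- tree@nodes[order(names(tree@nodes))]
  tree
}

#' Resolve a population path to its node
#' @param tree a [GatingTree-class].
#' @param path population path.
#' @return The [PopulationNode-class] at `path`.
#' @export
getNode <- function(tree, path) {
  path <- normPopPath(path)
  n <- tree@nodes[[path]]
  if (is.null(n))
    cytoStop("UNKNOWN_POPULATION", paste0("no population at '", path, "'"))
  n
}

#' All population paths in deterministic pre-order
#' @param tree a [GatingTree-class].
#' @return Character vector of canonical paths, root first.
#' @export
populationPaths <- function(tree) {
  out <- character(0)
  rec <- function(path) {
    out[[length(out) + 1L]] <<- path
    for (ch in tree@nodes[[path]]@children) rec(ch)
  }
  rec("root")
  out
}

# ---- Workspace --------------------------------------------------------

.dialects <- c("gatingml", "flowjo", "cytobank")

#' The interchange hub: samples, gating trees, transform and
#' compensation registries, and the source dialect
#'
#' `trees` maps sample ids to per-sample [GatingTree-class] objects; a
#' workspace may instead (or additionally) carry one shared `template`
#' tree which is instantiated per sample at resolve time, so per-sample
#' modifications never mutate the template.
#'
#' @slot samples named list of [CytoSample-class] (by sample id).
#' @slot trees named list of per-sample [GatingTree-class].
#' @slot template shared template [GatingTree-class] or NULL.
#' @slot transforms named list of [TransformDef-class] (by transform id).
#' @slot compensations named list of [SpilloverMatrix-class] (by id; an
#'   id equal to a sample id is that sample's custom matrix).
#' @slot dialect source dialect: "gatingml", "flowjo" or "cytobank".
#' @export
setClass("Workspace", representation(
  samples = "list", trees = "list", template = "ANY",
  transforms = "list", compensations = "list", dialect = "character"
))

#' @rdname Workspace-class
#' @param samples named list of [CytoSample-class] (names default to
#'   their sample ids).
#' @param trees named list of per-sample trees.
#' @param template shared template tree or NULL.
#' @param transforms named list of [TransformDef-class].
#' @param compensations named list of [SpilloverMatrix-class].
#' @param dialect source dialect tag.
#' @return A [Workspace-class] object.
#' @export
workspace <- function(samples = list(), trees = list(), template = NULL,
                      transforms = list(), compensations = list(),
                      dialect = "gatingml") {
  if (length(samples) && is.null(names(samples)))
    names(samples) <- vapply(samples, function(s) s@sampleId, character(1))
  if (!is.null(template) && !is(template, "GatingTree"))
    cytoStop("INVALID_WORKSPACE", "template must be a GatingTree or NULL")
  new("Workspace", samples = samples, trees = trees, template = template,
      transforms = transforms, compensations = compensations,
      dialect = dialect)
}

# ---- basic accessors --------------------------------------------------

#' @rdname CytoSample-class
#' @param object,x a [CytoSample-class].
#' @export
setGeneric("nEvents", function(object) standardGeneric("nEvents"))
#' @rdname CytoSample-class
#' @export
setMethod("nEvents", "CytoSample", function(object) nrow(object@exprs))

#' @rdname CytoSample-class
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname CytoSample-class
#' @export
setMethod("channelNames", "CytoSample", function(object) object@channels$name)

#' @rdname CytoSample-class
#' @export
setGeneric("markerNames", function(object) standardGeneric("markerNames"))
#' @rdname CytoSample-class
#' @export
setMethod("markerNames", "CytoSample", function(object) object@channels$marker)

#' @rdname CytoSample-class
#' @export
setGeneric("eventMatrix", function(object) standardGeneric("eventMatrix"))
#' @rdname CytoSample-class
#' @export
setMethod("eventMatrix", "CytoSample", function(object) object@exprs)

#' @rdname CytoSample-class
#' @export
setGeneric("keywords", function(object) standardGeneric("keywords"))
#' @rdname CytoSample-class
#' @export
setMethod("keywords", "CytoSample", function(object) object@keywords)

#' @rdname CytoSample-class
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))
#' @rdname CytoSample-class
#' @export
setMethod("sampleId", "CytoSample", function(object) object@sampleId)

#' @rdname Workspace-class
#' @param object,ws a [Workspace-class].
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))
#' @rdname Workspace-class
#' @export
setMethod("sampleIds", "Workspace", function(object) names(object@samples))

#' @rdname Workspace-class
#' @export
setGeneric("dialect", function(object) standardGeneric("dialect"))
#' @rdname Workspace-class
#' @export
setMethod("dialect", "Workspace", function(object) object@dialect)

#' Retrieve (or instantiate from the template) the gating tree of a sample
#'
#' Per-sample trees take precedence; otherwise the shared template is
#' copied (R value semantics make the copy implicit), so modifications
#' to the returned tree never mutate the template.
#'
#' @param ws a [Workspace-class].
#' @param sid sample id.
#' @return A [GatingTree-class].
#' @export
gatingTreeFor <- function(ws, sid) {
  if (!is.null(ws@trees[[sid]])) return(ws@trees[[sid]])
  if (!is.null(ws@template)) return(ws@template)
  cytoStop("UNKNOWN_POPULATION", paste0("no gating tree for sample '", sid, "'"))
}

#' Replace the samples of a workspace (e.g. after reading a sample-free
#' Gating-ML file)
#' @param ws a [Workspace-class].
#' @param samples named list of [CytoSample-class].
#' @return The modified workspace.
#' @export
setSamples <- function(ws, samples) {
  if (is.null(names(samples)))
    names(samples) <- vapply(samples, function(s) s@sampleId, character(1))
  ws@samples <- samples
  ws
}

# ---- show methods -----------------------------------------------------

setMethod("show", "CytoSample", function(object) {
  cat("CytoSample '", object@sampleId, "': ", nrow(object@exprs),
      " events x ", ncol(object@exprs), " channels\n", sep = "")
  cat("  channels:", paste(object@channels$name, collapse = ", "), "\n")
})

setMethod("show", "GatingTree", function(object) {
  paths <- populationPaths(object)
  cat("GatingTree with", length(paths), "populations\n")
  for (p in paths) {
    depth <- lengths(regmatches(p, gregexpr("/", p, fixed = TRUE)))
    cat(strrep("  ", depth), popName(p), "\n", sep = "")
  }
})

setMethod("show", "Workspace", function(object) {
  cat("Workspace [", object@dialect, " dialect]: ",
      length(object@samples), " sample(s), ",
      length(object@transforms), " transform(s), ",
      length(object@compensations), " compensation(s)\n", sep = "")
  if (!is.null(object@template))
    cat("  shared template tree with",
        length(populationPaths(object@template)), "populations\n")
})

setMethod("show", "TransformDef", function(object) {
  cat("TransformDef '", object@transformId, "' [", object@family,
      "] T=", object@T, " M=", object@M, " A=", object@A,
      if (object@family == "logicle") paste0(" W=", object@W), "\n", sep = "")
})

setMethod("show", "SpilloverMatrix", function(object) {
  cat("SpilloverMatrix over", length(object@detectors), "detectors:",
      paste(object@detectors, collapse = ", "), "\n")
  print(round(object@S, 4))
})
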
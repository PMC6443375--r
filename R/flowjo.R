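# FlowJo-dialect workspace (.wsp, v10 SampleList layout). The dialect
# stores gate coordinates on the RAW scale and declares transforms per
# channel (not per gate), so the writer inverse-transforms internal
# coordinates and the reader converts them back using each sample's
# declared transforms. Per-sample custom spillover matrices are part
# of the sample subtree and auto-selected on import. This is the one
# dialect that can serialize index-defined (cluster) populations, as
# enumerated derived populations.

# transform codec for one gate dimension: out = to serialized (raw)
# scale, into = back to the internal transformed scale
.rawCodecFactory <- function(ws) {
  function(dim) {
    if (dim@transformRef == "identity") return(list(out = identity,
                                                    into = identity))
    def <- ws@transforms[[dim@transformRef]]
    if (is.null(def))
      cytoStop("UNRESOLVED_TRANSFORM", paste0(
        "no transform registered as '", dim@transformRef, "'"))
    tf <- makeTransform(def)
    list(out = tf$inverse, into = tf$forward)
  }
}

# apply f to every gate dimension of every gate in a tree
.mapGateDims <- function(tree, f) {
  for (p in setdiff(populationPaths(tree), "root")) {
    g <- tree@nodes[[p]]@gate
    if (is.null(g) || !length(g@dims)) next
    g@dims <- lapply(g@dims, f)
    tree@nodes[[p]]@gate <- g
  }
  tree
}

# per-channel transform/compensation usage of one tree; the wsp layout
# cannot express per-gate conflicts, so they are export errors.
.flowjoUsage <- function(tree, ws) {
  chanTf <- list()
  compIds <- character(0)
  for (p in setdiff(populationPaths(tree), "root")) {
    g <- tree@nodes[[p]]@gate
    if (is.null(g) || is(g, "BooleanGate") || is(g, "ClusterGate")) next
    for (d in g@dims) {
      prev <- chanTf[[d@channel]]
      if (is.null(prev)) chanTf[[d@channel]] <- d@transformRef
      else if (!identical(prev, d@transformRef))
        cytoStop("UNSUPPORTED_EXPORT", paste0(
          "flowjo dialect declares one transform per channel; channel '",
          d@channel, "' is gated under both '", prev, "' and '",
          d@transformRef, "'"))
      if (!d@compensationRef %in% c("uncompensated", "auto"))
        compIds <- union(compIds, d@compensationRef)
    }
  }
  if (length(compIds) > 1L)
    cytoStop("UNSUPPORTED_EXPORT", paste0(
      "flowjo dialect carries a single per-sample compensation matrix; ",
      "gates reference: ", paste(compIds, collapse = ", ")))
  list(chanTf = chanTf,
       compId = if (length(compIds)) compIds else NA_character_)
}

#' Write a workspace as a FlowJo-dialect .wsp file
#'
#' Emits the v10 SampleList layout with per-sample gating trees,
#' population counts, per-channel transform declarations and (when
#' used) a per-sample spillover matrix. Gate coordinates are written on
#' the raw scale (inverse-transformed); ellipsoid gates are written as
#' 100-vertex polygons with the exact quadratic form kept in the gate's
#' custom information. Index-defined cluster populations are exported
#' as enumerated derived populations — the one dialect where this is
#' supported.
#'
#' @param ws a validating [Workspace-class] with at least one sample.
#' @param path output .wsp path.
#' @return `path`, invisibly.
#' @export
writeFlowjo <- function(ws, path) {
  .checkWritable(ws, "flowjo")
  if (!length(ws@samples))
    cytoStop("UNSUPPORTED_EXPORT",
             "flowjo export requires samples (the wsp layout is sample-centric)")
  codecFor <- .rawCodecFactory(ws)
  doc <- xml2::xml_new_root("Workspace", version = "20.0",
                            flowJoVersion = "10.8.0")
  for (a in names(.nsDecls())) xml2::xml_set_attr(doc, a, .nsDecls()[[a]])
  slist <- xml2::xml_add_child(doc, "SampleList")
  for (si in seq_along(ws@samples)) {
    sample <- ws@samples[[si]]
    sid <- sample@sampleId
    tree <- gatingTreeFor(ws, sid)
    usage <- .flowjoUsage(tree, ws)
    resolved <- resolveGating(ws, sid)
    counts <- vapply(populationPaths(tree),
                     function(p) sum(resolved[[p]]), integer(1))

    sEl <- xml2::xml_add_child(slist, "Sample")
    xml2::xml_add_child(sEl, "DataSet", uri = paste0("file:", sid),
                        sampleID = as.character(si))
    kws <- xml2::xml_add_child(sEl, "Keywords")
    xml2::xml_add_child(kws, "Keyword", name = "$FIL", value = sid)
    tEl <- xml2::xml_add_child(sEl, "Transformations")
    for (chan in names(usage$chanTf)) {
      ref <- usage$chanTf[[chan]]
      if (ref != "identity")
        .writeTransformEl(tEl, ws@transforms[[ref]], channel = chan)
    }
    compMatrix <- if (!is.na(usage$compId)) ws@compensations[[usage$compId]]
                  else ws@compensations[[sid]]
    if (!is.null(compMatrix)) .writeSpillEl(sEl, sid, compMatrix)
    # explicit matrix references become the per-sample matrix above,
    # auto-selected on re-import
    tree <- .mapGateDims(tree, function(d) {
      if (!d@compensationRef %in% c("uncompensated", "auto"))
        d@compensationRef <- "auto"
      d
    })

    node <- xml2::xml_add_child(sEl, "SampleNode", name = sid,
                                count = as.character(nEvents(sample)))
    writePops <- function(container, path) {
      kids <- tree@nodes[[path]]@children
      if (!length(kids)) return(invisible(NULL))
      subs <- xml2::xml_add_child(container, "Subpopulations")
      for (kp in kids) {
        kn <- tree@nodes[[kp]]
        if (is(kn@gate, "ClusterGate")) {
          xml2::xml_add_child(subs, "DerivedPopulation", name = kn@name,
                              count = as.character(counts[[kp]]),
                              indices = paste(kn@gate@indices,
                                              collapse = ","))
          next
        }
        pop <- xml2::xml_add_child(subs, "Population", name = kn@name,
                                   count = as.character(counts[[kp]]))
        gEl <- xml2::xml_add_child(pop, "Gate")
        .writeGateEl(gEl, kn@gate, paste0("s", si, "_", kn@name),
                     NA_character_, kn@name, codecFor = codecFor,
                     refOut = identity, writeTransformRef = FALSE,
                     nativeEllipse = FALSE)
        writePops(pop, kp)
      }
    }
    writePops(node, "root")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

# Locate a sample's FCS file: $FIL keyword match by name, then the
# DataSet URI basename, then a scan of the directory's FCS files for a
# matching $FIL keyword. Ambiguity is an error, never a guess.
.locateFcs <- function(fcsDir, fil, uri) {
  tried <- character(0)
  if (!is.na(fil) && nzchar(fil)) {
    p <- file.path(fcsDir, fil)
    tried <- c(tried, p)
    if (file.exists(p)) return(p)
  }
  if (!is.na(uri) && nzchar(uri)) {
    p <- file.path(fcsDir, basename(sub("^file:(//)?", "", uri)))
    tried <- c(tried, p)
    if (file.exists(p)) return(p)
  }
  all <- list.files(fcsDir, pattern = "\\.fcs$", ignore.case = TRUE,
                    full.names = TRUE)
  if (!is.na(fil) && nzchar(fil) && length(all)) {
    hits <- all[vapply(all, function(f) {
      s <- try(suppressMessages(readFCS(f)), silent = TRUE)
      !inherits(s, "try-error") && identical(s@sampleId, fil)
    }, logical(1))]
    if (length(hits) == 1L) return(hits)
    if (length(hits) > 1L)
      cytoStop("MISSING_FILE", paste0(
        "ambiguous FCS match for $FIL '", fil, "': ",
        paste(basename(hits), collapse = ", ")))
  }
  cytoStop("MISSING_FILE", paste0(
    "FCS file not found for sample '", fil, "'; candidates tried: ",
    paste(c(tried, basename(all)), collapse = ", ")))
}

#' Read a FlowJo-dialect .wsp workspace together with its FCS files
#'
#' Builds per-sample gating trees. Raw-scale gate coordinates are
#' converted to the transformed scale using the sample's declared
#' per-channel transforms (logged at INFO); a per-sample spillover
#' matrix, when present, is registered under the sample id and
#' auto-selected over the FCS $SPILLOVER keyword. Import never exposes
#' knobs to override matrices or transforms: modifications are explicit
#' post-import edits.
#'
#' @param path .wsp file.
#' @param fcsDir directory containing the sample FCS files.
#' @return A [Workspace-class] with dialect `"flowjo"`.
#' @export
readFlowjo <- function(path, fcsDir) {
  if (!file.exists(path))
    cytoStop("MISSING_FILE", paste0("no such file: ", path))
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)
  ws <- workspace(dialect = "flowjo")
  samples <- list(); trees <- list()
  transforms <- list(); comps <- list()

  for (sEl in xml2::xml_find_all(doc, "./SampleList/Sample")) {
    kwEls <- xml2::xml_find_all(sEl, "./Keywords/Keyword")
    kwmap <- setNames(xml2::xml_attr(kwEls, "value"),
                      xml2::xml_attr(kwEls, "name"))
    fil <- if ("$FIL" %in% names(kwmap)) kwmap[["$FIL"]] else NA_character_
    uri <- xml2::xml_attr(xml2::xml_find_first(sEl, "./DataSet"), "uri")
    fcsPath <- .locateFcs(fcsDir, fil, uri)
    sample <- readFCS(fcsPath)
    sid <- sample@sampleId

    chanTf <- list()
    for (trEl in xml2::xml_find_all(
           sEl, "./Transformations/transforms:transformation", ns)) {
      fn <- xml2::xml_find_first(trEl, "./transforms:*", ns)
      chan <- xml2::xml_attr(
        xml2::xml_find_first(fn, "./data-type:parameter", ns), "name")
      tid <- xml2::xml_attr(trEl, "id")
      if (is.na(tid)) tid <- paste0("tf_", chan)
      def <- .parseTransformFn(fn, tid)
      transforms[[tid]] <- def
      chanTf[[chan]] <- tid
      cytoLog("INFO", "sample '", sid, "': channel '", chan,
              "' uses ", def@family, " transform '", tid, "'")
    }
    spills <- .readSpillEls(sEl, ns)
    if (length(spills)) {
      comps[[sid]] <- spills[[1]]
      cytoLog("INFO", "sample '", sid,
              "': per-sample custom compensation matrix registered")
    }
    tfFor <- function(chan) {
      r <- chanTf[[chan]]
      if (is.null(r)) "identity" else r
    }
    wsLocal <- workspace(transforms = transforms, dialect = "flowjo")
    codecFor <- .rawCodecFactory(wsLocal)

    tree <- gatingTree()
    readPops <- function(container, parentPath) {
      subs <- xml2::xml_find_first(container, "./Subpopulations")
      if (inherits(subs, "xml_missing")) return(invisible(NULL))
      for (popEl in xml2::xml_find_all(
             subs, "./Population|./DerivedPopulation")) {
        nm <- xml2::xml_attr(popEl, "name")
        if (xml2::xml_name(popEl) == "DerivedPopulation") {
          idx <- xml2::xml_attr(popEl, "indices")
          idx <- if (is.na(idx) || !nzchar(idx)) integer(0)
                 else as.integer(strsplit(idx, ",", fixed = TRUE)[[1]])
          tree <<- addPopulation(tree, parentPath, nm, clusterGate(idx))
          next
        }
        gEl <- xml2::xml_find_first(popEl, "./Gate/gating:*", ns)
        if (inherits(gEl, "xml_missing"))
          cytoStop("UNSUPPORTED_GATE",
                   paste0("population '", nm, "' has no gate element"))
        gate <- .readGateEl(gEl, ns, codecFor = codecFor,
                            refIn = normPopPath,
                            transformForChannel = tfFor)
        tree <<- addPopulation(tree, parentPath, nm, gate)
        readPops(popEl, paste0(parentPath, "/", nm))
      }
    }
    sn <- xml2::xml_find_first(sEl, "./SampleNode")
    if (!inherits(sn, "xml_missing")) readPops(sn, "root")
    samples[[sid]] <- sample
    trees[[sid]] <- tree
  }
  workspace(samples = samples, trees = trees, transforms = transforms,
            compensations = comps, dialect = "flowjo")
}
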
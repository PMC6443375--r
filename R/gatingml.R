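# Gating-ML 2.0 dialect: a single shared gating hierarchy with
# transform and spillover registries; no event data and no
# index-defined (cluster) populations (the standard has no vocabulary
# for them).

#' Dialect capability matrix
#'
#' Explicit data consulted by the writers; exporting a feature a
#' dialect cannot represent fails loudly rather than silently dropping
#' it.
#'
#' @param dialect one of "gatingml", "flowjo", "cytobank".
#' @return List with fields `clusters` (index-defined populations
#'   serializable), `nativeEllipse`, `coordinateScale` ("transformed"
#'   or "raw"), `perSampleTrees`, `perGateCompensation`.
#' @export
dialectCapabilities <- function(dialect) {
  switch(dialect,
    gatingml = list(clusters = FALSE, nativeEllipse = TRUE,
                    coordinateScale = "transformed",
                    perSampleTrees = FALSE, perGateCompensation = TRUE),
    flowjo = list(clusters = TRUE, nativeEllipse = FALSE,
                  coordinateScale = "raw",
                  perSampleTrees = TRUE, perGateCompensation = FALSE),
    cytobank = list(clusters = FALSE, nativeEllipse = TRUE,
                    coordinateScale = "transformed",
                    perSampleTrees = TRUE, perGateCompensation = TRUE),
    cytoStop("USAGE", paste0("unknown dialect '", dialect,
                             "' (supported: gatingml, flowjo, cytobank)")))
}

.treeHasClusters <- function(tree) {
  any(vapply(populationPaths(tree), function(p) {
    g <- tree@nodes[[p]]@gate
    !is.null(g) && is(g, "ClusterGate")
  }, logical(1)))
}

.wsHasClusters <- function(ws) {
  trees <- c(if (!is.null(ws@template)) list(ws@template), ws@trees)
  any(vapply(trees, .treeHasClusters, logical(1)))
}

# The single exportable tree of a workspace for template-only dialects.
.exportTemplateTree <- function(ws) {
  if (!is.null(ws@template)) return(ws@template)
  if (length(ws@trees) == 1L) return(ws@trees[[1]])
  if (length(ws@trees) > 1L) {
    first <- ws@trees[[1]]
    same <- all(vapply(ws@trees[-1], function(tr)
      isTRUE(all.equal(tr, first)), logical(1)))
    if (same) return(first)
    cytoStop("UNSUPPORTED_EXPORT",
             "dialect cannot scope differing per-sample trees; export per sample or use the cytobank dialect")
  }
  cytoStop("INVALID_WORKSPACE", "workspace has no gating tree")
}

.checkWritable <- function(ws, dialect) {
  viol <- validateWorkspace(ws)
  if (length(viol))
    cytoStop("INVALID_WORKSPACE", paste0(
      "workspace does not validate: ", paste(viol, collapse = " | ")))
  caps <- dialectCapabilities(dialect)
  if (!caps$clusters && .wsHasClusters(ws))
    cytoStop("UNSUPPORTED_EXPORT", paste0(
      "index-defined (cluster) populations cannot be exported to the ",
      dialect, " dialect; use the flowjo dialect"))
  caps
}

# Serialize one tree's gates under an XML container. Ids are assigned
# "<prefix>pop_<i>" in pre-order; boolean operand paths become ids.
.writeTreeGates <- function(container, tree, prefix = "",
                            codecFor = .identityCodec,
                            nativeEllipse = TRUE,
                            writeTransformRef = TRUE,
                            perGateInfo = NULL) {
  paths <- populationPaths(tree)
  ids <- setNames(paste0(prefix, "pop_", seq_along(paths)), paths)
  for (p in setdiff(paths, "root")) {
    node <- tree@nodes[[p]]
    parentId <- if (node@parentPath == "root") NA_character_
                else ids[[node@parentPath]]
    el <- .writeGateEl(container, node@gate, ids[[p]], parentId,
                       node@name, codecFor = codecFor,
                       refOut = function(path) ids[[path]],
                       writeTransformRef = writeTransformRef,
                       nativeEllipse = nativeEllipse)
    if (!is.null(perGateInfo)) perGateInfo(el, p)
  }
  invisible(ids)
}

# Rebuild a tree from parsed gate elements: first pass fixes the
# hierarchy (parent ids), second pass materializes gates with boolean
# references translated from gate ids to population paths.
.assembleTree <- function(gateEls, ns, codecFor = .identityCodec,
                          transformForChannel = NULL) {
  recs <- list()
  idOrder <- character(0)
  for (el in gateEls) {
    id <- xml2::xml_attr(el, "id")
    if (is.na(id)) id <- paste0("anon_", length(recs) + 1L)
    recs[[id]] <- list(el = el, parent = xml2::xml_attr(el, "parent_id"),
                       name = .gateName(el, id))
    idOrder <- c(idOrder, id)
  }
  pathOf <- list()
  resolvePath <- function(id, seen = character(0)) {
    if (!is.null(pathOf[[id]])) return(pathOf[[id]])
    if (id %in% seen)
      cytoStop("CYCLE", paste0("gate parent cycle at '", id, "'"))
    r <- recs[[id]]
    if (is.null(r))
      cytoStop("DANGLING_REFERENCE",
               paste0("gate references unknown parent id '", id, "'"))
    parentPath <- if (is.na(r$parent)) "root"
                  else resolvePath(r$parent, c(seen, id))
    p <- paste0(parentPath, "/", r$name)
    pathOf[[id]] <<- p
    p
  }
  for (id in idOrder) resolvePath(id)
  tree <- gatingTree()
  # parents precede children when added in path-length order
  byDepth <- idOrder[order(nchar(unlist(pathOf[idOrder])))]
  for (id in byDepth) {
    gate <- .readGateEl(recs[[id]]$el, ns, codecFor = codecFor,
                        refIn = function(ref) {
                          p <- pathOf[[ref]]
                          if (is.null(p))
                            cytoStop("DANGLING_REFERENCE", paste0(
                              "boolean gate references unknown gate id '",
                              ref, "'"))
                          p
                        },
                        transformForChannel = transformForChannel)
    tree <- addPopulation(tree, popParentPath(pathOf[[id]]),
                          recs[[id]]$name, gate)
  }
  tree
}

#' Write a workspace as Gating-ML 2.0 XML
#'
#' Gates, the shared hierarchy, transform definitions and spillover
#' matrices are serialized in the Gating-ML 2.0 namespaces with
#' 17-significant-digit numerics (re-parsed parameters are
#' bit-identical). Event data are not part of the format. Workspaces
#' containing index-defined (cluster) populations are rejected.
#'
#' @param ws a validating [Workspace-class].
#' @param path output XML path.
#' @return `path`, invisibly.
#' @export
writeGatingML <- function(ws, path) {
  .checkWritable(ws, "gatingml")
  tree <- .exportTemplateTree(ws)
  doc <- xml2::xml_new_root("gating:Gating-ML")
  for (a in names(.nsDecls())) xml2::xml_set_attr(doc, a, .nsDecls()[[a]])
  for (def in ws@transforms) .writeTransformEl(doc, def)
  for (id in names(ws@compensations))
    .writeSpillEl(doc, id, ws@compensations[[id]])
  .writeTreeGates(doc, tree)
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a Gating-ML 2.0 file
#'
#' Produces a partial workspace: the shared gating tree (orphan gates
#' attach to root), transform registry and compensation registry, but
#' no samples — attach those with [setSamples()].
#'
#' @param path Gating-ML 2.0 XML file.
#' @return A [Workspace-class] with dialect `"gatingml"`.
#' @export
readGatingML <- function(path) {
  if (!file.exists(path))
    cytoStop("MISSING_FILE", paste0("no such file: ", path))
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)
  if (!.NS_GATING %in% ns)
    cytoStop("MALFORMED_FILE",
             "document is not in the Gating-ML 2.0 namespace")
  transforms <- .readTransformEls(doc, ns)
  comps <- .readSpillEls(doc, ns)
  gateEls <- xml2::xml_find_all(doc, "./gating:*", ns)
  tree <- .assembleTree(gateEls, ns)
  workspace(template = tree, transforms = transforms,
            compensations = comps, dialect = "gatingml")
}
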
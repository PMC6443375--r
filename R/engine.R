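# The gating engine: resolves a gating tree against a sample, exposing
# per-event population memberships, cell-level data access, population
# statistics, cluster attachment and F-measure comparison.

#' Validate a workspace
#'
#' Checks all structural invariants (resolvable transform and
#' compensation references, tree consistency, sample/tree key
#' agreement) and returns diagnostics rather than raising.
#'
#' @param ws a [Workspace-class].
#' @return Character vector of violation descriptions; empty iff the
#'   workspace is well formed.
#' @export
validateWorkspace <- function(ws) {
  out <- character(0)
  if (!ws@dialect %in% .dialects)
    out <- c(out, paste0("unknown dialect '", ws@dialect, "'"))
  for (sid in names(ws@trees))
    if (is.null(ws@samples[[sid]]) && length(ws@samples))
      out <- c(out, paste0("tree keyed by unknown sample '", sid, "'"))
  for (s in ws@samples) {
    v <- validObject(s, test = TRUE)
    if (!isTRUE(v))
      out <- c(out, paste0("sample '", s@sampleId, "': ",
                           paste(v, collapse = "; ")))
  }
  checkTree <- function(tree, label) {
    paths <- try(populationPaths(tree), silent = TRUE)
    if (inherits(paths, "try-error")) {
      out <<- c(out, paste0(label, ": tree traversal failed (cycle?)"))
      return(invisible(NULL))
    }
    for (p in paths) {
      node <- tree@nodes[[p]]
      kids <- popName(node@children)
      if (anyDuplicated(kids))
        out <<- c(out, paste0(label, ": duplicate sibling name under '",
                              p, "': ", kids[duplicated(kids)][1]))
      g <- node@gate
      if (is.null(g)) next
      for (dm in g@dims) {
        if (!dm@transformRef %in% c("identity", names(ws@transforms)))
          out <<- c(out, paste0(label, " '", p,
                                "': unresolved transform ref '",
                                dm@transformRef, "'"))
        if (!dm@compensationRef %in%
              c("uncompensated", "auto", names(ws@compensations)))
          out <<- c(out, paste0(label, " '", p,
                                "': unresolved compensation ref '",
                                dm@compensationRef, "'"))
      }
      if (is(g, "BooleanGate"))
        for (op in g@operands)
          if (is.null(tree@nodes[[op]]))
            out <<- c(out, paste0(label, " '", p,
                                  "': boolean operand '", op,
                                  "' does not exist"))
    }
  }
  if (!is.null(ws@template)) checkTree(ws@template, "template")
  for (sid in names(ws@trees)) checkTree(ws@trees[[sid]], paste0("tree[", sid, "]"))
  for (tid in names(ws@transforms)) {
    v <- validObject(ws@transforms[[tid]], test = TRUE)
    if (!isTRUE(v))
      out <- c(out, paste0("transform '", tid, "': ", paste(v, collapse = "; ")))
  }
  out
}

# Prepared channel views: compensation selected per dimension reference,
# then the per-dimension transform, cached within one resolve call.
.makeChannelPrep <- function(sample, ws) {
  compCache <- list()
  colCache <- list()
  chans <- channelNames(sample)
  compensated <- function(compRef) {
    key <- compRef
    if (is.null(compCache[[key]])) {
      sm <- selectCompensation(sample, ws, compRef)
      compCache[[key]] <<- if (isIdentitySpillover(sm)) sample@exprs
                           else compensate(sample@exprs, sm, chans)
    }
    compCache[[key]]
  }
  function(dim) {
    if (!dim@channel %in% chans)
      cytoStop("UNRESOLVED_CHANNEL",
               paste0("channel '", dim@channel, "' not in sample '",
                      sample@sampleId, "'"))
    key <- paste(dim@compensationRef, dim@transformRef, dim@channel,
                 sep = "\r")
    if (is.null(colCache[[key]])) {
      x <- compensated(dim@compensationRef)[, dim@channel]
      if (dim@transformRef != "identity") {
        def <- ws@transforms[[dim@transformRef]]
        if (is.null(def))
          cytoStop("UNRESOLVED_TRANSFORM",
                   paste0("no transform registered as '",
                          dim@transformRef, "'"))
        x <- makeTransform(def)$forward(x)
      }
      colCache[[key]] <<- x
    }
    colCache[[key]]
  }
}

.evalGeometricGate <- function(gate, prep, parent) {
  pts <- do.call(cbind, lapply(gate@dims, prep))
  pred <- if (is(gate, "RectangleGate")) inRectangle(pts, gate)
    else if (is(gate, "PolygonGate")) inPolygon(pts, gate)
    else if (is(gate, "EllipsoidGate")) inEllipsoid(pts, gate)
    else if (is(gate, "QuadrantGate")) inQuadrant(pts, gate)
    else cytoStop("UNSUPPORTED_GATE",
                  paste0("cannot evaluate gate of class ", class(gate)))
  parent & pred
}

#' Resolve a gating tree against a sample
#'
#' Computes the per-event boolean membership of every population:
#' root is all events; every other node is its parent's membership AND
#' its gate predicate, the predicate evaluated on channels prepared by
#' (1) compensation selection and application, (2) the per-dimension
#' display transform. Boolean gates are evaluated after their operands
#' (topological order, any already-defined path may be referenced);
#' cycles are reported as errors.
#'
#' @param ws a validating [Workspace-class].
#' @param sid sample id present in `ws`.
#' @param tree optionally, a tree to resolve instead of the sample's
#'   registered (or template) tree.
#' @return Named list of logical vectors (length = events), keyed by
#'   canonical population path.
#' @examples
#' fx <- standardFixture(n = 500)
#' res <- resolveGating(fx$workspace, sampleIds(fx$workspace)[1])
#' vapply(res, sum, 0)
#' @export
resolveGating <- function(ws, sid, tree = NULL) {
  viol <- validateWorkspace(ws)
  if (length(viol))
    cytoStop("INVALID_WORKSPACE",
             paste0("workspace does not validate: ",
                    paste(viol, collapse = " | ")))
  sample <- ws@samples[[sid]]
  if (is.null(sample))
    cytoStop("MISSING_FILE", paste0("no sample '", sid, "' in workspace"))
  if (is.null(tree)) tree <- gatingTreeFor(ws, sid)
  prep <- .makeChannelPrep(sample, ws)
  n <- nEvents(sample)
  resolved <- list(root = rep(TRUE, n))

  pending <- setdiff(populationPaths(tree), "root")
  while (length(pending)) {
    progressed <- FALSE
    for (p in pending) {
      node <- tree@nodes[[p]]
      parent <- resolved[[node@parentPath]]
      if (is.null(parent)) next
      g <- node@gate
      if (is(g, "BooleanGate")) {
        ops <- lapply(g@operands, function(op) resolved[[op]])
        if (any(vapply(ops, is.null, logical(1)))) next
        resolved[[p]] <- parent & evalBoolean(g, ops)
      } else if (is(g, "ClusterGate")) {
        rows <- which(parent)
        if (length(g@indices) && max(g@indices) > length(rows))
          cytoStop("LABEL_LENGTH",
                   paste0("cluster indices at '", p,
                          "' exceed parent population size"))
        m <- rep(FALSE, n)
        m[rows[g@indices]] <- TRUE
        resolved[[p]] <- m
      } else {
        resolved[[p]] <- .evalGeometricGate(g, prep, parent)
      }
      pending <- setdiff(pending, p)
      progressed <- TRUE
    }
    if (!progressed)
      cytoStop("CYCLE", paste0("boolean gate dependency cycle among: ",
                               paste(pending, collapse = ", ")))
  }
  resolved[populationPaths(tree)]
}

#' Membership indices of a resolved population
#' @param resolved result of [resolveGating()].
#' @param path population path.
#' @return Logical membership vector (a copy).
#' @export
getIndices <- function(resolved, path) {
  path <- normPopPath(path)
  v <- resolved[[path]]
  if (is.null(v))
    cytoStop("UNKNOWN_POPULATION", paste0("no population at '", path, "'"))
  v
}

#' Event-level data of a resolved population
#'
#' @param sample the [CytoSample-class] that was resolved.
#' @param resolved result of [resolveGating()].
#' @param path population path.
#' @param prepared if TRUE, return the gate-prepared view (compensated
#'   by the sample's auto-selected matrix); default is the raw,
#'   untransformed and uncompensated values.
#' @param ws workspace (required when `prepared = TRUE`).
#' @return Submatrix of member events, original column order.
#' @export
getData <- function(sample, resolved, path, prepared = FALSE, ws = NULL) {
  idx <- getIndices(resolved, path)
  mat <- sample@exprs
  if (prepared) {
    if (is.null(ws))
      cytoStop("INVALID_WORKSPACE", "prepared view needs the workspace")
    sm <- selectCompensation(sample, ws, "auto")
    if (!isIdentitySpillover(sm))
      mat <- compensate(mat, sm, channelNames(sample))
  }
  mat[idx, , drop = FALSE]
}

#' Population statistics table
#'
#' One row per population in deterministic pre-order: event count,
#' frequency of parent (0 when the parent is empty) and frequency of
#' total.
#'
#' @param resolved result of [resolveGating()].
#' @param tree the resolved [GatingTree-class].
#' @param nEvents total event count of the sample.
#' @param sampleId sample id for the `sample_id` column.
#' @return data.frame with columns sample_id, population_path,
#'   parent_path, count, freq_of_parent, freq_of_total.
#' @export
computeStats <- function(resolved, tree, nEvents, sampleId = "sample") {
  paths <- populationPaths(tree)
  counts <- vapply(paths, function(p) sum(resolved[[p]]), integer(1))
  parents <- popParentPath(paths)
  pcount <- ifelse(is.na(parents), NA_integer_, counts[parents])
  data.frame(
    sample_id = sampleId,
    population_path = paths,
    parent_path = ifelse(is.na(parents), "", parents),
    count = as.integer(counts),
    freq_of_parent = ifelse(is.na(parents), 1,
                            ifelse(pcount == 0, 0, counts / pcount)),
    freq_of_total = if (nEvents == 0) rep(0, length(paths))
                    else counts / nEvents,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Statistics for every sample of a workspace
#' @param ws a [Workspace-class] with samples.
#' @return Row-bound [computeStats()] tables over all samples.
#' @export
workspaceStats <- function(ws) {
  do.call(rbind, lapply(sampleIds(ws), function(sid) {
    res <- resolveGating(ws, sid)
    computeStats(res, gatingTreeFor(ws, sid),
                 nEvents(ws@samples[[sid]]), sid)
  }))
}

#' Write a population statistics table as CSV
#'
#' UTF-8, "." decimal separator, no thousands separators, header
#' `sample_id,population_path,parent_path,count,freq_of_parent,freq_of_total`.
#'
#' @param stats a [computeStats()] / [workspaceStats()] table.
#' @param path output file (or "" for stdout).
#' @return `path`, invisibly.
#' @export
writeStatsCsv <- function(stats, path) {
  utils::write.csv(stats, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Attach clustering results under a population
#'
#' Adds one index-defined child per distinct nonzero label, named
#' `<prefix>_<label>`; label 0 marks unassigned events. The children
#' partition the labeled events. Engines treat these nodes as opaque
#' membership vectors; only the FlowJo dialect can serialize them.
#'
#' @param tree a [GatingTree-class].
#' @param parentPath population the labels refer to.
#' @param labels per-event label vector over the parent's events.
#' @param prefix name prefix for the new populations.
#' @param parentCount if known, the parent's event count; a mismatching
#'   label vector length raises a label-length error (otherwise the
#'   check happens at resolve time).
#' @return The modified tree.
#' @export
attachClusters <- function(tree, parentPath, labels, prefix = "cluster",
                           parentCount = NULL) {
  parentPath <- normPopPath(parentPath)
  getNode(tree, parentPath)
  if (!is.null(parentCount) && length(labels) != parentCount)
    cytoStop("LABEL_LENGTH", sprintf(
      "label vector length %d != parent population size %d",
      length(labels), parentCount))
  for (lab in sort(unique(labels[labels != 0]))) {
    tree <- addPopulation(tree, parentPath, paste0(prefix, "_", lab),
                          clusterGate(which(labels == lab)))
  }
  tree
}

#' F-measure between two event sets
#'
#' Precision is taken with respect to the candidate set `b` (e.g. a
#' cluster) against the reference `a` (e.g. a manual gate):
#' P = |a & b| / |b|, R = |a & b| / |a|, F = 2PR / (P + R);
#' empty-set conventions: |b| = 0 gives P = 0, |a| = 0 gives R = 0,
#' P + R = 0 gives F = 0.
#'
#' @param a reference membership (logical).
#' @param b candidate membership (logical, same length).
#' @return List with elements `P`, `R`, `F`.
#' @examples
#' fMeasure(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
fMeasure <- function(a, b) {
  if (length(a) != length(b))
    cytoStop("INVALID_GATE", "membership vectors differ in length")
  tp <- sum(a & b)
  P <- if (sum(b) == 0) 0 else tp / sum(b)
  R <- if (sum(a) == 0) 0 else tp / sum(a)
  F <- if (P + R == 0) 0 else 2 * P * R / (P + R)
  list(P = P, R = R, F = F)
}
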
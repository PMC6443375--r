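# Synthetic fixtures: Gaussian-mixture cell populations observed
# through a known linear spillover, with ground-truth per-event labels.
# The generator is deterministic: a fixed, versioned pseudo-random
# algorithm (Mersenne-Twister with inversion-method normals) is
# selected explicitly, so identical seeds give identical fixtures
# across platforms and sessions. Event values are rounded to 32-bit
# float precision at generation time — the precision FCS data type F
# can carry — so FCS round-trips are bit-exact.

# run fn under a local, explicitly versioned RNG state
.withFixtureRNG <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  oldKind <- RNGkind("Mersenne-Twister", "Inversion", "Rejection")
  on.exit({
    do.call(RNGkind, as.list(oldKind))
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Specification of a synthetic Gaussian-mixture sample
#'
#' @param nEvents number of events to draw.
#' @param components list of components, each a list with `weight`
#'   (in (0, 1]; weights sum to 1), `mean` (length-d vector) and `cov`
#'   (d x d SPD matrix).
#' @param channels channel names (length d).
#' @param markers marker labels (optional).
#' @param spillover a [SpilloverMatrix-class] over the channels, or
#'   NULL for identity.
#' @param seed integer seed.
#' @return A validated spec (list with class "SyntheticSpec").
#' @export
syntheticSpec <- function(nEvents, components, channels,
                          markers = NULL, spillover = NULL, seed = 42L) {
  w <- vapply(components, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-12)
    cytoStop("INVALID_SPEC", sprintf(
      "component weights sum to %.15g, not 1", sum(w)))
  d <- length(channels)
  for (i in seq_along(components)) {
    cm <- components[[i]]
    if (length(cm$mean) != d || !all(dim(as.matrix(cm$cov)) == c(d, d)))
      cytoStop("INVALID_SPEC", sprintf(
        "component %d dimensions do not match %d channels", i, d))
    if (inherits(try(chol(as.matrix(cm$cov)), silent = TRUE), "try-error"))
      cytoStop("INVALID_SPEC", sprintf(
        "component %d covariance is not positive definite", i))
  }
  if (!is.null(spillover) &&
      !identical(sort(spillover@detectors), sort(channels)))
    cytoStop("INVALID_SPEC", "spillover detectors must match channels")
  structure(list(nEvents = as.integer(nEvents), components = components,
                 channels = channels,
                 markers = if (is.null(markers)) rep("", d) else markers,
                 spillover = spillover, seed = as.integer(seed)),
            class = "SyntheticSpec")
}

#' Draw a synthetic sample with ground-truth labels
#'
#' Events are drawn per-component from the specified Gaussian mixture
#' (component assignment by multinomial draw), then mixed through the
#' spillover matrix (observed = true x S) and rounded to 32-bit float
#' precision. Labels record the component of origin (1-based). The
#' spillover, when present, is recorded in the sample's $SPILLOVER
#' keyword.
#'
#' @param spec a [syntheticSpec()].
#' @return List with elements `sample` ([CytoSample-class]) and
#'   `labels` (integer vector, length nEvents).
#' @export
simulateSample <- function(spec) {
  if (!inherits(spec, "SyntheticSpec"))
    cytoStop("INVALID_SPEC", "expected a SyntheticSpec")
  d <- length(spec$channels)
  .withFixtureRNG(spec$seed, function() {
    w <- vapply(spec$components, `[[`, numeric(1), "weight")
    labels <- sample.int(length(w), spec$nEvents, replace = TRUE, prob = w)
    mat <- matrix(0, spec$nEvents, d)
    for (i in seq_along(spec$components)) {
      rows <- which(labels == i)
      if (!length(rows)) next
      cm <- spec$components[[i]]
      R <- chol(as.matrix(cm$cov))
      z <- matrix(stats::rnorm(length(rows) * d), ncol = d)
      mat[rows, ] <- sweep(z %*% R, 2, as.numeric(cm$mean), `+`)
    }
    kw <- c("$FIL" = paste0("synthetic_seed", spec$seed, ".fcs"))
    if (!is.null(spec$spillover)) {
      mat <- applySpillover(mat, spec$spillover, spec$channels)
      kw["$SPILLOVER"] <- buildSpilloverKeyword(spec$spillover)
    }
    mat <- asFloat32(mat)
    sample <- cytoSample(kw[["$FIL"]], mat, spec$channels,
                         markers = spec$markers, keywords = kw)
    list(sample = sample, labels = labels)
  })
}

#' Build the ground-truth reference workspace of a synthetic spec
#'
#' One ellipsoid gate per mixture component at the generating
#' parameters (center, covariance) with squared-distance threshold
#' `coverageRadius2`, gated on the compensated raw scale where the
#' generating mixture is Gaussian (an asinh-space image of a Gaussian
#' is not an ellipsoid, so exact label recovery requires raw-scale
#' gates). Per-channel asinh display transforms are declared in the
#' registry, and the spec's spillover is registered and referenced by
#' every gate dimension. Components whose means are closer than
#' `2 * sqrt(coverageRadius2)` (Mahalanobis, under each covariance)
#' trigger an overlap warning.
#'
#' @param spec a [syntheticSpec()].
#' @param coverageRadius2 squared Mahalanobis radius of each gate;
#'   default `qchisq(1 - 1e-7, d)` captures each component's events
#'   essentially completely while staying clear of well-separated
#'   neighbors.
#' @return A [Workspace-class] with the simulated sample attached.
#' @export
referenceWorkspace <- function(spec,
                               coverageRadius2 =
                                 stats::qchisq(1 - 1e-7,
                                               length(spec$channels))) {
  d <- length(spec$channels)
  sim <- simulateSample(spec)
  comps <- list()
  compRef <- "uncompensated"
  if (!is.null(spec$spillover) && !isIdentitySpillover(spec$spillover)) {
    comps[["spill"]] <- spec$spillover
    compRef <- "spill"
  }
  transforms <- list()
  for (ch in spec$channels) {
    tid <- paste0("asinh_", gsub("[^A-Za-z0-9]", "_", ch))
    transforms[[tid]] <- transformDef(tid, "asinh", T = 262144, M = 4.5,
                                      A = 0)
  }
  # separation check (Mahalanobis under each component's covariance)
  k <- length(spec$components)
  if (k > 1) {
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      ci <- spec$components[[i]]
      delta <- as.numeric(spec$components[[j]]$mean) - as.numeric(ci$mean)
      # under the first component's covariance (symmetric enough for a
      # well-formed fixture; the bound is advisory)
      md <- sqrt(sum(forwardsolve(t(chol(as.matrix(ci$cov))), delta)^2))
      if (md <= 2 * sqrt(coverageRadius2))
        warning(sprintf(
          "components %d and %d overlap (Mahalanobis separation %.2f <= %.2f); label recovery will be imperfect",
          i, j, md, 2 * sqrt(coverageRadius2)), call. = FALSE)
    }
  }
  tree <- gatingTree()
  for (i in seq_len(k)) {
    cm <- spec$components[[i]]
    dims <- lapply(spec$channels, gateDimension,
                   transformRef = "identity", compensationRef = compRef)
    tree <- addPopulation(tree, "root", paste0("pop", i),
                          ellipsoidGate(dims, as.numeric(cm$mean),
                                        as.matrix(cm$cov),
                                        coverageRadius2))
  }
  ws <- workspace(samples = list(sim$sample), template = tree,
                  transforms = transforms, compensations = comps,
                  dialect = "gatingml")
  attr(ws, "labels") <- sim$labels
  ws
}

#' The standard synthetic fixture
#'
#' Three Gaussian components with weights (0.5, 0.3, 0.2) over four
#' fluorescence channels, means separated by >= 12 standard deviations,
#' spillover off-diagonals <= 0.15, 10^4 events, seed 42. Every
#' downstream module is exercised end-to-end against this fixture's
#' ground-truth labels.
#'
#' @param n number of events.
#' @param seed integer seed.
#' @param spillover if FALSE, use identity spillover.
#' @return List with `spec`, `workspace` (reference workspace with the
#'   sample attached) and `labels`.
#' @examples
#' fx <- standardFixture(n = 1000)
#' table(fx$labels)
#' @export
standardFixture <- function(n = 10000L, seed = 42L, spillover = TRUE) {
  channels <- c("FL1-A", "FL2-A", "FL3-A", "FL4-A")
  markers <- c("CD3", "CD4", "CD8", "CD19")
  sd0 <- 3000
  corr <- function(r12) {
    C <- diag(4) * sd0^2
    C[1, 2] <- C[2, 1] <- r12 * sd0^2
    C
  }
  components <- list(
    list(weight = 0.5, mean = c(20000, 20000, 5000, 5000), cov = corr(0.3)),
    list(weight = 0.3, mean = c(60000, 5000, 40000, 8000), cov = corr(-0.2)),
    list(weight = 0.2, mean = c(5000, 60000, 20000, 45000), cov = corr(0.1))
  )
  sm <- if (spillover) {
    S <- diag(4)
    S[1, 2] <- 0.12; S[2, 1] <- 0.08
    S[2, 3] <- 0.10; S[3, 2] <- 0.05
    S[3, 4] <- 0.15; S[4, 3] <- 0.07
    spilloverMatrix(channels, S)
  } else NULL
  spec <- syntheticSpec(n, components, channels, markers = markers,
                        spillover = sm, seed = seed)
  ws <- referenceWorkspace(spec)
  list(spec = spec, workspace = ws, labels = attr(ws, "labels"))
}

#' Write a fixture bundle: FCS file, workspace XML and labels CSV
#'
#' @param spec a [syntheticSpec()].
#' @param dir output directory (created if needed).
#' @param dialect workspace dialect to emit.
#' @return Character vector of the three written paths.
#' @export
writeFixtureBundle <- function(spec, dir, dialect = "gatingml") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ws <- referenceWorkspace(spec)
  labels <- attr(ws, "labels")
  sid <- sampleIds(ws)[1]
  fcsPath <- file.path(dir, sid)
  writeFCS(ws@samples[[sid]], fcsPath)
  wsPath <- file.path(dir, paste0("workspace_",
                                  switch(dialect, flowjo = "flowjo.wsp",
                                         cytobank = "cytobank.xml",
                                         "gatingml.xml")))
  .writeDialect(ws, wsPath, dialect)
  labPath <- file.path(dir, "labels.csv")
  utils::write.csv(data.frame(event_index = seq_along(labels),
                              label = labels),
                   labPath, row.names = FALSE, quote = FALSE)
  c(fcs = fcsPath, workspace = wsPath, labels = labPath)
}

#' Parse a YAML synthetic-sample specification
#'
#' Fields: `n_events`, `channels`, optional `markers`, `seed`,
#' `components` (list of `weight`/`mean`/`cov` entries; `cov` may be a
#' full matrix, a diagonal vector, or a scalar), optional `spillover`
#' (row-major matrix over the channels).
#'
#' @param path YAML file.
#' @param seed optional seed overriding the file's.
#' @return A [syntheticSpec()].
#' @export
readSpecYaml <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  for (field in c("n_events", "channels", "components"))
    if (is.null(y[[field]]))
      cytoStop("INVALID_SPEC", paste0("spec is missing '", field, "'"))
  d <- length(y$channels)
  comps <- lapply(y$components, function(cm) {
    cov <- cm$cov
    cov <- if (is.null(cov)) diag(d)
           else if (length(unlist(cov)) == 1) diag(d) * as.numeric(cov)
           else if (is.list(cov)) do.call(rbind, lapply(cov, as.numeric))
           else if (length(cov) == d) diag(as.numeric(cov))
           else matrix(as.numeric(unlist(cov)), d, d, byrow = TRUE)
    list(weight = as.numeric(cm$weight), mean = as.numeric(unlist(cm$mean)),
         cov = cov)
  })
  sm <- if (!is.null(y$spillover))
    spilloverMatrix(y$channels,
                    do.call(rbind, lapply(y$spillover, as.numeric)))
  syntheticSpec(y$n_events, comps, y$channels, markers = y$markers,
                spillover = sm,
                seed = if (!is.null(seed)) seed
                       else if (!is.null(y$seed)) y$seed else 42L)
}

# ---- randomized fixture workspaces (round-trip test harness) ----------

#' Generate a randomized workspace/sample fixture
#'
#' A random sample (events uniform on the display scale, mapped to the
#' raw scale through randomly assigned per-channel transforms, then
#' optionally spilled) plus a random gating tree of depth <= 3 mixing
#' rectangle, polygon, ellipsoid, quadrant and boolean gates. Used to
#' exercise dialect round-trips; every dialect can represent the
#' generated feature set.
#'
#' @param seed integer seed.
#' @param nEvents events to draw.
#' @param maxGates upper bound on non-root populations.
#' @return List with `workspace` (sample attached, template tree) and
#'   `sample`.
#' @export
randomGatingFixture <- function(seed, nEvents = 600L, maxGates = 7L) {
  .withFixtureRNG(seed, function() {
    d <- sample(3:4, 1)
    channels <- paste0("FL", seq_len(d), "-A")
    fams <- sample(c("identity", "linear", "log", "asinh", "logicle"),
                   d, replace = TRUE)
    transforms <- list()
    chanRef <- character(d)
    for (j in seq_len(d)) {
      if (fams[j] == "identity") { chanRef[j] <- "identity"; next }
      tid <- paste0("tf", j)
      transforms[[tid]] <- transformDef(
        tid, fams[j], T = sample(c(1024, 262144, 10000), 1),
        M = stats::runif(1, 4, 5), A = stats::runif(1, 0, 0.4),
        W = stats::runif(1, 0.2, 1))
      chanRef[j] <- tid
    }
    useSpill <- stats::runif(1) < 0.5
    comps <- list()
    compRef <- "uncompensated"
    if (useSpill) {
      S <- diag(d)
      off <- which(upper.tri(S) | lower.tri(S))
      S[off] <- stats::runif(length(off), 0, 0.1)
      comps[["spill"]] <- spilloverMatrix(channels, S)
      compRef <- "spill"
    }
    # events uniform in display space, pushed back to the raw scale
    u <- matrix(stats::runif(nEvents * d, 0.02, 0.98), ncol = d)
    raw <- u
    for (j in seq_len(d)) {
      if (chanRef[j] == "identity") next
      raw[, j] <- makeTransform(transforms[[chanRef[j]]])$inverse(u[, j])
    }
    if (useSpill) raw <- applySpillover(raw, comps[["spill"]], channels)
    sample <- cytoSample(sprintf("random_seed%d.fcs", seed),
                         asFloat32(raw), channels)

    dimFor <- function(j) gateDimension(channels[j], chanRef[j], compRef)
    randomGate <- function() {
      type <- sample(c("rect", "poly", "ellipse", "quad"), 1,
                     prob = c(0.35, 0.3, 0.2, 0.15))
      jj <- sample(seq_len(d), 2)
      if (type == "rect") {
        ndim <- sample(1:2, 1)
        dims <- lapply(jj[seq_len(ndim)], dimFor)
        lo <- stats::runif(ndim, 0.05, 0.5)
        hi <- lo + stats::runif(ndim, 0.1, 0.45)
        if (ndim > 1 && stats::runif(1) < 0.3) lo[1] <- NA
        rectangleGate(dims, lo, hi)
      } else if (type == "poly") {
        nv <- sample(3:7, 1)
        ang <- sort(stats::runif(nv, 0, 2 * pi))
        r <- stats::runif(nv, 0.08, 0.35)
        cx <- stats::runif(1, 0.3, 0.7); cy <- stats::runif(1, 0.3, 0.7)
        polygonGate(lapply(jj, dimFor),
                    cbind(cx + r * cos(ang), cy + r * sin(ang)))
      } else if (type == "ellipse") {
        ctr <- stats::runif(2, 0.3, 0.7)
        ang <- stats::runif(1, 0, pi)
        R <- matrix(c(cos(ang), -sin(ang), sin(ang), cos(ang)), 2)
        C <- R %*% diag(stats::runif(2, 0.005, 0.04)) %*% t(R)
        ellipsoidGate(lapply(jj, dimFor), ctr, (C + t(C)) / 2,
                      stats::runif(1, 1, 4))
      } else {
        quadrantGate(lapply(jj, dimFor), stats::runif(2, 0.2, 0.8),
                     sample(c("++", "+-", "-+", "--"), 1))
      }
    }
    tree <- gatingTree()
    nGates <- sample(3:maxGates, 1)
    for (g in seq_len(nGates)) {
      paths <- populationPaths(tree)
      depths <- lengths(strsplit(paths, "/", fixed = TRUE))
      parents <- paths[depths <= 3]
      parent <- sample(parents, 1)
      nm <- paste0("P", g)
      existing <- setdiff(populationPaths(tree), "root")
      if (length(existing) >= 2 && stats::runif(1) < 0.25) {
        op <- sample(c("AND", "OR", "NOT"), 1)
        nops <- if (op == "NOT") 1 else 2
        gate <- booleanGate(op, sample(existing, nops))
      } else {
        gate <- randomGate()
      }
      tree <- addPopulation(tree, parent, nm, gate)
    }
    ws <- workspace(samples = list(sample), template = tree,
                    transforms = transforms, compensations = comps,
                    dialect = "gatingml")
    list(workspace = ws, sample = sample)
  })
}
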
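# Vectorized gate-membership predicates over event coordinates on the
# transformed scale. Convention throughout: boundary inclusive ("on the
# line = in the gate"), even-odd rule for polygons, and quadrant ties
# resolved to the "+" side so the four quadrants partition the plane.

#' Rectangle gate membership
#'
#' @param points n x d numeric matrix on the transformed scale.
#' @param gate a [RectangleGate-class]; NA bounds impose no constraint.
#' @return Logical vector of length n.
#' @export
inRectangle <- function(points, gate) {
  points <- as.matrix(points)
  if (ncol(points) != length(gate@dims))
    cytoStop("INVALID_GATE", "point dimensionality does not match gate")
  keep <- rep(TRUE, nrow(points))
  for (j in seq_along(gate@dims)) {
    if (!is.na(gate@min[j])) keep <- keep & points[, j] >= gate@min[j]
    if (!is.na(gate@max[j])) keep <- keep & points[, j] <= gate@max[j]
  }
  keep
}

# Point-on-segment test used for boundary inclusivity: collinear within
# a scale-relative tolerance and inside the segment's bounding box.
.onSegment <- function(px, py, x1, y1, x2, y2) {
  scale <- max(1, abs(x1), abs(y1), abs(x2), abs(y2))
  cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
  abs(cross) <= 1e-12 * scale * scale &
    px >= pmin(x1, x2) - 1e-12 * scale & px <= pmax(x1, x2) + 1e-12 * scale &
    py >= pmin(y1, y2) - 1e-12 * scale & py <= pmax(y1, y2) + 1e-12 * scale
}

#' Polygon gate membership (even-odd rule, boundary inclusive)
#'
#' Crossing-count (even-odd) interior plus the boundary itself;
#' vertices and points on edges are members. Self-intersecting polygons
#' are handled by the same rule.
#'
#' @param points n x 2 numeric matrix.
#' @param gate a [PolygonGate-class].
#' @return Logical vector of length n.
#' @export
inPolygon <- function(points, gate) {
  points <- as.matrix(points)
  v <- gate@vertices
  nv <- nrow(v)
  px <- points[, 1]; py <- points[, 2]
  inside <- rep(FALSE, length(px))
  onEdge <- rep(FALSE, length(px))
  j <- nv
  for (i in seq_len(nv)) {
    x1 <- v[j, 1]; y1 <- v[j, 2]; x2 <- v[i, 1]; y2 <- v[i, 2]
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < x1 + (py - y1) * (x2 - x1) / (y2 - y1))
    crosses[is.na(crosses)] <- FALSE
    inside <- xor(inside, crosses)
    onEdge <- onEdge | .onSegment(px, py, x1, y1, x2, y2)
    j <- i
  }
  inside | onEdge
}

#' Ellipsoid gate membership: (x - mu)' C^-1 (x - mu) <= D2
#'
#' Evaluated through the Cholesky factorization of the shape matrix
#' (never by explicit inversion), boundary inclusive.
#'
#' @param points n x d numeric matrix.
#' @param gate an [EllipsoidGate-class].
#' @return Logical vector of length n.
#' @export
inEllipsoid <- function(points, gate) {
  points <- as.matrix(points)
  C <- gate@cov
  if (max(abs(C - t(C))) > 1e-8 * max(1, max(abs(C))))
    cytoStop("INVALID_GATE", "ellipsoid shape matrix is not symmetric")
  R <- try(chol(C), silent = TRUE)   # C = R'R
  if (inherits(R, "try-error"))
    cytoStop("INVALID_GATE", "ellipsoid shape matrix is not positive definite")
  centered <- t(points) - gate@mu
  z <- forwardsolve(t(R), centered)  # solve R' z = (x - mu)
  colSums(z * z) <= gate@distSq
}

#' Quadrant gate membership
#'
#' @param points n x 2 numeric matrix.
#' @param gate a [QuadrantGate-class]; "+" means >= the divider, "-"
#'   means < (ties belong to the "+" side).
#' @return Logical vector of length n.
#' @export
inQuadrant <- function(points, gate) {
  points <- as.matrix(points)
  sel <- strsplit(gate@selector, "")[[1]]
  sideX <- if (sel[1] == "+") points[, 1] >= gate@dividers[1]
           else points[, 1] < gate@dividers[1]
  sideY <- if (sel[2] == "+") points[, 2] >= gate@dividers[2]
           else points[, 2] < gate@dividers[2]
  sideX & sideY
}

#' Elementwise boolean combination of operand memberships
#'
#' @param gate a [BooleanGate-class].
#' @param operandMemberships list of logical vectors (equal length),
#'   one per operand.
#' @return Logical vector.
#' @export
evalBoolean <- function(gate, operandMemberships) {
  n <- length(operandMemberships)
  if (gate@operator == "NOT" && n != 1L)
    cytoStop("INVALID_GATE", "NOT takes exactly one operand")
  if (gate@operator != "NOT" && n < 1L)
    cytoStop("INVALID_GATE", "boolean gate needs at least one operand")
  lens <- lengths(operandMemberships)
  if (length(unique(lens)) > 1L)
    cytoStop("INVALID_GATE", "operand membership vectors differ in length")
  switch(gate@operator,
    NOT = !operandMemberships[[1]],
    AND = Reduce(`&`, operandMemberships),
    OR  = Reduce(`|`, operandMemberships))
}

#' Approximate an ellipsoid gate by an inscribed polygon
#'
#' Used when exporting to dialects without a native ellipse element.
#' Vertices lie exactly on the ellipse boundary (equal-angle placement
#' in the whitened space), so the polygon is inscribed.
#'
#' @param gate a 2-dimensional [EllipsoidGate-class].
#' @param n number of vertices.
#' @return A [PolygonGate-class] over the same dimensions.
#' @export
polygonizeEllipsoid <- function(gate, n = 100L) {
  if (length(gate@dims) != 2L)
    cytoStop("UNSUPPORTED_EXPORT",
             "only 2-dimensional ellipsoids can be polygonized")
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  circ <- rbind(cos(theta), sin(theta)) * sqrt(gate@distSq)
  R <- chol(gate@cov)                      # C = R'R
  verts <- t(t(R) %*% circ + gate@mu)      # x = mu + R' u, |u| = sqrt(D2)
  polygonGate(gate@dims, verts)
}
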
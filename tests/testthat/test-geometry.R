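dim2 <- list(gateDimension("x"), gateDimension("y"))

test_that("rectangle membership is boundary-inclusive with open sides", {
  g1 <- rectangleGate(list(gateDimension("x")), 0, 10)
  expect_identical(inRectangle(matrix(c(-1, 0, 5, 10, 11)), g1),
                   c(FALSE, TRUE, TRUE, TRUE, FALSE))
  gLower <- rectangleGate(dim2, c(0, 0), c(NA, NA))
  expect_true(inRectangle(matrix(c(5, 5), 1), gLower))
  expect_false(inRectangle(matrix(c(-1, 5), 1), gLower))
})

test_that("polygon membership follows the even-odd rule, boundary inclusive", {
  sq <- polygonGate(dim2, rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_true(inPolygon(matrix(c(0.5, 0.5), 1), sq))
  expect_false(inPolygon(matrix(c(2, 2), 1), sq))
  expect_true(inPolygon(matrix(c(1, 0.5), 1), sq))    # edge point
  expect_true(inPolygon(matrix(c(0, 0), 1), sq))      # vertex
  # self-intersecting bowtie agrees with the independent oracle
  bow <- polygonGate(dim2, rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2)))
  set.seed(12)
  pts <- cbind(runif(2000, -0.5, 2.5), runif(2000, -0.5, 2.5))
  expect_identical(inPolygon(pts, bow),
                   unname(oraclePointInPolygon(pts, bow@vertices)))
})

test_that("convex polygons agree with a half-plane intersection oracle", {
  set.seed(13)
  for (i in 1:5) {
    ang <- sort(runif(sample(3:8, 1), 0, 2 * pi))
    verts <- cbind(cos(ang), sin(ang))   # convex, counter-clockwise
    g <- polygonGate(dim2, verts)
    pts <- cbind(runif(2000, -1.2, 1.2), runif(2000, -1.2, 1.2))
    expect_identical(inPolygon(pts, g),
                     unname(oracleConvexPolygon(pts, verts)))
  }
})

test_that("ellipsoid membership is the quadratic form, boundary inclusive", {
  g <- ellipsoidGate(dim2, c(0, 0), diag(2), 1)
  expect_identical(inEllipsoid(rbind(c(0, 0), c(1, 0), c(2, 0)), g),
                   c(TRUE, TRUE, FALSE))
  g2 <- ellipsoidGate(dim2, c(1, 1), matrix(c(4, 0, 0, 1), 2), 1)
  expect_true(inEllipsoid(matrix(c(3, 1), 1), g2))     # distance^2 = 1
  expect_false(inEllipsoid(matrix(c(3.1, 1), 1), g2))
  # agreement with direct quadratic-form evaluation
  set.seed(14)
  A <- matrix(rnorm(9), 3)
  C <- crossprod(A) + diag(3) * 0.1
  g3 <- ellipsoidGate(list(gateDimension("x"), gateDimension("y"),
                           gateDimension("z")),
                      c(1, -1, 2), C, 5)
  pts <- matrix(rnorm(3000, 0, 3), ncol = 3)
  direct <- apply(pts, 1, function(p) {
    v <- p - g3@mu
    drop(t(v) %*% solve(C) %*% v) <= 5
  })
  expect_identical(inEllipsoid(pts, g3), unname(direct))
})

test_that("quadrant ties go to the plus side and selectors partition", {
  g <- function(sel) quadrantGate(dim2, c(0, 0), sel)
  expect_true(inQuadrant(matrix(c(1, 1), 1), g("++")))
  expect_true(inQuadrant(matrix(c(0, 5), 1), g("++")))   # tie on x
  expect_false(inQuadrant(matrix(c(0, 5), 1), g("-+")))
  set.seed(15)
  pts <- cbind(c(runif(5000, -2, 2), 0, 0),
               c(runif(5000, -2, 2), 0, 1))
  counts <- Reduce(`+`, lapply(c("++", "+-", "-+", "--"),
                               function(s) inQuadrant(pts, g(s))))
  expect_true(all(counts == 1L))
})

test_that("boolean gates combine memberships elementwise with arity checks", {
  expect_identical(evalBoolean(booleanGate("NOT", "a"),
                               list(c(TRUE, FALSE, TRUE))),
                   c(FALSE, TRUE, FALSE))
  expect_identical(evalBoolean(booleanGate("AND", c("a", "b")),
                               list(c(TRUE, TRUE, FALSE),
                                    c(TRUE, FALSE, FALSE))),
                   c(TRUE, FALSE, FALSE))
  expect_identical(evalBoolean(booleanGate("OR", c("a", "b")),
                               list(c(TRUE, FALSE, FALSE),
                                    c(FALSE, FALSE, TRUE))),
                   c(TRUE, FALSE, TRUE))
  expect_error(evalBoolean(booleanGate("AND", c("a", "b")),
                           list(c(TRUE), c(TRUE, FALSE))),
               class = "cyto_invalid_gate")
})

test_that("membership is invariant under joint translation", {
  set.seed(16)
  pts <- cbind(runif(500), runif(500))
  shift <- c(3.7, -2.2)
  sq <- polygonGate(dim2, rbind(c(0.2, 0.2), c(0.8, 0.3), c(0.5, 0.9)))
  sq2 <- polygonGate(dim2, sweep(sq@vertices, 2, -shift))
  expect_identical(inPolygon(pts, sq),
                   inPolygon(sweep(pts, 2, -shift), sq2))
  el <- ellipsoidGate(dim2, c(0.5, 0.5), diag(2) * 0.04, 2)
  el2 <- ellipsoidGate(dim2, c(0.5, 0.5) + shift, diag(2) * 0.04, 2)
  expect_identical(inEllipsoid(pts, el),
                   inEllipsoid(sweep(pts, 2, -shift), el2))
})

test_that("polygonized ellipsoids are inscribed approximations", {
  g <- ellipsoidGate(dim2, c(0.4, 0.6),
                     matrix(c(0.02, 0.008, 0.008, 0.01), 2), 2)
  poly <- polygonizeEllipsoid(g, 100L)
  # all vertices lie exactly on the ellipse boundary
  R <- chol(g@cov)
  d2 <- colSums(forwardsolve(t(R), t(poly@vertices) - g@mu)^2)
  expect_equal(d2, rep(g@distSq, 100), tolerance = 1e-12)
})
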
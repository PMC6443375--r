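test_that("an empty tree resolves to root containing every event", {
  s <- cytoSample("s.fcs", matrix(rnorm(30), 10, 3), c("A", "B", "C"))
  ws <- workspace(samples = list(s), template = gatingTree())
  res <- resolveGating(ws, "s.fcs")
  expect_identical(res, list(root = rep(TRUE, 10)))
})

test_that("children are conjunctions of parent membership and gate predicate", {
  ws <- tinyWorkspace(nEvents = 300)
  res <- resolveGating(ws, "tiny.fcs")
  expect_true(all(res[["root/cells/lymph"]] <= res[["root/cells"]]))
  expect_true(all(res[["root/cells"]] <= res[["root"]]))
})

test_that("resolve matches the naive per-event recursive evaluator", {
  for (seed in 1:12) {
    fx <- randomGatingFixture(seed, nEvents = 100L)
    ws <- fx$workspace
    sid <- sampleIds(ws)[1]
    fast <- resolveGating(ws, sid)
    slow <- oracleResolve(ws, sid)
    for (p in names(fast))
      expect_identical(unname(fast[[p]]), unname(slow[[p]]),
                       info = sprintf("seed %d population %s", seed, p))
  }
})

test_that("resolve is deterministic and containment holds on larger fixtures", {
  fx <- randomGatingFixture(99, nEvents = 2000L)
  ws <- fx$workspace; sid <- sampleIds(ws)[1]
  r1 <- resolveGating(ws, sid)
  r2 <- resolveGating(ws, sid)
  expect_identical(r1, r2)
  tree <- ws@template
  for (p in setdiff(populationPaths(tree), "root"))
    expect_true(all(r1[[p]] <= r1[[tree@nodes[[p]]@parentPath]]), info = p)
})

test_that("boolean dependency cycles are detected and named", {
  s <- cytoSample("s.fcs", matrix(rnorm(10), 5, 2), c("A", "B"))
  tree <- gatingTree()
  tree <- addPopulation(tree, "root", "u", booleanGate("NOT", "root/v"))
  tree <- addPopulation(tree, "root", "v", booleanGate("NOT", "root/u"))
  ws <- workspace(samples = list(s), template = tree)
  err <- tryCatch(resolveGating(ws, "s.fcs"), cytoError = identity)
  expect_identical(errorToken(err), "CYCLE")
  expect_match(conditionMessage(err), "root/u")
})

test_that("cell-level access returns member rows and errors on unknown paths", {
  ws <- tinyWorkspace(nEvents = 200)
  res <- resolveGating(ws, "tiny.fcs")
  expect_identical(getIndices(res, "root"), rep(TRUE, 200))
  expect_error(getIndices(res, "/xyz"), class = "cyto_unknown_population")
  s <- ws@samples[[1]]
  d <- getData(s, res, "root/cells")
  expect_identical(nrow(d), sum(res[["root/cells"]]))
  expect_identical(unname(d),
                   unname(eventMatrix(s)[res[["root/cells"]], , drop = FALSE]))
  expect_identical(colnames(d), channelNames(s))
  # empty population yields a 0 x k matrix
  tree <- gatingTreeFor(ws, "tiny.fcs")
  tree <- addPopulation(tree, "root", "none",
                        rectangleGate(list(gateDimension("FSC-A", "lin1")),
                                      5, 6))
  res2 <- resolveGating(ws, "tiny.fcs", tree = tree)
  expect_identical(dim(getData(s, res2, "root/none")), c(0L, 3L))
})

test_that("population statistics satisfy their frequency identities", {
  s <- cytoSample("s.fcs", matrix(runif(1000, 0, 100), 500, 2),
                  c("A", "B"))
  tree <- gatingTree()
  ws0 <- workspace(samples = list(s), template = tree)
  st0 <- computeStats(resolveGating(ws0, "s.fcs"), tree, 500, "s.fcs")
  expect_identical(nrow(st0), 1L)
  expect_identical(st0$count, 500L)
  expect_equal(st0$freq_of_parent, 1)
  expect_equal(st0$freq_of_total, 1)

  g <- rectangleGate(list(gateDimension("A")), 0, 50)
  tree <- addPopulation(tree, "root", "g", g)
  tree <- addPopulation(tree, "root", "notg", booleanGate("NOT", "root/g"))
  ws <- workspace(samples = list(s), template = tree)
  res <- resolveGating(ws, "s.fcs")
  st <- computeStats(res, tree, 500, "s.fcs")
  expect_identical(st$population_path,
                   c("root", "root/g", "root/notg"))
  expect_identical(st$count[2] + st$count[3], st$count[1])  # complement
  expect_equal(st$freq_of_parent[2], st$count[2] / 500)
  expect_true(all(st$count[-1] <= st$count[1]))
  # stats CSV interface
  tf <- withr::local_tempfile(fileext = ".csv")
  writeStatsCsv(st, tf)
  expect_identical(
    readLines(tf, n = 1),
    "\"sample_id\",\"population_path\",\"parent_path\",\"count\",\"freq_of_parent\",\"freq_of_total\"")
})

test_that("cluster attachment partitions the labeled events", {
  s <- cytoSample("s.fcs", matrix(runif(600), 300, 2), c("A", "B"))
  tree <- addPopulation(gatingTree(), "root", "parent",
                        rectangleGate(list(gateDimension("A")), 0, 0.5))
  ws <- workspace(samples = list(s), template = tree)
  res <- resolveGating(ws, "s.fcs")
  np <- sum(res[["root/parent"]])
  labels <- rep_len(c(1L, 1L, 2L, 0L), np)
  tree2 <- attachClusters(tree, "root/parent", labels, parentCount = np)
  res2 <- resolveGating(ws, "s.fcs", tree = tree2)
  c1 <- sum(res2[["root/parent/cluster_1"]])
  c2 <- sum(res2[["root/parent/cluster_2"]])
  expect_identical(c1, sum(labels == 1))
  expect_identical(c2, sum(labels == 2))
  expect_identical(c1 + c2, sum(labels != 0))  # partition of labeled
  expect_true(all(res2[["root/parent/cluster_1"]] <= res2[["root/parent"]]))
  # all-zero labels add nothing; length mismatch errors
  expect_length(populationPaths(attachClusters(tree, "root/parent",
                                               rep(0L, np),
                                               parentCount = np)), 2)
  expect_error(attachClusters(tree, "root/parent", c(1L, 2L),
                              parentCount = np),
               class = "cyto_label_length")
})

test_that("F-measure follows the precision/recall conventions", {
  a <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(fMeasure(a, a)$F, 1)
  expect_equal(fMeasure(a, !a)$F, 0)
  # |a| = 100, |b| = 50, overlap 25 -> P = 0.5, R = 0.25, F = 1/3
  a2 <- rep(c(TRUE, FALSE), c(100, 100))
  b2 <- rep(c(FALSE, TRUE, FALSE), c(75, 50, 75))
  f <- fMeasure(a2, b2)
  expect_equal(f$P, 0.5)
  expect_equal(f$R, 0.25)
  expect_equal(f$F, 1 / 3)
  expect_equal(fMeasure(logical(4), b2[1:4])$F, 0)
  expect_error(fMeasure(a, a[1:2]), class = "cyto_invalid_gate")
})

test_that("the standard fixture's labels are recovered exactly", {
  fx <- standardFixture(n = 2000)
  ws <- fx$workspace; sid <- sampleIds(ws)[1]
  res <- resolveGating(ws, sid)
  for (i in 1:3)
    expect_equal(fMeasure(fx$labels == i,
                          res[[paste0("root/pop", i)]])$F, 1)
  st <- computeStats(res, gatingTreeFor(ws, sid), 2000, sid)
  expect_identical(st$count[-1], unname(c(table(fx$labels))))
})
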
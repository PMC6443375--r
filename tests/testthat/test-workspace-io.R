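test_that("Gating-ML round-trip preserves gates, transforms and matrices", {
  fx <- randomGatingFixture(21)
  ws <- fx$workspace
  tf <- withr::local_tempfile(fileext = ".xml")
  writeGatingML(ws, tf)
  ws2 <- readGatingML(tf)
  expect_identical(dialect(ws2), "gatingml")
  # registries survive bit-exactly (17-digit serialization)
  expect_equal(ws2@transforms, ws@transforms)
  for (id in names(ws@compensations))
    expect_identical(ws2@compensations[[id]]@S, ws@compensations[[id]]@S)
  expect_equal(ws2@template, ws@template)
  # memberships on the identical sample are bit-identical
  ws2 <- setSamples(ws2, ws@samples)
  sid <- sampleIds(ws)[1]
  expect_identical(resolveGating(ws2, sid), resolveGating(ws, sid))
})

test_that("minimal foreign Gating-ML parses with defaults under root", {
  xml <- paste0(
    '<gating:Gating-ML xmlns:gating="http://www.isac-net.org/std/Gating-ML/v2.0/gating" ',
    'xmlns:data-type="http://www.isac-net.org/std/Gating-ML/v2.0/datatypes">',
    '<gating:PolygonGate gating:id="g1">',
    '<gating:dimension gating:compensation-ref="uncompensated">',
    '<data-type:fcs-dimension data-type:name="FL1"/></gating:dimension>',
    '<gating:dimension gating:compensation-ref="uncompensated">',
    '<data-type:fcs-dimension data-type:name="FL2"/></gating:dimension>',
    '<gating:vertex><gating:coordinate data-type:value="0"/>',
    '<gating:coordinate data-type:value="0"/></gating:vertex>',
    '<gating:vertex><gating:coordinate data-type:value="1"/>',
    '<gating:coordinate data-type:value="0"/></gating:vertex>',
    '<gating:vertex><gating:coordinate data-type:value="0"/>',
    '<gating:coordinate data-type:value="1"/></gating:vertex>',
    '</gating:PolygonGate></gating:Gating-ML>')
  tf <- withr::local_tempfile(fileext = ".xml")
  writeLines(xml, tf)
  ws <- readGatingML(tf)
  paths <- populationPaths(ws@template)
  expect_identical(paths, c("root", "root/g1"))
  g <- getNode(ws@template, "root/g1")@gate
  expect_s4_class(g, "PolygonGate")
  expect_identical(vapply(g@dims, function(d) d@transformRef,
                          character(1)), c("identity", "identity"))
  expect_length(ws@transforms, 0)
})

test_that("dangling parent ids and unknown gate elements are rejected", {
  base <- '<gating:Gating-ML xmlns:gating="http://www.isac-net.org/std/Gating-ML/v2.0/gating" xmlns:data-type="http://www.isac-net.org/std/Gating-ML/v2.0/datatypes">%s</gating:Gating-ML>'
  rect <- paste0(
    '<gating:RectangleGate gating:id="g1" gating:parent_id="ghost">',
    '<gating:dimension gating:min="0" gating:compensation-ref="uncompensated">',
    '<data-type:fcs-dimension data-type:name="FL1"/></gating:dimension>',
    '</gating:RectangleGate>')
  tf <- withr::local_tempfile(fileext = ".xml")
  writeLines(sprintf(base, rect), tf)
  expect_error(readGatingML(tf), class = "cyto_dangling_reference")
  writeLines(sprintf(base, '<gating:CurlyGate gating:id="g1"/>'), tf)
  expect_error(readGatingML(tf), class = "cyto_unsupported_gate")
})

test_that("FlowJo dialect round-trips stats exactly, raw-scale coordinates", {
  fx <- randomGatingFixture(22)
  ws <- fx$workspace
  sid <- sampleIds(ws)[1]
  fd <- withr::local_tempdir()
  writeFCS(ws@samples[[1]], file.path(fd, sid))
  wsp <- withr::local_tempfile(fileext = ".wsp")
  writeFlowjo(ws, wsp)
  ws2 <- readFlowjo(wsp, fd)
  expect_identical(dialect(ws2), "flowjo")
  st1 <- workspaceStats(ws)
  st2 <- workspaceStats(ws2)
  expect_identical(st1$count, st2$count)
  expect_identical(st1$population_path, st2$population_path)
  expect_identical(resolveGating(ws2, sid)[[2]],
                   resolveGating(ws, sid)[[2]])
  # coordinates in the file are on the raw scale: re-transforming the
  # serialized vertices through the declared transform must reproduce
  # the internal transformed-scale coordinates
  doc <- xml2::read_xml(wsp)
  expect_true(length(xml2::xml_find_all(doc, "//SampleNode")) == 1)
})

test_that("FlowJo import reports missing FCS files with candidates", {
  fx <- randomGatingFixture(23)
  ws <- fx$workspace
  fd <- withr::local_tempdir()
  writeFCS(ws@samples[[1]], file.path(fd, sampleIds(ws)[1]))
  wsp <- withr::local_tempfile(fileext = ".wsp")
  writeFlowjo(ws, wsp)
  empty <- withr::local_tempdir()
  err <- tryCatch(readFlowjo(wsp, empty), cytoError = identity)
  expect_identical(errorToken(err), "MISSING_FILE")
  expect_match(conditionMessage(err), sampleIds(ws)[1], fixed = TRUE)
})

test_that("a per-sample workspace matrix beats the FCS $SPILLOVER keyword", {
  fx <- standardFixture(n = 300)
  ws <- fx$workspace
  sid <- sampleIds(ws)[1]
  fd <- withr::local_tempdir()
  writeFCS(ws@samples[[1]], file.path(fd, sid))
  wsp <- withr::local_tempfile(fileext = ".wsp")
  writeFlowjo(ws, wsp)   # embeds the custom matrix in the sample subtree
  ws2 <- readFlowjo(wsp, fd)
  # the FCS keyword is still present, but the workspace matrix is chosen
  expect_true("$SPILLOVER" %in% names(keywords(ws2@samples[[sid]])))
  chosen <- selectCompensation(ws2@samples[[sid]], ws2, "auto")
  expect_equal(chosen@S, ws@compensations[["spill"]]@S)
  expect_identical(workspaceStats(ws2)$count, workspaceStats(ws)$count)
})

test_that("cluster export succeeds for flowjo and fails elsewhere", {
  ws <- tinyWorkspace(nEvents = 120)
  sid <- sampleIds(ws)[1]
  res <- resolveGating(ws, sid)
  np <- sum(res[["root/cells"]])
  tree <- attachClusters(gatingTreeFor(ws, sid), "root/cells",
                         rep_len(c(1L, 2L, 2L), np), parentCount = np)
  wsC <- workspace(samples = ws@samples, template = tree,
                   transforms = ws@transforms)
  wsp <- withr::local_tempfile(fileext = ".wsp")
  expect_no_error(writeFlowjo(wsC, wsp))
  fd <- withr::local_tempdir()
  writeFCS(ws@samples[[1]], file.path(fd, sid))
  ws2 <- readFlowjo(wsp, fd)
  expect_identical(workspaceStats(ws2)$count, workspaceStats(wsC)$count)
  for (writer in list(writeGatingML, writeCytobank)) {
    err <- tryCatch(writer(wsC, withr::local_tempfile(fileext = ".xml")),
                    cytoError = identity)
    expect_identical(errorToken(err), "UNSUPPORTED_EXPORT")
  }
})

test_that("Cytobank dialect round-trips, scoped per sample, via ACS", {
  fx <- randomGatingFixture(24)
  ws <- fx$workspace
  sid <- sampleIds(ws)[1]
  # template (unscoped) document
  xf <- withr::local_tempfile(fileext = ".xml")
  writeCytobank(ws, xf, experiment = "unit test experiment")
  ws2 <- readCytobank(xf)
  expect_identical(attr(ws2, "experiment"), "unit test experiment")
  ws2 <- setSamples(ws2, ws@samples)
  expect_identical(resolveGating(ws2, sid), resolveGating(ws, sid))
  # logicle parameters survive as exact decimal text
  lg <- Filter(function(d) d@family == "logicle", ws@transforms)
  if (length(lg))
    expect_identical(ws2@transforms[[lg[[1]]@transformId]]@W, lg[[1]]@W)

  # two-sample ACS with per-sample scoped trees
  s2 <- ws@samples[[1]]
  s2@sampleId <- "second.fcs"
  s2@keywords[["$FIL"]] <- "second.fcs"
  trees <- list(gatingTreeFor(ws, sid), gatingTreeFor(ws, sid))
  names(trees) <- c(sid, "second.fcs")
  wsM <- workspace(samples = list(ws@samples[[1]], s2), trees = trees,
                   transforms = ws@transforms,
                   compensations = ws@compensations,
                   dialect = "cytobank")
  acs <- withr::local_tempfile(fileext = ".acs")
  packACS(wsM, acs)
  wsA <- readCytobank(acs)
  expect_length(wsA@samples, 2)
  expect_setequal(names(wsA@trees), c(sid, "second.fcs"))
  expect_identical(workspaceStats(wsA)$count, workspaceStats(wsM)$count)
  # a zip with FCS members but no XML workspace is malformed
  fd <- withr::local_tempdir()
  writeFCS(ws@samples[[1]], file.path(fd, sid))
  zz <- withr::local_tempfile(fileext = ".zip")
  packZip(zz, setNames(file.path(fd, sid), sid))
  expect_error(readCytobank(zz), class = "cyto_malformed_container")
})

test_that("ellipsoid polygonization error is small on boundary-adjacent events", {
  set.seed(30)
  g <- ellipsoidGate(list(gateDimension("x"), gateDimension("y")),
                     c(0.5, 0.5), matrix(c(0.02, 0.006, 0.006, 0.015), 2),
                     2)
  poly <- polygonizeEllipsoid(g, 100L)
  # events concentrated near the boundary shell
  theta <- runif(10000, 0, 2 * pi)
  r <- sqrt(g@distSq) * runif(10000, 0.9, 1.1)
  R <- chol(g@cov)
  pts <- t(t(R) %*% rbind(r * cos(theta), r * sin(theta)) + g@mu)
  exact <- inEllipsoid(pts, g)
  approx <- inPolygon(pts, poly)
  expect_lt(mean(exact != approx), 0.005)
})

test_that("cross-dialect conversion preserves counts on the standard fixture", {
  fx <- standardFixture(n = 1500)
  ws <- fx$workspace
  sid <- sampleIds(ws)[1]
  st0 <- workspaceStats(ws)
  fd <- withr::local_tempdir()
  writeFCS(ws@samples[[1]], file.path(fd, sid))
  g <- withr::local_tempfile(fileext = ".xml")
  writeGatingML(ws, g)
  out <- withr::local_tempfile(fileext = ".wsp")
  convertWorkspace(g, "gatingml", "flowjo", out, fcsDir = fd)
  ws2 <- readFlowjo(out, fd)
  expect_identical(workspaceStats(ws2)$count, st0$count)
  out2 <- withr::local_tempfile(fileext = ".xml")
  convertWorkspace(out, "flowjo", "cytobank", out2, fcsDir = fd)
  ws3 <- readCytobank(out2, fcsDir = fd)
  expect_identical(workspaceStats(ws3)$count, st0$count)
})
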
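test_that("simulation is deterministic under a fixed seed", {
  fx1 <- standardFixture(n = 500)
  fx2 <- standardFixture(n = 500)
  expect_identical(eventMatrix(fx1$workspace@samples[[1]]),
                   eventMatrix(fx2$workspace@samples[[1]]))
  expect_identical(fx1$labels, fx2$labels)
  # and FCS payloads are byte-identical
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeFCS(fx1$workspace@samples[[1]], f1)
  writeFCS(fx2$workspace@samples[[1]], f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("component counts follow the multinomial within 3 binomial SDs", {
  fx <- standardFixture(n = 10000)
  w <- c(0.5, 0.3, 0.2)
  counts <- tabulate(fx$labels, 3)
  for (i in 1:3) {
    sd <- sqrt(10000 * w[i] * (1 - w[i]))
    expect_lt(abs(counts[i] - 10000 * w[i]), 3 * sd)
  }
})

test_that("a tight single component recovers its mean", {
  spec <- syntheticSpec(5000,
                        list(list(weight = 1, mean = c(100, 200),
                                  cov = diag(2) * 1e-6)),
                        c("A", "B"), seed = 3L)
  sim <- simulateSample(spec)
  expect_lt(max(abs(colMeans(eventMatrix(sim$sample)) - c(100, 200))),
            1e-2)
  expect_true(all(sim$labels == 1L))
})

test_that("invalid specs are rejected with the offending field", {
  expect_error(syntheticSpec(100,
                             list(list(weight = 0.5, mean = 0, cov = 1),
                                  list(weight = 0.4, mean = 0, cov = 1)),
                             "A"),
               class = "cyto_invalid_spec")
  expect_error(syntheticSpec(100,
                             list(list(weight = 1, mean = c(0, 0),
                                       cov = matrix(c(1, 2, 2, 1), 2))),
                             c("A", "B")),
               class = "cyto_invalid_spec")
})

test_that("overlapping components trigger an overlap warning, not an error", {
  spec <- syntheticSpec(200,
                        list(list(weight = 0.5, mean = c(0, 0), cov = diag(2)),
                             list(weight = 0.5, mean = c(0, 0), cov = diag(2))),
                        c("A", "B"), seed = 4L)
  expect_warning(referenceWorkspace(spec), "overlap")
})

test_that("chi-square coverage radii recover labels at the expected rate", {
  fx <- standardFixture(n = 4000)
  ws <- referenceWorkspace(fx$spec, coverageRadius2 = qchisq(0.999, 4))
  labels <- attr(ws, "labels")
  res <- resolveGating(ws, sampleIds(ws)[1])
  for (i in 1:3) {
    f <- fMeasure(labels == i, res[[paste0("root/pop", i)]])
    expect_gte(f$F, 0.999 - 3 * sqrt(0.001 / (4000 / 3)))
  }
})

test_that("YAML specs parse into equivalent fixtures", {
  yamlPath <- system.file("extdata", "standard_fixture.yaml",
                          package = "cytoBridge")
  spec <- readSpecYaml(yamlPath)
  expect_identical(spec$nEvents, 10000L)
  expect_identical(spec$channels, c("FL1-A", "FL2-A", "FL3-A", "FL4-A"))
  expect_equal(spec$spillover@S[1, 2], 0.12)
  spec2 <- readSpecYaml(yamlPath, seed = 11L)
  expect_identical(spec2$seed, 11L)
  # the YAML fixture is the standard fixture
  builtin <- standardFixture(n = 10000)$spec
  expect_equal(spec$components, builtin$components)
  expect_equal(spec$spillover@S, builtin$spillover@S)
})

test_that("fixture bundles write FCS, workspace and labels consistently", {
  spec <- syntheticSpec(400, standardFixture(n = 10)$spec$components,
                        c("FL1-A", "FL2-A", "FL3-A", "FL4-A"), seed = 5L)
  dir <- withr::local_tempdir()
  paths <- writeFixtureBundle(spec, dir)
  expect_true(all(file.exists(paths)))
  labs <- utils::read.csv(paths[["labels"]])
  s <- readFCS(paths[["fcs"]])
  expect_identical(nrow(labs), nEvents(s))
  ws <- readGatingML(paths[["workspace"]])
  ws <- setSamples(ws, list(s))
  res <- resolveGating(ws, sampleId(s))
  st <- computeStats(res, gatingTreeFor(ws, sampleId(s)), nEvents(s))
  expect_identical(st$count[-1], unname(c(table(labs$label))))
})
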
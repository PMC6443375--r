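test_that("$SPILLOVER keyword parsing handles normalization and truncation", {
  sm <- parseSpilloverKeyword("2,FL1,FL2,1,0.1,0.05,1")
  expect_identical(sm@detectors, c("FL1", "FL2"))
  expect_equal(unname(sm@S), matrix(c(1, 0.05, 0.1, 1), 2))
  # stored with diagonal 2: row-scaled back to unit diagonal
  sm2 <- parseSpilloverKeyword("2,FL1,FL2,2,0.2,0.1,2")
  expect_equal(unname(sm2@S), matrix(c(1, 0.05, 0.1, 1), 2))
  expect_error(parseSpilloverKeyword("2,FL1,FL2,1,0.1"),
               class = "cyto_malformed_spillover")
  # keyword serialization round-trips bit-exactly
  expect_equal(parseSpilloverKeyword(buildSpilloverKeyword(sm))@S, sm@S)
})

test_that("compensation solves observed = true x S on detector columns", {
  sm <- spilloverMatrix(c("FL1", "FL2"),
                        matrix(c(1, 0.1, 0, 1), 2, byrow = TRUE))
  obs <- matrix(c(10, 10), 1, dimnames = list(NULL, c("FL1", "FL2")))
  expect_equal(unname(compensate(obs, sm)), matrix(c(10, 9), 1))
  # identity spillover leaves everything exactly unchanged
  id <- spilloverMatrix(c("FL1", "FL2"), diag(2))
  expect_identical(compensate(obs, id), obs)
  expect_error(spilloverMatrix(c("A", "B"), matrix(1, 2, 2)) |>
                 compensate(events = obs, channels = c("FL1", "FL2")),
               class = "cyto_unresolved_channel")
  sing <- spilloverMatrix(c("FL1", "FL2"),
                          matrix(c(1, 1, 1, 1), 2) + diag(2) * 1e-14)
  expect_error(compensate(obs, sing), class = "cyto_singular_matrix")
})

test_that("compensating after spillover recovers inputs, other columns bitwise", {
  set.seed(9)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    S <- diag(k)
    off <- which(row(S) != col(S))
    S[off] <- runif(length(off), 0, 1 / (2 * k))  # diagonally dominant
    dets <- paste0("FL", seq_len(k))
    sm <- spilloverMatrix(dets, S)
    X <- matrix(rnorm(200 * (k + 1), 100, 50), ncol = k + 1,
                dimnames = list(NULL, c(dets, "FSC-A")))
    Y <- applySpillover(X, sm)
    Z <- compensate(Y, sm)
    expect_lt(max(abs(Z[, dets] - X[, dets]) / pmax(1, abs(X[, dets]))),
              1e-9)
    expect_identical(Z[, "FSC-A"], X[, "FSC-A"])   # column locality
    expect_identical(Y[, "FSC-A"], X[, "FSC-A"])
  }
})

test_that("compensation selection follows the documented precedence", {
  fx <- standardFixture(n = 200)
  ws <- fx$workspace
  s <- ws@samples[[1]]
  # explicit gate reference wins
  expect_equal(selectCompensation(s, ws, "spill")@S,
               ws@compensations[["spill"]]@S)
  # uncompensated always forces identity
  expect_true(cytoBridge:::isIdentitySpillover(
    selectCompensation(s, ws, "uncompensated")))
  # auto: workspace per-sample custom matrix beats the FCS keyword
  custom <- spilloverMatrix(channelNames(s), diag(4) + 0.01 -
                              diag(4) * 0.01)
  ws2 <- ws
  ws2@compensations[[s@sampleId]] <- custom
  expect_equal(selectCompensation(s, ws2, "auto")@S, custom@S)
  # auto with no custom matrix: the $SPILLOVER keyword
  expect_equal(selectCompensation(s, ws, "auto")@S,
               parseSpilloverKeyword(keywords(s)[["$SPILLOVER"]])@S)
  # auto with neither: identity
  s2 <- cytoSample("plain.fcs", matrix(0, 1, 2), c("A", "B"))
  expect_true(cytoBridge:::isIdentitySpillover(
    selectCompensation(s2, workspace(), "auto")))
  # unresolved explicit reference errors
  expect_error(selectCompensation(s, ws, "compX"),
               class = "cyto_unresolved_compensation")
})
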
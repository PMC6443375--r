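test_that("linear and log transforms hit their anchor points", {
  expect_equal(flin(0, T = 1000, A = 0), 0)
  expect_equal(flin(1000, T = 1000, A = 0), 1)
  expect_equal(flin(500, T = 1000, A = 0), 0.5)
  expect_equal(flog(1000, T = 1000, M = 4.5), 1)
  expect_equal(flog(1000 * 10^-4.5, T = 1000, M = 4.5), 0)
  # non-positive inputs clamp one decade below the display floor
  expect_equal(flog(-5, T = 1000, M = 4.5),
               flog(1000 * 10^(-5.5), T = 1000, M = 4.5))
  expect_false(any(is.nan(flog(c(-10, 0, 1e-30), T = 1000, M = 4.5))))
})

test_that("asinh transform anchors and oddness hold", {
  for (A in c(0, 0.3, 1)) {
    expect_equal(fasinh(0, T = 1000, M = 4, A = A), A / (4 + A))
    expect_equal(fasinh(1000, T = 1000, M = 4, A = A), 1)
    expect_equal(fasinh(-1000, T = 1000, M = 4, A = A),
                 (A - 4) / (A + 4))
  }
})

test_that("logicle forward map hits top of scale and inverts the biexponential", {
  expect_equal(logicleForward(262144, T = 262144, W = 0.5, M = 4.5), 1,
               tolerance = 1e-12)
  y <- seq(0.01, 0.99, by = 0.01)
  x <- logicleInverse(y, T = 262144, W = 0.5, M = 4.5)
  expect_lt(max(abs(logicleForward(x, T = 262144, W = 0.5, M = 4.5) - y)),
            1e-8)
})

test_that("logicle forward agrees with an independent bisection oracle", {
  xs <- c(0, -1000, -100, 100, 5000, 262144,
          logicleInverse(seq(0.05, 0.95, by = 0.1),
                         T = 262144, W = 0.5, M = 4.5))
  got <- logicleForward(xs, T = 262144, W = 0.5, M = 4.5)
  ref <- oracleLogicleForward(xs, T = 262144, W = 0.5, M = 4.5)
  expect_lt(max(abs(got - ref)), 1e-9)
})

test_that("makeTransform dispatches families and rejects bad parameters", {
  lin <- makeTransform(transformDef("l", "linear", T = 1000, A = 0))
  expect_equal(lin$forward(500), 0.5)
  expect_error(transformDef("bad", "logicle", T = 262144, M = 4.5, W = 3),
               class = "cyto_invalid_transform")   # W > M/2
  expect_error(makeTransform("nonsense"),
               class = "cyto_unsupported_transform")
  # asinh inverse/forward sweep at spec tolerance
  set.seed(20)
  tf <- makeTransform(transformDef("a", "asinh", T = 10000, M = 4.5,
                                   A = 0.2))
  x <- runif(1e5, -10000, 1e5)
  err <- abs(tf$inverse(tf$forward(x)) - x) / pmax(1, abs(x))
  expect_lt(max(err), 1e-8)
})

test_that("all families are strictly increasing over random parameter sets", {
  set.seed(33)
  for (i in 1:25) {
    fam <- sample(c("linear", "log", "asinh", "logicle"), 1)
    T <- 10^runif(1, 2, 6)
    M <- runif(1, 3, 5.5)
    A <- runif(1, 0, if (fam == "logicle") 0.5 else 1.5)
    W <- runif(1, 0, M / 2 - 0.01)
    def <- transformDef("t", fam, T = T, M = M, A = A, W = W)
    tf <- makeTransform(def)
    xs <- sort(c(0, T, runif(500,
                             if (fam == "log") T * 10^(-M) else -T, 2 * T)))
    ys <- tf$forward(xs)
    expect_true(all(diff(ys) > 0) || fam == "log" && all(diff(ys) >= 0),
                info = sprintf("family %s not increasing (seed case %d)",
                               fam, i))
  }
})

test_that("transforms map the display range into [0, 1]", {
  for (def in list(transformDef("a", "linear", T = 1000, A = 50),
                   transformDef("b", "log", T = 10000, M = 4),
                   transformDef("c", "asinh", T = 262144, M = 4.5, A = 0.5),
                   transformDef("d", "logicle", T = 262144, M = 4.5,
                                A = 0.2, W = 0.5))) {
    tf <- makeTransform(def)
    bottom <- tf$inverse(0)
    xs <- seq(bottom, def@T, length.out = 200)
    ys <- tf$forward(xs)
    expect_true(all(ys >= -1e-9 & ys <= 1 + 1e-9), info = def@family)
  }
})

test_that("logicle approaches the log transform as W -> 0 above the floor", {
  T <- 262144; M <- 4.5
  xs <- 10^seq(log10(T * 10^(-M + 1)), log10(T), length.out = 200)
  diff <- abs(logicleForward(xs, T = T, W = 0, M = M) - flog(xs, T, M))
  expect_lt(max(diff), 1e-3)
})

test_that("FlowJo width-basis declarations map onto valid logicles", {
  def <- flowjoBiexpToLogicle("b1", T = 262144, M = 4.5, widthBasis = -10)
  expect_identical(def@family, "logicle")
  expect_true(def@W >= 0 && def@W <= def@M / 2)
  tf <- makeTransform(def)
  expect_equal(tf$forward(262144), 1, tolerance = 1e-10)
})
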
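# Display-scale transforms in the Gating-ML 2.0 parameterization.
# All forward maps send [bottom-of-scale, T] into [0, 1] and are
# strictly increasing; each family has a closed-form inverse except the
# logicle, whose forward map is defined implicitly as the inverse of the
# Parks-Moore biexponential and is computed by safeguarded root-finding.

LN10 <- log(10)

#' Linear display transform: y = (x + A) / (T + A)
#'
#' @param x raw values.
#' @param T top-of-scale value (> 0).
#' @param A additional negative range (>= 0); flin(T) = 1, flin(-A) = 0.
#' @return Transformed values.
#' @export
flin <- function(x, T, A = 0) (x + A) / (T + A)

flinInv <- function(y, T, A = 0) y * (T + A) - A

# Inputs at or below zero are clamped one decade below the display
# floor rather than producing NaN: compensated FCS data routinely go
# negative and import must not fail.
flogFloor <- function(T, M) T * 10^(-M - 1)

#' Log display transform: y = log10(x / T) / M + 1
#'
#' @param x raw values; values <= 0 are clamped to `T * 10^(-M-1)`.
#' @param T top-of-scale value (> 0).
#' @param M display decades (> 0); flog(T) = 1, flog(T * 10^-M) = 0.
#' @return Transformed values.
#' @export
flog <- function(x, T, M) {
  x <- pmax(x, flogFloor(T, M))
  log10(x / T) / M + 1
}

flogInv <- function(y, T, M) T * 10^(M * (y - 1))

#' Inverse hyperbolic sine display transform
#'
#' `y = (asinh(x * sinh(M ln10) / T) + A ln10) / ((M + A) ln10)`;
#' fasinh(T) = 1, fasinh(0) = A / (M + A).
#'
#' @param x raw values.
#' @param T top-of-scale value (> 0).
#' @param M display decades (> 0).
#' @param A additional negative decades (>= 0).
#' @return Transformed values.
#' @export
fasinh <- function(x, T, M, A = 0) {
  (asinh(x * sinh(M * LN10) / T) + A * LN10) / ((M + A) * LN10)
}

fasinhInv <- function(y, T, M, A = 0) {
  T * sinh(y * (M + A) * LN10 - A * LN10) / sinh(M * LN10)
}

# ---- logicle ----------------------------------------------------------

# Biexponential parameters (a, b, c, d, f) from (T, W, M, A), following
# the Parks-Moore construction: b = (M + A) ln10; d solves
# 2 (ln d - ln b) + w (b + d) = 0 with w = W / (M + A) (d = b when
# w = 0); the remaining constants pin B(1) = T and B(x1) = 0 with the
# linearization width symmetric about x1.
logicleParams <- function(T, W, M, A = 0) {
  if (T <= 0 || M <= 0 || W < 0 || W > M / 2 || A < 0 || A + W > M)
    cytoStop("INVALID_TRANSFORM", sprintf(
      "invalid logicle parameters T=%g W=%g M=%g A=%g (need T>0, M>0, 0<=W<=M/2, A>=0, A+W<=M)",
      T, W, M, A))
  b <- (M + A) * LN10
  w <- W / (M + A)
  x2 <- A / (M + A)
  x1 <- x2 + w
  x0 <- x2 + 2 * w
  d <- if (w == 0) b else {
    g <- function(d) 2 * (log(d) - log(b)) + w * (b + d)
    stats::uniroot(g, lower = b * 1e-12, upper = b, tol = 1e-15 * b,
                   maxiter = 1000L)$root
  }
  ca <- exp(x0 * (b + d))
  fa <- exp(b * x1) - ca * exp(-d * x1)
  a <- T / (exp(b) - fa - ca * exp(-d))
  list(a = a, b = b, c = ca * a, d = d, f = fa * a, w = w, x2 = x2)
}

biexp <- function(y, p) p$a * exp(p$b * y) - p$c * exp(-p$d * y) - p$f
biexpDeriv <- function(y, p) p$a * p$b * exp(p$b * y) + p$c * p$d * exp(-p$d * y)

#' Logicle display transform (forward) and its biexponential inverse
#'
#' The inverse is the closed-form Parks-Moore biexponential
#' `B(y) = a e^(b y) - c e^(-d y) - f`; the forward map solves
#' `B(y) = x` by vectorized Newton iteration safeguarded by bisection
#' over the bracket `[-A/(M+A) - 1, 2]`, to an accuracy of
#' `1e-10 * T` on the raw axis so precision is uniform across the scale.
#'
#' @param x raw values (forward) .
#' @param y display-scale values (inverse).
#' @param T top-of-scale value (> 0); logicleForward(T) = 1.
#' @param W linearization width in decades (0 <= W <= M/2).
#' @param M display decades (> 0).
#' @param A additional negative decades (>= 0, A + W <= M).
#' @return Transformed (forward) or raw (inverse) values.
#' @examples
#' y <- logicleForward(c(0, 100, 262144), T = 262144, W = 0.5, M = 4.5)
#' logicleInverse(y, T = 262144, W = 0.5, M = 4.5)
#' @export
logicleForward <- function(x, T, W, M, A = 0) {
  p <- logicleParams(T, W, M, A)
  n <- length(x)
  if (!n) return(numeric(0))
  # well inside the contracted 1e-10 * T so that accuracy on the
  # display scale stays below 1e-9 even where B'(y) is small
  tol <- 1e-13 * T
  lo <- rep(-p$x2 - 1, n)
  hi <- rep(2, n)
  # bracket sanity: B is increasing; widen either end for values beyond
  # the nominal display range
  bad <- biexp(hi, p) < x
  while (any(bad)) { hi[bad] <- hi[bad] + 1; bad <- biexp(hi, p) < x }
  bad <- biexp(lo, p) > x
  while (any(bad)) { lo[bad] <- lo[bad] - 1; bad <- biexp(lo, p) > x }
  y <- (lo + hi) / 2
  fy <- biexp(y, p) - x
  for (iter in seq_len(200L)) {
    active <- abs(fy) > tol
    if (!any(active)) break
    # maintain bracket
    lo[active & fy < 0] <- y[active & fy < 0]
    hi[active & fy > 0] <- y[active & fy > 0]
    step <- fy / biexpDeriv(y, p)
    cand <- y - step
    outside <- active & (cand <= lo | cand >= hi | !is.finite(cand))
    cand[outside] <- (lo[outside] + hi[outside]) / 2
    y[active] <- cand[active]
    fy[active] <- biexp(y[active], p) - x[active]
  }
  y
}

#' @rdname logicleForward
#' @export
logicleInverse <- function(y, T, W, M, A = 0) {
  p <- logicleParams(T, W, M, A)
  biexp(y, p)
}

# ---- dispatch ---------------------------------------------------------

#' Build a forward/inverse transform pair from a definition
#'
#' @param def a [TransformDef-class], or the string `"identity"`.
#' @return A list with elements `forward` and `inverse`, both
#'   vectorized functions, satisfying `inverse(forward(x)) == x` to
#'   1e-8 relative on the family's domain.
#' @examples
#' tf <- makeTransform(transformDef("t1", "asinh", T = 1000, M = 4))
#' tf$inverse(tf$forward(c(-10, 0, 1000)))
#' @export
makeTransform <- function(def) {
  if (identical(def, "identity"))
    return(list(forward = identity, inverse = identity))
  if (!is(def, "TransformDef"))
    cytoStop("UNSUPPORTED_TRANSFORM", "expected a TransformDef or 'identity'")
  v <- validObject(def, test = TRUE)
  if (!isTRUE(v)) cytoStop("INVALID_TRANSFORM", paste(v, collapse = "; "))
  T <- def@T; M <- def@M; A <- def@A; W <- def@W
  switch(def@family,
    linear = list(forward = function(x) flin(x, T, A),
                  inverse = function(y) flinInv(y, T, A)),
    log = list(forward = function(x) flog(x, T, M),
               inverse = function(y) flogInv(y, T, M)),
    asinh = list(forward = function(x) fasinh(x, T, M, A),
                 inverse = function(y) fasinhInv(y, T, M, A)),
    logicle = {
      logicleParams(T, W, M, A)  # fail fast on bad parameters
      list(forward = function(x) logicleForward(x, T, W, M, A),
           inverse = function(y) logicleInverse(y, T, W, M, A))
    },
    cytoStop("UNSUPPORTED_TRANSFORM",
             paste0("unknown transform family '", def@family, "'"))
  )
}

# Gating-ML 2.0 conventional defaults, used when a dialect omits scale
# parameters; the substitution is logged.
defaultLogicle <- function(transformId = "logicle_default") {
  cytoLog("INFO", "transform '", transformId,
          "': defaulting to logicle T=262144 W=0.5 M=4.5 A=0")
  transformDef(transformId, "logicle", T = 262144, M = 4.5, A = 0, W = 0.5)
}

#' Map a FlowJo biexponential declaration onto the logicle family
#'
#' FlowJo workspaces declare biexponential axes by top-of-scale `T`,
#' decades `M` and a width basis `wb`; the linearization width is
#' derived as `W = max(0, (M - log10(T / |wb|)) / 2)`, a documented
#' approximation of FlowJo's rendering.
#'
#' @param transformId id for the resulting definition.
#' @param T top of scale.
#' @param M display decades.
#' @param widthBasis FlowJo width basis (typically negative).
#' @return A logicle [TransformDef-class].
#' @export
flowjoBiexpToLogicle <- function(transformId, T, M, widthBasis) {
  W <- if (widthBasis == 0) 0 else max(0, (M - log10(T / abs(widthBasis))) / 2)
  W <- min(W, M / 2)
  transformDef(transformId, "logicle", T = T, M = M, A = 0, W = W)
}
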
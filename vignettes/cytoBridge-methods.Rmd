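---
title: "cytoBridge: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cytoBridge: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytoBridge)
```

# The problem

Hierarchical gating is deceptively stateful. A gate drawn on a
bivariate plot implicitly conditions on every upstream population, on
the display transform of each axis, and on the spillover matrix that
was active when the analyst drew it. Reproducing a gated analysis from
raw FCS files therefore requires capturing all of that context, and
each analysis platform captures it in its own Gating-ML variant.
cytoBridge maintains one in-memory representation — a `Workspace`
holding samples, gating trees, a transform registry and a compensation
registry — that every dialect reader produces and every writer
consumes, so conversion between dialects is read-then-write through a
single semantic model.

# The gating model

Population membership is defined recursively: the reserved root node
contains every event, and each child contains the events that are in
its parent *and* satisfy its gate, with the gate evaluated on channels
prepared by (1) spillover compensation and (2) the per-dimension
display transform. Two conventions are fixed package-wide:

* **Boundary inclusivity.** Every geometric predicate treats the
  boundary as inside ("on the line = in the gate"). For quadrant gates
  the tie goes to the "+" side, which makes the four quadrants an
  exact partition — a property the test suite asserts on random data.
* **Internal coordinates are always on the transformed scale.**
  Dialects that store raw-scale coordinates (FlowJo) are converted at
  parse time, so there is exactly one evaluation path.

Boolean gates may reference any population in the tree, not just
siblings; evaluation is topologically ordered and reference cycles are
reported as errors listing the cycle. Cluster (index-defined)
populations are opaque membership vectors attached under a parent:
one child per nonzero label, partitioning the labeled events.

## Compensation

The spillover convention is the FCS `$SPILLOVER` one: rows are true
signals, columns are detectors, observed = true × S, so compensation
right-multiplies the detector sub-matrix by `solve(S)`. Only detector
columns are touched; everything else is returned bit-identical.
Matrix selection per sample mirrors platform behavior and is strictly
prioritized: an explicit gate reference wins, then a per-sample custom
matrix registered in the workspace (as FlowJo embeds them), then the
FCS `$SPILLOVER`/`$SPILL` keyword, then identity. A gate dimension
marked `uncompensated` always means identity. Import never exposes
knobs to override matrices or transforms — a faithful reproduction is
only faithful if the context cannot be quietly changed — so
modifications are explicit post-import edits. Each selection is logged
at INFO with its provenance.

## Transforms

The four families follow the Gating-ML 2.0 parameterization
(`T` top of scale, `M` decades, `A` negative decades, `W` logicle
linearization width). Numerical choices:

* `flog` clamps inputs ≤ 0 to `T·10^(−M−1)` — one decade below the
  display floor — instead of erroring, because compensated data
  routinely go negative and import must not fail.
* The logicle forward map has no closed form; it solves
  `B(y) = x` for the Parks–Moore biexponential by vectorized Newton
  iteration safeguarded by bisection. The bracket starts at
  `[−A/(M+A) − 1, 2]` and is widened adaptively when a value lies
  beyond it (wide-`W`, strongly negative inputs need a deeper bracket).
  Convergence is declared at `10⁻¹³·T` on the raw axis — comfortably
  inside the `10⁻¹⁰·T` contract — so that accuracy on the display
  scale stays below 10⁻⁹ even where `B′(y)` is small. The `d`
  parameter solves `2(ln d − ln b) + w(b + d) = 0` by `uniroot` at
  relative tolerance 10⁻¹⁵.
* As `W → 0` with `A = 0` the logicle approaches the plain log
  transform, but only away from the display floor: at `x = T·10^{−M}`
  the exact `w = 0` logicle is `2a·sinh(by)`, which differs from
  `flog` by ≈ 0.046 display units there. The agreement property is
  therefore asserted from one decade above the floor, where it holds
  to 10⁻³.
* Unused parameters are canonicalized at construction (`A = 0` for
  log, `W = 0.5` outside logicle) so definitions compare equal after a
  serialization round-trip that only writes family-relevant
  parameters.
* FlowJo biexponential declarations are mapped onto the logicle family
  with `W = max(0, (M − log10(T/|wb|))/2)` from the declared width
  basis `wb`. This is a documented approximation of FlowJo's
  rendering, not an exact correspondence.

## Dialects

The capability matrix (`dialectCapabilities()`) is explicit data:
coordinate scale (raw for FlowJo, transformed otherwise), native
ellipse support, per-sample trees, per-gate compensation references,
and cluster support. Writers consult it and fail loudly
(`UNSUPPORTED_EXPORT`) instead of silently dropping features; only the
FlowJo dialect accepts cluster populations (as enumerated derived
populations), matching the asymmetric platform support for
high-dimensional clustering results.

Two design choices deserve explanation:

* **Ellipsoids in the FlowJo dialect.** The dialect lacks a native
  ellipse element here, so 2-D ellipsoids are exported as inscribed
  100-vertex polygons. A polygon is not an ellipse, though: a sliver
  of boundary-adjacent events (measured at well under 0.5% in the
  tests) would change membership, which would break the exact
  round-trip contract. The writer therefore also embeds the exact
  quadratic form (transformed-scale μ, C, D²) in the gate's
  custom-information block; our reader prefers it when present and
  falls back to the polygon for foreign files. Ellipsoids in more than
  two dimensions — which FlowJo cannot display at all — use a
  bounding-box carrier with the same embedded exact form.
* **Numeric serialization** uses 17 significant digits everywhere, so
  re-parsed doubles are bit-identical and membership after a
  write/read cycle is exactly reproducible. FlowJo raw-scale
  coordinates pass through an inverse/forward transform pair on top of
  that; the residual is at the last-ulp level and can only matter for
  an event exactly on a gate boundary.

Sample-to-gate matching across dialects is keyed by `$FIL`, then exact
filename, then declared URI; an ambiguous match is an error, never a
guess. ACS containers are handled minimally: zip extraction and member
discovery by extension, with the TOC manifest optional. Because the
environment provides no zip-writing tool, the container writer is a
small ZIP implementation emitting stored (uncompressed) entries with
table-driven CRC-32 — adequate for desk-scale bundles and readable by
any unzip.

# The synthetic-data module

Real demonstration data for this class of tool are external downloads;
the fixture module replaces them with a generative model whose ground
truth is known by construction. `simulateSample()` draws events from a
Gaussian mixture on the linear (raw) scale, applies a known spillover
(observed = true × S), rounds to 32-bit float — the precision FCS data
type F can represent, which makes FCS round-trips bit-exact — and
records each event's component of origin. `referenceWorkspace()`
builds the matching analysis: one ellipsoid gate per component at the
generating parameters with squared radius `D²`, the spillover
registered and referenced, and per-channel asinh display transforms
declared. The gates live on the compensated raw scale, because that is
the scale on which the mixture is Gaussian — the asinh image of a
Gaussian is not an ellipsoid, so exact label recovery is only
well-defined there.

The standard fixture is three components with weights (0.5, 0.3, 0.2)
over four channels, n = 10⁴, seed 42, spillover off-diagonals ≤ 0.15,
and component means separated by 12 within-component standard
deviations. The separation and the default coverage radius
`D² = qchisq(1 − 10⁻⁷, d)` were chosen together, a priori, from the
two tail bounds that exact recovery needs: the radius captures each
component's own n events essentially completely
(n · 10⁻⁷ expected escapes), while the separation keeps foreign events
out of the enlarged ellipsoids (a foreign event would need a ≥ 5.8σ
excursion). At 8σ separation with conventional χ²₀.₉₉₉ radii those
two requirements collide; the wider geometry makes both hold
simultaneously. The generator uses an explicitly versioned RNG
(Mersenne-Twister, inversion-method normals) set locally, so a seed
fully determines a fixture across sessions and platforms.

What the fixtures do **not** emulate: doublets, debris, acquisition
drift, non-linear spectral effects, or heavy-tailed populations.
Passing the round-trip and recovery suites therefore demonstrates
correctness of the interchange and gating machinery, not robustness of
any gating strategy to real instrument artifacts.

`randomGatingFixture()` generates the adversarial counterpart used by
the round-trip tests: events uniform on the display scale pushed back
through randomly assigned per-channel transforms, optional random
spillover, and random trees (depth ≤ 3) mixing all gate geometries and
boolean gates. One transform per channel and a single spillover per
workspace keep the generated feature set inside every dialect's
capability envelope — the FlowJo layout cannot express per-gate
transform conflicts, and the writer refuses them rather than guessing.

# Problem sizes and verification

The shipped test suite runs the full property set at the sizes the
package's own acceptance script uses: 50 randomized workspaces × 3
dialect round-trips (exact membership equality), all 6 ordered dialect
conversion pairs on the standard fixture (exact count equality),
ground-truth recovery at n = 10⁴ (F ≥ 0.999 with spillover; exactly
1.0 with identity spillover and gates at the generating parameters),
10⁶ random points per transform family (inverse-of-forward within
10⁻⁸ relative), logicle versus an independent plain-bisection oracle
at 10³ points (within 10⁻⁹), 100 random diagonally dominant spillover
matrices (recovery within 10⁻⁹ relative), 20 random polygons × 10⁴
points against an independent ray-casting oracle, 50 random trees
against a naive per-event recursive evaluator, and 200 random FCS
round-trips at float32 precision in both byte orders. The whole suite
completes in well under a minute on a single CPU.

# Known limitations

* Diva workspaces are not supported (the format is undocumented), nor
  are FlowJo v9 Mac-format workspaces, Hyperlog/Splitscale transforms,
  or FCS 2.0 / `$DATATYPE D` / multi-dataset FCS files.
* The Cytobank dialect's extensions (experiment metadata, per-gate
  sample scoping) are pinned by this package's own fixtures; foreign
  Cytobank exports exercising undocumented corners of that vocabulary
  may need reader extensions.
* Event storage is in-memory; there is no disk-backed mode.
* Gate coordinates written for FlowJo are raw-scale by convention.
  Rendering agreement with FlowJo at single-event granularity on gate
  boundaries is not guaranteed (FlowJo's own boundary handling is not
  specified).
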
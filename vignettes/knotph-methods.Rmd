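---
title: "Methods: persistent homology and geometry of random polygonal knots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: persistent homology and geometry of random polygonal knots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model, the algorithms, the tunable parameters
and the design choices behind `knotph`, in the spirit of the methods
sections of modelling packages: what is computed, under which assumptions,
and what the included tests do and do not establish.

## The model

A knot embedding is a closed equilateral polygon in 3-space: an ordered
cycle of $n$ vertices with every edge of unit length, so the length
$\ell(K)$ equals the edge count. The topology of interest is that of the
metric neighbourhood $\nu_t(K)$ — the thickened curve — as the radius $t$
grows: its first homology starts at rank 1 (the knot's own loop), gains
classes whenever the thickening touches itself, and dies entirely once the
neighbourhood fills the surrounding volume.

The package approximates this evolution combinatorially: the polygon is
interpolated to a point cloud $P(K)$ with $s = 10$ samples per unit edge
(spacing exactly $0.1$, each vertex emitted once) and the dimension-1
persistent homology of the Vietoris–Rips filtration on $P(K)$ is computed.
All filtration values are reported in the *pairwise-distance (diameter)
scale*; `diameter_to_radius()` halves them for the thickened-curve picture
and is used nowhere else in the package.

From the barcode $\{(b_i, d_i)\}$ come the Betti curve
$\beta_1(t) = \#\{i : b_i \le t < d_i\}$ (closed at birth, open at death, a
convention that makes the counting function and the integral identity
$\int \beta_1 = \sum_i (d_i - b_i)$ exact), the integral $I(K)$, the
longest bar $M(K)$ and the bar count $\#B(K)$.

## The Rips engine

No persistence engine is part of this R stack, so the package implements
one: persistent cohomology over $\mathbb{F}_2$ with clearing, processing
the cycle-creating edges in decreasing filtration order with implicitly
generated coboundary columns, the standard algorithm of the fast engines in
this field. Two structural facts make it exact and finite:

* the filtration is truncated at the *enclosing radius*
  $\min_p \max_q d(p,q)$; at that value the complex is a cone over the
  minimizing point, so $H_1$ vanishes there and beyond, every class dies at
  or before it, and no interval is lost;
* triangles inherit their filtration value from their longest edge, so
  zero-persistence pairs are recognized during cofacet enumeration and
  skipped without reduction (colexicographic enumeration makes the first
  equal-diameter cofacet the pivot).

Correctness is frozen by a dual-route test: `reference_persistence_h1()`
builds the filtration through 2-simplices explicitly and reduces the
dimension-2 boundary matrix with the textbook column algorithm, in plain R,
and must agree with the engine interval-by-interval (tolerance $10^{-9}$)
on every fixture cloud (random clouds, circles with heavy distance ties,
collinear and duplicated points, interpolated polygons). The oracle
refuses clouds above 60 points; it exists to check the engine, not to
replace it.

Cost grows steeply with cloud size and with how densely the curve folds
onto itself (coiled tube-like embeddings are the worst case). The test
suite sizes its studies accordingly; see "Problem sizes" below.

## Random polygon generation

The study's sampler is a *crankshaft* Markov chain: pick two distinct
vertices, rigidly rotate the sub-chain strictly between them about the
chord through them by an angle uniform on $[0, 2\pi)$. The move preserves
closure and edge lengths exactly and the chain is ergodic on the space of
closed equilateral polygons. A direct uniform sampler would be preferable
in principle; the chain is the package's documented approximation of
uniformity, started at the planar regular polygon with a default burn-in of
$30n$ moves.

Two calibration facts support the default. First, uniform closed
equilateral $n$-gons satisfy $E[R_g^2] = (n+1)/12$ *exactly*: the edge
vectors are exchangeable under the closure constraint, forcing
$E[e_i\cdot e_j] = -1/(n-1)$, and the pairwise-distance expansion of
$R_g^2$ does the rest. The suite checks the sampled mean against this
closed form at $n = 50$ (within three standard errors). Second, the
4-gon family admits the exact identity $R_g^2 = 1/2 - h^2/4$, with $h$ the
distance between the two diagonal midpoints (Euler's quadrilateral
identity); chain output must satisfy it to machine precision. Note the
identity shows $R_g^2$ is *not* constant over closed unit 4-gons — only the
planar rhombi attain $1/2$.

Floating-point drift is controlled by exact re-projection (alternating
unit-normalization of edges with removal of the closure defect) every 1000
moves and at the end; the polygon invariants are asserted at tolerance
$10^{-9}$ after every projection.

Typed sampling is rejection: draw, classify, keep on match, with an
attempt budget; exhausted cells are reported incomplete and never padded.
Per-polygon seeds derive from a root seed and a counter
(`seed + 1000003 * counter mod 2^31 - 1`), so datasets are reproducible
record by record and cells can be regenerated independently.

## Knot identification

Knot types are read off generic planar diagrams: orthogonal projection
along a random direction, transverse crossings ordered along the curve,
over/under by depth, signs by the right-hand rule. Projections within
$10^{-9}$ (projected units) of a degeneracy — crossing at a vertex image,
equal depths, near-parallel overlapping edges, an edge parallel to the
direction — are rejected and redrawn (budget 20 directions). The Gauss
code is simplified by Reidemeister I and II moves, then the Alexander
polynomial is computed from the Wirtinger presentation via Fox calculus:
each crossing contributes the row $(1-t)\,x_{over} + t\,x_{in} - x_{out}$
(positive) or $(t-1)\,x_{over} + x_{in} - t\,x_{out}$ (negative, scaled by
$t$), one row and one column are deleted, and the determinant is evaluated
over $\mathbb{Z}_p$ ($p = 2^{31}-1$) at enough points to Lagrange-interpolate
exactly, then lifted to the symmetric range and normalized to value $+1$ at
$t = 1$. Coefficients of knots realizable at these lengths are minuscule
compared to $p/2$, so the lift is exact in practice.

The classifier votes over 5 projections and looks the normalized sequence
up among the eight prime types through six crossings; non-matches are
`unknown`, ties vote `unknown`, and the trivial polynomial maps to `0_1` —
a documented caveat, as Alexander-trivial nontrivial knots exist but first
occur at 11 crossings, far beyond the scales studied. The reference table
stores the standard published sequences normalized to $\Delta(1) = +1$;
tests verify the table is pairwise distinct, that embeddings of $3_1$
(torus curve), $4_1$ (parametric figure-eight) and $5_1$ ((2,5) torus
curve) reproduce their entries through the full geometric pipeline, and
that every computed polynomial is palindromic with $\Delta(1) = 1$ and
projection-invariant. Chirality is ignored throughout (Alexander cannot
see it, and the type list is achiral in labelling).

## Geometric measures

* $R_g$ is vertex-based (uniform mass at the vertices), the standard
  convention for equilateral chain models.
* The minimal enclosing sphere is exact (Welzl's move-to-front recursion
  with support sets up to 4; deterministic internal shuffle so results do
  not depend on R's RNG state).
* Convex hull volume by incremental construction; coplanar degenerate
  input returns volume 0 with a warning, since short polygons can be
  nearly planar.
* Discrete curvature is the turning-angle sum; discrete torsion the sum of
  signed dihedral angles between consecutive osculating planes, with both
  the signed and the absolute sum reported (the field uses both; a vertex
  with collinear neighbours contributes 0). The sign convention is frozen
  by a right-handed-helix fixture test.
* The ACN's primary estimator averages crossing counts over random
  projections (default 100 directions, seeded), which carries the
  $1/4\pi$ normalization intrinsically; the Gauss double integral with
  per-pair adaptive Gauss–Legendre quadrature (recursive panel refinement,
  needed because nearly touching segment pairs make the integrand peak
  like the inverse cube of the separation) is the deterministic
  cross-check. For straight segments the triple product is constant per
  pair and vanishes for adjacent pairs, so the integral is proper and
  adjacent pairs contribute exactly zero.

## Deviation from ideality

$\delta_\varepsilon(K) = \frac{1}{S}\int_0^S f_{S,\varepsilon}(t)\,
\max(\beta_1(t) - 1, 0)\,dt$, with $S$ the support of the Betti curve and
$f_{S,\varepsilon}$ the linear weight equal to 1 at 0 and 0 from
$S - \varepsilon$ on. Ideal (ropelength-minimizing) embeddings keep
$\beta_1 = 1$ until the injectivity radius, so excess early homology is a
deviation signal; the weight erases late bars, the $1/S$ prefactor and the
scale-covariance of the barcode make the statistic invariant under rigid
motions and uniform rescaling (asserted empirically at $10^{-9}$). The
integral is evaluated in closed form piecewise over the step intervals —
no quadrature. $\varepsilon$ defaults to $0.1$ (one interpolation spacing)
in distance-scale units; the acceptance suite checks the trefoil-family
ordering for $\varepsilon \in \{0.05, 0.1, 0.2\}$. $\delta_\varepsilon$
consumes the unfiltered Betti curve by default (`use_spike_filter` flips
this), reading the early bars as signal.

The trefoil test family places a (2,3) torus curve
$((R + r\cos 3u)\cos 2u, (R + r\cos 3u)\sin 2u, r\sin 3u)$ at
$(R, r) = (2, 1)$ ("balanced", the stand-in for a near-ideal embedding —
true ideal coordinates are not published), $(5, 1)$ ("elongated"), and
balanced with $z$ scaled by $0.05$ ("flattened"), resampled to $n$ equal
arclength points and projected to exact unit edges. The scientific claim
checked is the *ordering*
$\delta(\text{balanced}) < \delta(\text{elongated}) <
\delta(\text{flattened})$, not the values.

## The spike and its filter

Two consecutive unit edges meeting at internal angle $\theta$ produce, at
sampling spacing $d = 0.1$, an extra four-point Rips class born at
$4d\sin(\theta/2)$ and dying at $d\sqrt{5 - 4\cos\theta}$; it exists
exactly when $\theta < \arccos(3/4) \approx 41.4^\circ$. These classes
pile up just after $t = 0.1$ and form the first spike of averaged Betti
curves. `critical_spike_angle()` rediscovers the threshold by bisection
with the persistence engine, and the acceptance script reports it to one
decimal. `spike_filter()` removes bars with birth in $[0.10, 0.13]$ and
persistence $\le 0.05$ — the window implied by the closed form for angles
down to $\sim 20^\circ$ — and is idempotent; all three thresholds are
arguments. Averages and $\delta_\varepsilon$ use unfiltered curves by
default.

## Statistical analyses

`build_dataset1()` emulates the random-knot protocol (lengths 10–100 in
steps of 10 at full scale), `build_dataset2()` the typed protocol (types
through six crossings, lengths 50–200 in steps of 50) by rejection.
Correlation tables always carry both Pearson and Spearman coefficients
(the choice used in the source analyses is not pinned down); groups with
fewer than 3 complete records are skipped with a warning; split-half
robustness reports both halves and the maximal coefficient discrepancy.
Incomplete cells are reported, never imputed; composite-knot contamination
at long lengths is not filtered.

## Problem sizes

Full-scale protocols ($10^4$ knots per length, $10^3$ per type cell) are
far beyond a desk run; the package's own study sizes, fixed once, are:
`n_per_length = 200` and `n_per_cell = 50` as pipeline defaults with types
restricted to `0_1`, `3_1`, `4_1`; within the test suite, the correlation
checks use lengths $\{20, 50, 100\}$ with 50 polygons per length, the
unknot linearity check uses lengths $\{50, 100, 150, 200\}$ with 4 unknots
per cell, the Fáry–Milnor sweep uses 100 rejection-sampled trefoils at
length 50, and the trefoil family runs at $n = 60$ edges, where the
elongated embedding's Rips computation remains tractable for the engine
while the family ordering is already stable (it holds identically at
$n = 90$). Stochastic checks run under
fixed seeds at tolerances stated per test; signs and orderings, not
magnitudes, are the assertions.

## Known limitations

* The crankshaft chain approximates uniformity; burn-in is a heuristic
  (backed by the exact-$E[R_g^2]$ check), not a coupling bound.
* Alexander classification folds distinct $\ge 7$-crossing types into
  `unknown` and cannot see chirality.
* The Rips picture differs from the true metric-neighbourhood homology at
  small scales (the spike is an artefact of the complex choice, present —
  wider — for the Čech alternative) and the point cloud discretizes the
  curve at spacing 0.1; features are those of $P(K)$, not of $\nu_t(K)$.
* Injectivity radius, ropelength, $L/D$ and ideal-embedding computation
  are out of scope.
* Synthetic polygons emulate the study conditions (lengths, protocols,
  spacing); they are not data from any physical polymer, and passing tests
  establish internal consistency of the model, not biological fidelity.
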
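# knotph

Tools for studying how random knots occupy space, for researchers in
structural bioinformatics and polymer/biopolymer modelling who work with
knotted chain models (DNA, proteins, synthetic polymers).

A random knot is modelled as a closed equilateral polygon in 3-space with
unit edges, so its length ℓ(K) equals its number of edges. The package
couples two families of descriptors of such an embedding K:

* **Topological-data-analysis features.** The polygon is interpolated to a
  point cloud P(K) with 10 samples per unit edge and the dimension-1
  persistent homology of its Vietoris–Rips filtration is computed (all
  filtration values in the pairwise-distance, "diameter", scale). From the
  barcode come the Betti curve β₁(t), its integral I(K) (the summed bar
  lengths), the longest bar M(K), and the bar count #B(K).
* **Geometric compactness measures.** Radius of gyration Rg, the minimal
  enclosing sphere (radius RS and volume), convex hull volume, discrete
  total curvature and torsion, and the average crossing number (ACN),
  estimated by Monte-Carlo averaging of crossing counts over random
  projections and cross-checked by the Gauss double integral.

Knot types are identified by projecting to a generic diagram, simplifying
the Gauss code, and computing the Alexander polynomial, which distinguishes
all prime knots through six crossings (`0_1`, `3_1`, `4_1`, `5_1`, `5_2`,
`6_1`, `6_2`, `6_3`; everything else is `unknown`).

The package reproduces, at desk scale, the statistical phenomenology of
this model: I(K) correlates negatively with occupied volume (hull, sphere,
Rg) and positively with the ACN, increasingly so with length, while per-type
mean I grows linearly in length. It also computes a deviation-from-ideality
statistic

δε(K) = (1/S) ∫₀^S f_{S,ε}(t) · max(β₁(K)(t) − 1, 0) dt,

where S is the support of the Betti curve and f_{S,ε} a linear cut-off
weight: ideal (ropelength-minimizing) embeddings keep β₁ = 1 until their
injectivity radius, so excess early homology measures deviation from
ideality.

The dimension-1 Rips persistence engine is implemented in compiled code
(persistent cohomology with clearing and implicit coboundaries) and is
verified, interval by interval, against an explicit boundary-matrix
reduction oracle included in the package.

## Worked example

```r
library(knotph)
set.seed(1)

p <- sample_random_polygon(50)        # uniform-ish closed equilateral 50-gon
classify_knot(p)
#> [1] "0_1"
#> attr(,"alexander")
#> [1] 1

cloud <- interpolate_polygon(p, s = 10)   # 500 points, spacing 0.1
bc <- rips_h1_barcode(cloud)
bc
#> dimension-1 Rips barcode: 83 intervals
#>   total persistence 6.323, longest bar 1.108

cv <- betti_curve(bc)
delta_ideality(cv, epsilon = 0.1)
#> support S = 1.399, epsilon = 0.1, delta = 2.37137

geometric_summary(p)[, c("Rg", "V_hull", "acn")]
#>         Rg   V_hull  acn
#> 1 1.586227 18.45179 37.3
```

The barcode says the thickened curve carries 83 one-dimensional holes over
its filtration history; most are short-lived vertex-angle artefacts born
just after the sampling spacing 0.1 (two consecutive edges meeting below
arccos(3/4) ≈ 41.4° create one). The longest bar (≈ 1.1) is the curve's
own loop. δε ≈ 2.37 quantifies the excess homology under the early cut-off
weight: this compact random unknot (Rg ≈ 1.59, ACN ≈ 37) is far from
ideal — compare ≈ 0.02 for a well-proportioned torus trefoil and ≈ 1.3 for
a nearly planar one (the trefoil-family ordering checked in the acceptance
suite).

Dataset-scale runs (`build_dataset1()`, `build_dataset2()`,
`run_pipeline()`) produce per-knot feature tables and correlation tables as
CSV; `inst/scripts/knotph.R` wraps the same functions as a small command
line (`sample`, `classify`, `features`, `ideality`, `pipeline1`,
`pipeline2`).

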
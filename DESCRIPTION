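Package: knotph
Title: Persistent Homology and Geometry of Random Polygonal Knots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying how random knots occupy space. Generates
    random closed equilateral polygons in 3-space (optionally conditioned
    on knot type via Alexander-polynomial classification), computes
    dimension-1 Vietoris-Rips persistent homology of interpolated point
    clouds, extracts barcode features (Betti curves, their integrals,
    longest and total bar statistics), measures geometric compactness
    (radius of gyration, minimal enclosing sphere, convex hull volume,
    total curvature and torsion, average crossing number), correlates the
    two families of descriptors across lengths and knot types, and
    computes a deviation-from-ideality statistic for knot embeddings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
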
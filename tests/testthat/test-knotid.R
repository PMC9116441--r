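test_that("projection of a planar convex polygon has no crossings", {
  d <- project_to_diagram(regular_polygon(12), c(0, 0, 1))
  expect_equal(nrow(d), 0L)
  expect_equal(as.character(classify_knot(regular_polygon(20))), "0_1")
})

test_that("a generic trefoil projection reduces to three crossings", {
  set.seed(1)
  tb <- trefoil_family("balanced", 60)
  got <- NULL
  for (rep in 1:10) {
    d <- tryCatch(project_to_diagram(tb, knotph:::random_unit_vector()),
                  knotph_degenerate_projection = function(e) NULL)
    if (!is.null(d)) { got <- simplify_gauss(d); break }
  }
  expect_equal(nrow(got) / 2L, 3)
})

test_that("projection along an edge direction is degenerate", {
  v <- unclass(regular_polygon(10))
  e1 <- v[2, ] - v[1, ]
  expect_error(project_to_diagram(v, e1 / sqrt(sum(e1^2))),
               class = "knotph_degenerate_projection")
})

test_that("Reidemeister simplification removes kinks and cancelling pairs", {
  # single kink: both passages of one crossing adjacent
  k1 <- knotph:::new_knot_diagram(c(1, 1), c(TRUE, FALSE), c(1L, 1L))
  expect_equal(nrow(simplify_gauss(k1)), 0L)
  # nested double kink
  k2 <- knotph:::new_knot_diagram(c(1, 2, 2, 1), c(TRUE, TRUE, FALSE, FALSE),
                                  c(1L, -1L, -1L, 1L))
  expect_equal(nrow(simplify_gauss(k2)), 0L)
  # reduced trefoil code is a fixed point
  tre <- knotph:::new_knot_diagram(c(1, 2, 3, 1, 2, 3),
                                   c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
                                   rep(1L, 6))
  expect_identical(simplify_gauss(tre)$crossing, tre$crossing)
  # R2 pair: strand over at both crossings, other strand under at both
  r2 <- knotph:::new_knot_diagram(c(1, 2, 2, 1), c(TRUE, TRUE, FALSE, FALSE),
                                  c(1L, -1L, -1L, 1L))
  expect_equal(nrow(simplify_gauss(r2)), 0L)
})

test_that("Alexander polynomials of the minimal torus and twist codes", {
  tre <- knotph:::new_knot_diagram(c(1, 2, 3, 1, 2, 3),
                                   c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
                                   rep(1L, 6))
  expect_equal(alexander_poly(tre), c(1L, -1L, 1L))
  f8 <- knotph:::new_knot_diagram(c(1, 2, 3, 4, 2, 1, 4, 3),
                                  c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
                                  c(1L, 1L, -1L, -1L, 1L, 1L, -1L, -1L))
  expect_equal(alexander_poly(f8), c(-1L, 3L, -1L))
  expect_equal(alexander_poly(knotph:::new_knot_diagram(integer(0), logical(0),
                                                        integer(0))), 1L)
})

test_that("Alexander polynomial is projection-invariant and unimodular at 1", {
  set.seed(3)
  polys <- list(trefoil_family("balanced", 60), figure_eight_polygon(80),
                sample_random_polygon(40))
  for (p in polys) {
    coeffs <- list()
    tries <- 0
    while (length(coeffs) < 5 && tries < 20) {
      tries <- tries + 1
      d <- tryCatch(project_to_diagram(p, knotph:::random_unit_vector()),
                    knotph_degenerate_projection = function(e) NULL)
      if (is.null(d)) next
      co <- alexander_poly(simplify_gauss(d))
      expect_equal(sum(co), 1L)  # normalized value at t = 1
      expect_equal(co, rev(co))  # palindromic coefficient sequence
      coeffs[[length(coeffs) + 1]] <- co
    }
    expect_gte(length(coeffs), 5)
    for (co in coeffs) expect_equal(co, coeffs[[1]])
  }
})

test_that("the reference table is pairwise distinct and matched by embeddings", {
  tab <- knotph:::alexander_table
  keys <- vapply(tab, paste, "", collapse = " ")
  expect_equal(anyDuplicated(keys), 0L)
  # every entry normalizes to +1 at t = 1 and is palindromic
  for (co in tab) {
    expect_equal(sum(co), 1L)
    expect_equal(co, rev(co))
  }
  set.seed(4)
  expect_equal(as.character(classify_knot(trefoil_family("balanced", 60))), "3_1")
  expect_equal(as.character(classify_knot(figure_eight_polygon(80))), "4_1")
  expect_equal(as.character(classify_knot(torus25_polygon(100))), "5_1")
})

test_that("classification is stable across seeds", {
  set.seed(5)
  p <- sample_random_polygon(50)
  set.seed(101)
  l1 <- as.character(classify_knot(p))
  set.seed(202)
  l2 <- as.character(classify_knot(p))
  expect_equal(l1, l2)
})
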
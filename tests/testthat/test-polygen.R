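test_that("regular polygons have exact unit edges, closure, and circumradius", {
  for (n in c(3L, 4L, 6L, 100L)) {
    p <- regular_polygon(n)
    expect_lt(max(abs(edge_lengths(p) - 1)), 1e-9)
    v <- unclass(p)
    edges <- rbind(v[-1, ], v[1, ]) - v
    expect_lt(sqrt(sum(colSums(edges)^2)), 1e-9)
  }
  # unit-edge hexagon: vertices at distance 1 from the centroid
  h <- unclass(regular_polygon(6))
  expect_equal(sqrt(rowSums(sweep(h, 2, colMeans(h))^2)),
               rep(1, 6), tolerance = 1e-12)
  expect_error(regular_polygon(2), "n must be")
})

test_that("crankshaft moves are isometries of the sub-chain", {
  set.seed(11)
  p <- sample_random_polygon(20)
  for (rep in 1:20) {
    p <- crankshaft_step(p)
    expect_lt(max(abs(edge_lengths(p) - 1)), 1e-9)
  }
  # explicit zero-angle rotation is the identity
  v <- unclass(regular_polygon(8))
  expect_identical(rotate_subchain_cpp(v, 0L, 3L, 0), v)
  # near-full-turn rotation returns near the start (continuity)
  almost <- rotate_subchain_cpp(v, 0L, 3L, 2 * pi - 1e-9)
  expect_lt(max(abs(almost - v)), 1e-7)
})

test_that("sampled polygons are reproducible and satisfy the invariants", {
  set.seed(5)
  a <- sample_random_polygon(10)
  set.seed(5)
  b <- sample_random_polygon(10)
  expect_identical(unclass(a), unclass(b))
  expect_lt(max(abs(edge_lengths(a) - 1)), 1e-9)
})

test_that("closed equilateral 4-gons satisfy Rg^2 = 1/2 - h^2/4 exactly", {
  # h is the distance between the two diagonal midpoints (Euler's
  # quadrilateral identity); planar rhombi (h = 0) attain Rg^2 = 1/2
  set.seed(21)
  for (rep in 1:25) {
    v <- unclass(sample_random_polygon(4, n_steps = 50 + rep))
    h2 <- sum(((v[1, ] + v[3, ]) / 2 - (v[2, ] + v[4, ]) / 2)^2)
    expect_equal(radius_of_gyration(v)^2, 0.5 - h2 / 4, tolerance = 1e-10)
  }
  expect_equal(radius_of_gyration(regular_polygon(4))^2, 0.5, tolerance = 1e-12)
  # non-planar counterexample to the naive constant-1/2 expectation
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1 / 2, 1 / 2, 1 / sqrt(2)))
  expect_equal(radius_of_gyration(knot_polygon(v))^2, 7 / 16, tolerance = 1e-12)
})

test_that("mean squared radius of gyration matches the exact closed form", {
  # uniform closed equilateral polygons have E[Rg^2] = (n+1)/12, from
  # exchangeability of edge vectors under the closure constraint
  set.seed(31)
  n <- 50L
  m <- 120L
  rg2 <- replicate(m, radius_of_gyration(sample_random_polygon(n))^2)
  z <- (mean(rg2) - (n + 1) / 12) / (sd(rg2) / sqrt(m))
  expect_lt(abs(z), 3)
})

test_that("fixed-type rejection sampling returns the requested type", {
  set.seed(41)
  p <- sample_fixed_type(6, "0_1", max_attempts = 50)
  expect_equal(as.character(classify_knot(p)), "0_1")
  expect_gte(attr(p, "attempts"), 1L)
  set.seed(42)
  p3 <- sample_fixed_type(50, "3_1", max_attempts = 500)
  # the returned polygon re-classifies identically under fresh projections
  for (rep in 1:5) expect_equal(as.character(classify_knot(p3)), "3_1")
  # an improbable type with a tiny budget fails with the attempt count
  set.seed(43)
  expect_error(sample_fixed_type(50, "6_3", max_attempts = 1),
               "no 6_3 found among 1")
})

test_that("knotting probability is positive and grows with length", {
  set.seed(61)
  frac_knotted <- vapply(c(50L, 100L, 200L), function(n) {
    mean(replicate(40, as.character(classify_knot(sample_random_polygon(n),
                                                  n_tries = 3L)) != "0_1"))
  }, numeric(1))
  expect_gt(frac_knotted[1], 0)
  # monotone growth within generous sampling error at 40 draws per length
  expect_gt(frac_knotted[2], frac_knotted[1] - 0.1)
  expect_gt(frac_knotted[3], frac_knotted[2] - 0.1)
  expect_gt(frac_knotted[3], frac_knotted[1])
})

test_that("equilateralize projects near-equilateral polygons back exactly", {
  set.seed(51)
  v <- unclass(sample_random_polygon(30)) + matrix(rnorm(90, sd = 1e-4), 30, 3)
  p <- equilateralize(v)
  expect_lt(max(abs(edge_lengths(p) - 1)), 1e-9)
  expect_lt(max(abs(unclass(p) - v)), 1e-2)  # projection stays close
})
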
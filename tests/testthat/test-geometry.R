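test_that("radius of gyration: closed forms and rigid-motion invariance", {
  expect_equal(radius_of_gyration(regular_polygon(4)), sqrt(0.5), tolerance = 1e-12)
  set.seed(1)
  p <- sample_random_polygon(30)
  m <- random_rigid_motion()
  expect_equal(radius_of_gyration(apply_motion(unclass(p), m)),
               radius_of_gyration(p), tolerance = 1e-9)
})

test_that("minimal enclosing sphere: closed forms and brute-force oracle", {
  ms <- min_enclosing_sphere(rbind(c(-1, 0, 0), c(1, 0, 0)))
  expect_equal(ms$radius, 1, tolerance = 1e-12)
  expect_equal(ms$center, c(0, 0, 0), tolerance = 1e-12)
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  ms <- min_enclosing_sphere(sq)
  expect_equal(ms$radius, sqrt(2) / 2, tolerance = 1e-9)
  expect_equal(ms$center, c(0.5, 0.5, 0), tolerance = 1e-9)
  set.seed(2)
  for (rep in 1:20) {
    pts <- matrix(rnorm(3 * 8), 8, 3)
    expect_equal(min_enclosing_sphere(pts)$radius, brute_force_miniball(pts),
                 tolerance = 1e-9)
  }
  # all points inside
  set.seed(3)
  pts <- matrix(rnorm(3 * 200), 200, 3)
  ms <- min_enclosing_sphere(pts)
  expect_lt(max(sqrt(rowSums(sweep(pts, 2, ms$center)^2))) - ms$radius, 1e-9)
  expect_error(min_enclosing_sphere(matrix(numeric(0), 0, 3)), "at least one")
})

test_that("sphere and hull volumes", {
  expect_equal(sphere_volume(1), 4 * pi / 3, tolerance = 1e-12)
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(hull_volume(cube), 1, tolerance = 1e-9)
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
               c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
  expect_equal(hull_volume(tet), 1 / (6 * sqrt(2)), tolerance = 1e-9)
  expect_warning(v0 <- hull_volume(unclass(regular_polygon(10))), "degenerate")
  expect_equal(v0, 0)
  # interior points do not change the hull
  set.seed(4)
  pts <- matrix(rnorm(3 * 50), 50, 3)
  inner <- matrix(rnorm(3 * 30, sd = 0.1), 30, 3)
  expect_equal(hull_volume(rbind(pts, inner)), hull_volume(pts), tolerance = 1e-9)
})

test_that("sphere always contains the hull and the vertices", {
  set.seed(5)
  for (n in c(10, 40)) {
    p <- sample_random_polygon(n)
    g <- suppressWarnings(geometric_summary(p, acn_dirs = 10))
    expect_gte(g$V_sphere, g$V_hull)
    expect_gte(g$RS, g$Rg)
  }
})

test_that("total curvature: planar polygons give 2 pi; knots exceed 4 pi", {
  for (n in c(3, 7, 50)) {
    expect_equal(total_curvature(regular_polygon(n)), 2 * pi, tolerance = 1e-9)
  }
  expect_gt(total_curvature(trefoil_family("balanced", 60)), 4 * pi)
})

test_that("total torsion: planar zero, mirror antisymmetry, helix sign", {
  tor <- total_torsion(regular_polygon(12))
  expect_equal(tor$signed, 0, tolerance = 1e-9)
  expect_equal(tor$absolute, 0, tolerance = 1e-9)
  set.seed(6)
  p <- unclass(sample_random_polygon(20))
  t1 <- total_torsion(p)
  mir <- p
  mir[, 3] <- -mir[, 3]
  t2 <- total_torsion(mir)
  expect_equal(t2$signed, -t1$signed, tolerance = 1e-9)
  expect_equal(t2$absolute, t1$absolute, tolerance = 1e-9)
  # a long right-handed helix closed by a nearly planar return path: the
  # helix vertices dominate the signed sum, so the total is positive
  u <- seq(0, 24 * pi, length.out = 121)[-121]
  helix <- cbind(cos(u), sin(u), 0.2 * u)
  zs <- seq(helix[nrow(helix), 3], helix[1, 3], length.out = 10)
  ret <- cbind(4 + 0.5 * cos(seq(0, pi, length.out = 10)), 0, zs)
  th <- total_torsion(rbind(helix, ret))
  expect_gt(th$signed, 0)
  expect_gte(th$absolute, abs(th$signed))
})

test_that("average crossing number: zero for convex planar, scale-invariant", {
  set.seed(7)
  acn <- acn_projection_mc(regular_polygon(10), 50)
  expect_equal(acn$acn, 0)
  expect_equal(acn$stderr, 0)
  set.seed(8)
  p <- unclass(sample_random_polygon(30))
  set.seed(99)
  a1 <- acn_projection_mc(p, 50)
  set.seed(99)
  a2 <- acn_projection_mc(10 * p, 50)
  expect_equal(a1$acn, a2$acn)
})

test_that("Monte-Carlo and Gauss-integral ACN agree", {
  set.seed(9)
  tb <- trefoil_family("balanced", 60)
  mc <- acn_projection_mc(tb, 500)
  gi <- acn_gauss_integral(tb, 8)
  expect_lt(abs(mc$acn - gi), 3 * mc$stderr)
  # planar polygon: the Gauss integrand vanishes identically
  expect_lt(acn_gauss_integral(regular_polygon(20), 4), 1e-6)
  # quadrature convergence on a length-30 polygon
  set.seed(10)
  p30 <- sample_random_polygon(30)
  expect_lt(abs(acn_gauss_integral(p30, 16) - acn_gauss_integral(p30, 8)), 1e-4)
})
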
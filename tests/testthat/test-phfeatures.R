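test_that("interpolation emits s points per edge at exact spacing", {
  p <- regular_polygon(50)
  cl <- interpolate_polygon(p, 10)
  expect_equal(nrow(cl), 500L)
  d <- sqrt(rowSums((cl[2:11, ] - cl[1:10, ])^2))
  expect_equal(d, rep(0.1, 10), tolerance = 1e-12)
  expect_equal(nrow(interpolate_polygon(p, 1)), 50L)
  expect_equal(unclass(interpolate_polygon(p, 1))[1:50, ], unclass(p)[1:50, ],
               ignore_attr = TRUE)
})

test_that("engine and explicit boundary-matrix oracle agree exactly", {
  set.seed(12)
  clouds <- list(
    rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),     # square corners
    cbind(cos(2 * pi * (0:39) / 40), sin(2 * pi * (0:39) / 40), 0),  # circle, ties
    cbind(0:4, 0, 0),                                           # collinear
    matrix(rnorm(3 * 25), 25, 3),
    matrix(rnorm(3 * 40), 40, 3),
    unclass(interpolate_polygon(regular_polygon(4), 10))        # curve-like
  )
  for (cl in clouds)
    expect_barcodes_equal(rips_h1_barcode(cl), reference_persistence_h1(cl))
  # the square's 4 corners: born at the side, killed at the diagonal
  b <- rips_h1_barcode(clouds[[1]])
  expect_equal(nrow(b), 1L)
  expect_equal(unname(b[1, ]), c(1, sqrt(2)), tolerance = 1e-12)
  # degenerate inputs
  expect_equal(nrow(rips_h1_barcode(matrix(rnorm(6), 2, 3))), 0L)
  expect_equal(nrow(reference_persistence_h1(matrix(rnorm(6), 2, 3))), 0L)
  expect_equal(nrow(rips_h1_barcode(clouds[[3]])), 0L)
})

test_that("dense circle samples carry one dominant class dying near sqrt(3)", {
  th <- 2 * pi * (0:199) / 200
  b <- rips_h1_barcode(cbind(cos(th), sin(th), 0))
  pers <- b[, 2] - b[, 1]
  expect_equal(sum(pers > 1), 1L)
  main <- b[which.max(pers), ]
  expect_lt(abs(main[2] - sqrt(3)), 0.05)
})

test_that("the sharp-vertex spike interval matches the closed form", {
  # two unit edges at 35 degrees, sampled at spacing 0.1: the extra class is
  # born at 4 d sin(theta/2) and dies at d sqrt(5 - 4 cos(theta))
  th <- 35 * pi / 180
  r <- seq(0, 1, by = 0.1)
  cloud <- rbind(cbind(r, 0, 0),
                 cbind(rev(r[-1]) * cos(th), rev(r[-1]) * sin(th), 0))
  b <- rips_h1_barcode(cloud)
  expect_equal(nrow(b), 1L)
  expect_equal(unname(b[1, 1]), 0.4 * sin(th / 2), tolerance = 1e-9)
  expect_equal(unname(b[1, 2]), 0.1 * sqrt(5 - 4 * cos(th)), tolerance = 1e-9)
  # the spike filter removes it at the defaults, and is idempotent
  f <- spike_filter(b)
  expect_equal(nrow(f), 0L)
  long <- knotph:::new_barcode(rbind(c(0.105, 0.505), b))
  kept <- spike_filter(long)
  expect_equal(nrow(kept), 1L)
  expect_equal(unname(kept[1, ]), c(0.105, 0.505))
  expect_equal(as.matrix(spike_filter(kept)), as.matrix(kept))
})

test_that("Betti curves count intervals and integrate exactly", {
  b <- knotph:::new_barcode(rbind(c(1, 3), c(2, 4)))
  cv <- betti_curve(b)
  expect_equal(betti_at(cv, c(0.5, 1, 2.5, 3.5, 4, 5)), c(0, 1, 2, 1, 0, 0))
  expect_equal(integral_I(b), 4)
  expect_equal(max_bar_M(b), 2)
  expect_equal(num_bars_B(b), 2L)
  expect_equal(knotph:::betti_integral(cv), integral_I(b))
  # empty barcode
  e <- knotph:::new_barcode(matrix(numeric(0), 0, 2))
  expect_equal(betti_at(betti_curve(e), 1), 0)
  expect_equal(c(integral_I(e), max_bar_M(e), num_bars_B(e)), c(0, 0, 0))
  # shifting intervals leaves the summaries unchanged
  bs <- knotph:::new_barcode(rbind(c(1, 3), c(2, 4)) + 7)
  expect_equal(c(integral_I(bs), max_bar_M(bs), num_bars_B(bs)),
               c(integral_I(b), max_bar_M(b), num_bars_B(b)))
})

test_that("integral identity holds on generated barcodes", {
  set.seed(13)
  for (rep in 1:5) {
    cl <- matrix(rnorm(3 * 30), 30, 3)
    b <- rips_h1_barcode(cl)
    expect_equal(knotph:::betti_integral(betti_curve(b)), integral_I(b),
                 tolerance = 1e-12)
  }
})

test_that("I and M are motion-invariant and scale linearly", {
  set.seed(14)
  cl <- unclass(interpolate_polygon(sample_random_polygon(10), 5))
  b0 <- rips_h1_barcode(cl)
  m <- random_rigid_motion()
  b1 <- rips_h1_barcode(apply_motion(cl, m))
  expect_equal(integral_I(b1), integral_I(b0), tolerance = 1e-9)
  expect_equal(max_bar_M(b1), max_bar_M(b0), tolerance = 1e-9)
  b3 <- rips_h1_barcode(3 * cl)
  expect_equal(integral_I(b3), 3 * integral_I(b0), tolerance = 1e-9)
  expect_equal(max_bar_M(b3), 3 * max_bar_M(b0), tolerance = 1e-9)
  expect_equal(num_bars_B(b3), num_bars_B(b0))
})

test_that("averaging Betti curves is pointwise and finds the first maximum", {
  c1 <- betti_curve(knotph:::new_barcode(rbind(c(0, 2))))
  c2 <- betti_curve(knotph:::new_barcode(rbind(c(0, 1), c(0, 1), c(0, 1))))
  avg <- average_betti_curve(list(c1, c2))
  expect_equal(betti_at(avg, c(0.5, 1.5)), c(2, 0.5))
  same <- average_betti_curve(list(c1, c1))
  expect_equal(betti_at(same, c(0.5, 1.5)), betti_at(c1, c(0.5, 1.5)))
  cm <- curve_max(avg)
  expect_equal(cm$t, 0)
  expect_equal(cm$value, 2)
  expect_error(average_betti_curve(list()), "at least one")
})

test_that("averaged unknot Betti curves show the early spike and a later bump", {
  set.seed(15)
  curves <- list()
  while (length(curves) < 40) {
    p <- sample_random_polygon(50)
    if (as.character(classify_knot(p, n_tries = 3)) != "0_1") next
    curves[[length(curves) + 1]] <- betti_curve(rips_h1_barcode(interpolate_polygon(p)))
  }
  avg <- average_betti_curve(curves)
  # local maxima of the averaged step curve
  v <- avg$values
  peaks <- which(diff(sign(diff(c(0, v, 0)))) == -2)
  expect_gte(length(peaks), 2)
  first <- avg$breaks[peaks[1]]
  # births of the sharpest-angle classes sit exactly at the sampling
  # spacing (the 0.1 edge completes their cycle last), so the first peak
  # can fall on the closed-at-birth boundary itself
  expect_gte(first, 0.1 - 1e-9)
  expect_lt(first, 0.15)
})
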
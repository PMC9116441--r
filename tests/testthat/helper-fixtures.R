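# shared fixtures: parametric knotted curves resampled to equilateral
# polygons, and small oracles used across test files

resample_curve <- function(curve, n) {
  seg <- sqrt(rowSums((curve - rbind(curve[nrow(curve), ], curve[-nrow(curve), ]))^2))
  arc <- cumsum(seg)
  total <- arc[length(arc)]
  idx <- findInterval(total * (seq_len(n) - 1L) / n, c(0, arc))
  v <- curve[pmin(pmax(idx, 1L), nrow(curve)), , drop = FALSE]
  equilateralize(v / (total / n))
}

figure_eight_polygon <- function(n = 80L) {
  u <- seq(0, 2 * pi, length.out = 20001L)[-1L]
  resample_curve(cbind((2 + cos(2 * u)) * cos(3 * u),
                       (2 + cos(2 * u)) * sin(3 * u), sin(4 * u)), n)
}

torus25_polygon <- function(n = 100L) {
  u <- seq(0, 2 * pi, length.out = 20001L)[-1L]
  resample_curve(cbind((2 + cos(5 * u)) * cos(2 * u),
                       (2 + cos(5 * u)) * sin(2 * u), sin(5 * u)), n)
}

# brute-force minimal enclosing ball for <= 8 points: best ball over all
# support subsets of size 2, 3, 4 that contains every point
brute_force_miniball <- function(pts) {
  n <- nrow(pts)
  best <- Inf
  contains_all <- function(c, r2) all(rowSums((pts - matrix(c, n, 3, byrow = TRUE))^2) <= r2 * (1 + 1e-10) + 1e-12)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    c <- (pts[i, ] + pts[j, ]) / 2
    r2 <- sum((pts[i, ] - c)^2)
    if (r2 < best && contains_all(c, r2)) best <- r2
  }
  if (n >= 3) {
    for (s in utils::combn(n, 3, simplify = FALSE)) {
      a <- pts[s[1], ]; b <- pts[s[2], ]; d <- pts[s[3], ]
      nrm <- crossp(b - a, d - a)
      if (sum(nrm^2) < 1e-20) next
      # equidistant from all three and in their plane
      M <- rbind(b - a, d - a, nrm)
      rhs <- c((sum(b^2) - sum(a^2)) / 2, (sum(d^2) - sum(a^2)) / 2, sum(nrm * a))
      ctr <- tryCatch(solve(M, rhs), error = function(e) NULL)
      if (is.null(ctr)) next
      r2 <- sum((a - ctr)^2)
      if (r2 < best && contains_all(ctr, r2)) best <- r2
    }
  }
  if (n >= 4) {
    for (s in utils::combn(n, 4, simplify = FALSE)) {
      a <- pts[s[1], ]
      M <- 2 * rbind(pts[s[2], ] - a, pts[s[3], ] - a, pts[s[4], ] - a)
      rhs <- c(sum(pts[s[2], ]^2) - sum(a^2), sum(pts[s[3], ]^2) - sum(a^2),
               sum(pts[s[4], ]^2) - sum(a^2))
      det <- det(M)
      if (abs(det) < 1e-12) next
      ctr <- solve(M, rhs)
      r2 <- sum((a - ctr)^2)
      if (r2 < best && contains_all(ctr, r2)) best <- r2
    }
  }
  sqrt(best)
}

crossp <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

random_rigid_motion <- function() {
  # QR of a random matrix gives a uniform-ish rotation; add a translation
  qr_r <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(qr_r) < 0) qr_r[, 1] <- -qr_r[, 1]
  list(R = qr_r, t = rnorm(3, sd = 5))
}

apply_motion <- function(v, m) {
  sweep(v %*% t(m$R), 2, -m$t)
}

expect_barcodes_equal <- function(a, b, tol = 1e-9) {
  a <- as.matrix(a); b <- as.matrix(b)
  a <- a[order(a[, 1], a[, 2]), , drop = FALSE]
  b <- b[order(b[, 1], b[, 2]), , drop = FALSE]
  expect_equal(nrow(a), nrow(b))
  if (nrow(a) > 0) expect_lt(max(abs(a - b)), tol)
}
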
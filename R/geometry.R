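#' Radius of gyration
#'
#' Root-mean-square distance of the polygon's vertices from their centroid
#' (uniform mass at the vertices, the standard convention for equilateral
#' polymer models).
#'
#' @param p a [knot_polygon()] or vertex matrix.
#' @return a length-1 numeric.
#' @export
radius_of_gyration <- function(p) {
  v <- if (inherits(p, "knot_polygon")) vertices_of(p) else as.matrix(p)
  ctr <- colMeans(v)
  sqrt(mean(rowSums((v - matrix(ctr, nrow(v), 3L, byrow = TRUE))^2)))
}

#' Minimal enclosing sphere
#'
#' Exact smallest enclosing ball of a 3D point set (Welzl's randomized
#' recursion with move-to-front).
#'
#' @param points `n x 3` matrix, `n >= 1`.
#' @return list with `center` (length-3) and `radius`.
#' @export
min_enclosing_sphere <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 1L) stop("at least one point required")
  if (ncol(points) != 3L) stop("points must be n x 3")
  res <- miniball_cpp(points)
  list(center = res[1:3], radius = res[4L])
}

#' Volumes of the circumscribing sphere and convex hull
#'
#' `sphere_volume` is the closed form `(4/3) pi r^3`; `hull_volume` computes
#' the volume of the convex hull of a 3D point set by incremental hull
#' construction.  Degenerate (coplanar or collinear) inputs have hull volume
#' 0, reported with a warning, since very short polygons can be nearly
#' planar.
#'
#' @param radius sphere radius.
#' @param points `n x 3` matrix.
#' @return a length-1 numeric volume.
#' @export
sphere_volume <- function(radius) (4 / 3) * pi * radius^3

#' @rdname sphere_volume
#' @export
hull_volume <- function(points) {
  points <- as.matrix(points)
  vol <- hull_volume_cpp(points)
  if (vol == 0) warning("degenerate point set: hull volume 0")
  vol
}

#' Total curvature and torsion of a closed polygon
#'
#' `total_curvature` sums the turning angles between consecutive edge
#' vectors (radians); by Fenchel's theorem it is at least `2 pi`, and by the
#' Fary-Milnor theorem it exceeds `4 pi` on every knotted polygon.
#' `total_torsion` sums the signed dihedral angles between consecutive
#' osculating planes (the planes spanned by edge pairs `(e_{i-1}, e_i)` and
#' `(e_i, e_{i+1})`), returning both the signed sum and the sum of absolute
#' values; a vertex with collinear neighbours contributes 0.
#'
#' @param p a [knot_polygon()] or vertex matrix of a closed polygon.
#' @return `total_curvature`: a numeric; `total_torsion`: list with
#'   `signed` and `absolute`.
#' @export
total_curvature <- function(p) {
  v <- if (inherits(p, "knot_polygon")) vertices_of(p) else as.matrix(p)
  e <- rbind(v[-1L, , drop = FALSE], v[1L, , drop = FALSE]) - v
  len <- sqrt(rowSums(e^2))
  if (any(len == 0)) stop("zero-length edge")
  u <- e / len
  uprev <- rbind(u[nrow(u), , drop = FALSE], u[-nrow(u), , drop = FALSE])
  sum(acos(pmin(1, pmax(-1, rowSums(u * uprev)))))
}

#' @rdname total_curvature
#' @export
total_torsion <- function(p) {
  v <- if (inherits(p, "knot_polygon")) vertices_of(p) else as.matrix(p)
  n <- nrow(v)
  e <- rbind(v[-1L, , drop = FALSE], v[1L, , drop = FALSE]) - v
  idx <- seq_len(n)
  prv <- c(n, idx[-n])
  nxt <- c(idx[-1L], 1L)
  signed <- 0
  absolute <- 0
  for (i in idx) {
    n1 <- pracma_cross(e[prv[i], ], e[i, ])
    n2 <- pracma_cross(e[i, ], e[nxt[i], ])
    a1 <- sqrt(sum(n1^2)); a2 <- sqrt(sum(n2^2))
    if (a1 < 1e-12 || a2 < 1e-12) next  # collinear triple: zero by convention
    cosang <- max(-1, min(1, sum(n1 * n2) / (a1 * a2)))
    ang <- acos(cosang)
    s <- sign(sum(pracma_cross(n1, n2) * e[i, ]))
    signed <- signed + s * ang
    absolute <- absolute + ang
  }
  list(signed = signed, absolute = absolute)
}

pracma_cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Average crossing number by Monte-Carlo projection
#'
#' Averages the number of transverse crossings of the projected diagram over
#' `n_dirs` uniformly random directions on the sphere (the definition of the
#' ACN as a normalized integral over projections); degenerate directions are
#' redrawn.  Uses R's random number generator.
#'
#' @param p a [knot_polygon()] or vertex matrix.
#' @param n_dirs number of random directions.
#' @param tol projection degeneracy tolerance.
#' @return list with `acn` (mean) and `stderr` (sample standard error).
#' @export
acn_projection_mc <- function(p, n_dirs = 100L, tol = 1e-9) {
  v <- if (inherits(p, "knot_polygon")) vertices_of(p) else as.matrix(p)
  counts <- numeric(n_dirs)
  for (i in seq_len(n_dirs)) {
    repeat {
      cnt <- count_crossings_cpp(v, random_unit_vector(), tol)
      if (cnt >= 0L) break
    }
    counts[i] <- cnt
  }
  list(acn = mean(counts),
       stderr = if (n_dirs > 1L) sd(counts) / sqrt(n_dirs) else 0)
}

#' Average crossing number by the Gauss double integral
#'
#' Evaluates `(1/4pi)` times the double integral of
#' `|(gamma'(t) x gamma'(s)) . (gamma(t) - gamma(s))| / |gamma(t)-gamma(s)|^3`
#' over ordered segment pairs by Gauss-Legendre quadrature.  For straight
#' segments the triple product is constant per pair, and it vanishes for
#' adjacent or identical segments, so only non-adjacent pairs contribute.
#' Serves as the deterministic cross-check of [acn_projection_mc()].
#'
#' @param p a [knot_polygon()] or vertex matrix.
#' @param quad_order nodes per axis of the Gauss-Legendre rule applied on
#'   each panel; panels are refined adaptively, so the result is accurate
#'   even for nearly touching segment pairs, where the integrand peaks like
#'   the inverse cube of the separation.
#' @param tol absolute tolerance per segment pair for the adaptive
#'   refinement.
#' @return a length-1 numeric.
#' @export
acn_gauss_integral <- function(p, quad_order = 8L, tol = 1e-8) {
  if (quad_order < 2L) stop("quad_order must be >= 2")
  v <- if (inherits(p, "knot_polygon")) vertices_of(p) else as.matrix(p)
  n <- nrow(v)
  e <- rbind(v[-1L, , drop = FALSE], v[1L, , drop = FALSE]) - v
  gl <- gauss_legendre_01(quad_order)
  # GL estimate of the pair integral of 1/|base - a e1 + b e2|^3 over the
  # parameter rectangle [a0,a1] x [b0,b1], nodes mapped per panel
  panel <- function(base, e1, e2, a0, a1, b0, b1) {
    xa <- a0 + (a1 - a0) * gl$x
    xb <- b0 + (b1 - b0) * gl$x
    dx <- outer(-xa * e1[1L], xb * e2[1L], "+") + base[1L]
    dy <- outer(-xa * e1[2L], xb * e2[2L], "+") + base[2L]
    dz <- outer(-xa * e1[3L], xb * e2[3L], "+") + base[3L]
    s <- (dx * dx + dy * dy + dz * dz)^1.5
    (a1 - a0) * (b1 - b0) * sum(outer(gl$w, gl$w) / s)
  }
  refine <- function(base, e1, e2, a0, a1, b0, b1, whole, depth) {
    am <- (a0 + a1) / 2
    bm <- (b0 + b1) / 2
    parts <- panel(base, e1, e2, a0, am, b0, bm) +
      panel(base, e1, e2, am, a1, b0, bm) +
      panel(base, e1, e2, a0, am, bm, b1) +
      panel(base, e1, e2, am, a1, bm, b1)
    if (depth >= 14L || abs(parts - whole) < tol) return(parts)
    refine(base, e1, e2, a0, am, b0, bm,
           panel(base, e1, e2, a0, am, b0, bm), depth + 1L) +
      refine(base, e1, e2, am, a1, b0, bm,
             panel(base, e1, e2, am, a1, b0, bm), depth + 1L) +
      refine(base, e1, e2, a0, am, bm, b1,
             panel(base, e1, e2, a0, am, bm, b1), depth + 1L) +
      refine(base, e1, e2, am, a1, bm, b1,
             panel(base, e1, e2, am, a1, bm, b1), depth + 1L)
  }
  total <- 0
  for (i in seq_len(n - 2L)) {
    for (j in seq.int(i + 2L, n)) {
      if (i == 1L && j == n) next  # cyclically adjacent
      cr <- pracma_cross(e[i, ], e[j, ])
      base <- v[j, ] - v[i, ]
      cnum <- abs(sum(cr * base))  # constant triple product for segments
      if (cnum == 0) next
      whole <- panel(base, e[i, ], e[j, ], 0, 1, 0, 1)
      total <- total + cnum * refine(base, e[i, ], e[j, ], 0, 1, 0, 1, whole, 0L)
    }
  }
  2 * total / (4 * pi)  # ordered pairs double the unordered sum
}

# Gauss-Legendre nodes/weights on [0, 1]
gauss_legendre_01 <- function(k) {
  # Golub-Welsch: eigen-decomposition of the Jacobi matrix on [-1, 1]
  i <- seq_len(k - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, k, k)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  ev <- eigen(J, symmetric = TRUE)
  x <- ev$values
  w <- 2 * ev$vectors[1L, ]^2
  ord <- order(x)
  list(x = (x[ord] + 1) / 2, w = w[ord] / 2)
}

#' All geometric compactness measures of a polygon
#'
#' Convenience wrapper returning the radius of gyration, minimal enclosing
#' sphere radius and volume, convex hull volume, total curvature, signed and
#' absolute total torsion, and the Monte-Carlo average crossing number.
#'
#' @param p a [knot_polygon()].
#' @param acn_dirs directions for the ACN estimate.
#' @return a one-row data frame with columns `Rg`, `RS`, `V_sphere`,
#'   `V_hull`, `curv_total`, `tors_signed`, `tors_abs`, `acn`, `acn_stderr`.
#' @export
geometric_summary <- function(p, acn_dirs = 100L) {
  v <- vertices_of(p)
  ms <- min_enclosing_sphere(v)
  tors <- total_torsion(v)
  acn <- acn_projection_mc(v, acn_dirs)
  vol <- suppressWarnings(hull_volume(v))
  data.frame(Rg = radius_of_gyration(v), RS = ms$radius,
             V_sphere = sphere_volume(ms$radius), V_hull = vol,
             curv_total = total_curvature(v), tors_signed = tors$signed,
             tors_abs = tors$absolute, acn = acn$acn, acn_stderr = acn$stderr)
}
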
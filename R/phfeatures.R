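#' Interpolated point cloud along a polygon
#'
#' Replaces each unit edge by `s` equally spaced samples (including the
#' starting vertex, so consecutive samples are exactly `1/s` apart and every
#' vertex appears once).  The default `s = 10` gives spacing 0.1, the
#' sampling density of the study protocol: the short-lived Rips classes at
#' sharp vertex angles are then born just after filtration value 0.1.
#'
#' @param p a [knot_polygon()] or vertex matrix of a closed polygon.
#' @param s samples per edge.
#' @return a `knot_cloud`: `(n s) x 3` matrix of points, with attribute
#'   `samples_per_edge`.
#' @export
interpolate_polygon <- function(p, s = 10L) {
  s <- as.integer(s)
  if (s < 1L) stop("s must be >= 1")
  v <- if (inherits(p, "knot_polygon")) vertices_of(p) else as.matrix(p)
  n <- nrow(v)
  nxt <- rbind(v[-1L, , drop = FALSE], v[1L, , drop = FALSE])
  pts <- matrix(0, n * s, 3L)
  row <- 1L
  for (i in seq_len(n)) for (j in seq_len(s)) {
    pts[row, ] <- v[i, ] + ((j - 1L) / s) * (nxt[i, ] - v[i, ])
    row <- row + 1L
  }
  structure(pts, samples_per_edge = s, class = "knot_cloud")
}

#' Dimension-1 Vietoris-Rips barcode
#'
#' Computes the dimension-1 persistence of the Vietoris-Rips filtration of a
#' point cloud, with filtration values in the pairwise-distance ("diameter")
#' scale.  The engine performs persistent-cohomology reduction with
#' clearing and implicit coboundary columns; the filtration is truncated at
#' the enclosing radius, beyond which the complex is a cone and no
#' dimension-1 class survives, so every interval is recovered exactly.
#' On a finite cloud all dimension-1 classes die, so all intervals are
#' finite; zero-persistence pairs are discarded.
#'
#' @param cloud point matrix (rows are points).
#' @return a `rips_barcode`: matrix with columns `birth`, `death`, ordered
#'   by birth.
#' @export
rips_h1_barcode <- function(cloud) {
  cloud <- unclass(as.matrix(cloud))
  if (nrow(cloud) < 3L) return(new_barcode(matrix(numeric(0), 0L, 2L)))
  b <- rips_h1_cpp(cloud)
  new_barcode(b[order(b[, 1L], b[, 2L]), , drop = FALSE])
}

new_barcode <- function(m) {
  colnames(m) <- c("birth", "death")
  structure(m, class = "rips_barcode")
}

#' @export
print.rips_barcode <- function(x, ...) {
  cat(sprintf("dimension-1 Rips barcode: %d intervals\n", nrow(x)))
  if (nrow(x)) {
    cat(sprintf("  total persistence %.4g, longest bar %.4g\n",
                integral_I(x), max_bar_M(x)))
  }
  invisible(x)
}

#' Reference dimension-1 persistence by explicit boundary reduction
#'
#' Independent oracle for [rips_h1_barcode()]: builds the full Rips
#' filtration through 2-simplices explicitly and reduces the dimension-2
#' boundary matrix over the two-element field with the standard column
#' algorithm.  Intended for verification only; refuses clouds with more
#' than 60 points.
#'
#' @param cloud point matrix with at most 60 rows.
#' @return a `rips_barcode`.
#' @export
reference_persistence_h1 <- function(cloud) {
  cloud <- unclass(as.matrix(cloud))
  m <- nrow(cloud)
  if (m > 60L) stop("reference_persistence_h1 is an oracle; use <= 60 points")
  if (m < 3L) return(new_barcode(matrix(numeric(0), 0L, 2L)))
  D <- as.matrix(stats::dist(cloud))
  edges <- t(utils::combn(m, 2L))
  ediam <- D[edges]
  eord <- order(ediam, edges[, 2L], edges[, 1L])
  edges <- edges[eord, , drop = FALSE]
  ediam <- ediam[eord]
  erank <- matrix(0L, m, m)
  for (r in seq_len(nrow(edges))) {
    erank[edges[r, 1L], edges[r, 2L]] <- r
    erank[edges[r, 2L], edges[r, 1L]] <- r
  }
  tris <- t(utils::combn(m, 3L))
  tdiam <- pmax(D[tris[, c(1L, 2L)]], D[tris[, c(1L, 3L)]], D[tris[, c(2L, 3L)]])
  tord <- order(tdiam, tris[, 3L], tris[, 2L], tris[, 1L])
  tris <- tris[tord, , drop = FALSE]
  tdiam <- tdiam[tord]
  low_owner <- integer(nrow(edges))
  cols <- vector("list", nrow(tris))
  xor_sorted <- function(a, b) {
    s <- sort(c(a, b))
    s[!(duplicated(s) | duplicated(s, fromLast = TRUE))]
  }
  birth <- death <- numeric(0)
  for (ti in seq_len(nrow(tris))) {
    tr <- tris[ti, ]
    col <- sort(c(erank[tr[1L], tr[2L]], erank[tr[1L], tr[3L]], erank[tr[2L], tr[3L]]))
    repeat {
      if (length(col) == 0L) break
      lw <- col[length(col)]
      if (low_owner[lw] == 0L) {
        low_owner[lw] <- ti
        cols[[ti]] <- col
        if (tdiam[ti] > ediam[lw]) {
          birth <- c(birth, ediam[lw])
          death <- c(death, tdiam[ti])
        }
        break
      }
      col <- xor_sorted(col, cols[[low_owner[lw]]])
    }
  }
  b <- cbind(birth, death)
  new_barcode(b[order(b[, 1L], b[, 2L]), , drop = FALSE])
}

#' Betti curve of a barcode
#'
#' The integer step function whose value at `t` is the number of intervals
#' with `birth <= t < death` (closed at birth, open at death).  Represented
#' by ascending breakpoints and the value on each interval
#' `[break_i, break_{i+1})`; the value before the first breakpoint is 0 and
#' the value from the last breakpoint on is 0.
#'
#' @param b a `rips_barcode` (or 2-column matrix).
#' @return a `betti_curve`: list with `breaks` and `values`.
#' @export
betti_curve <- function(b) {
  b <- as.matrix(b)
  if (nrow(b) == 0L)
    return(structure(list(breaks = numeric(0), values = numeric(0)),
                     class = "betti_curve"))
  brk <- sort(unique(c(b[, 1L], b[, 2L])))
  val <- vapply(brk, function(t) sum(b[, 1L] <= t & t < b[, 2L]), numeric(1))
  structure(list(breaks = brk, values = val), class = "betti_curve")
}

#' @export
print.betti_curve <- function(x, ...) {
  cat(sprintf("Betti curve: %d breakpoints, max %s, integral %.4g\n",
              length(x$breaks),
              if (length(x$values)) format(max(c(0, x$values))) else "0",
              betti_integral(x)))
  invisible(x)
}

#' @export
plot.betti_curve <- function(x, ...) {
  if (length(x$breaks) == 0L) {
    graphics::plot(0, 0, type = "n", xlab = "t", ylab = "beta1", ...)
    return(invisible(x))
  }
  graphics::plot(stats::stepfun(x$breaks, c(0, x$values), right = FALSE),
                 do.points = FALSE, xlab = "t (diameter scale)",
                 ylab = "beta1", ...)
  invisible(x)
}

#' Evaluate a Betti curve
#'
#' @param curve a `betti_curve`.
#' @param t numeric vector of filtration values.
#' @return the curve's values at `t`.
#' @export
betti_at <- function(curve, t) {
  if (length(curve$breaks) == 0L) return(rep(0, length(t)))
  idx <- findInterval(t, curve$breaks)
  out <- numeric(length(t))
  pos <- idx >= 1L
  out[pos] <- curve$values[idx[pos]]
  out
}

# integral of a step curve (real-valued allowed); the final value is 0
betti_integral <- function(curve) {
  k <- length(curve$breaks)
  if (k < 2L) return(0)
  sum(curve$values[-k] * diff(curve$breaks))
}

#' Barcode summary features
#'
#' `integral_I` is the sum of interval lengths (equal to the integral of the
#' Betti curve), `max_bar_M` the length of the longest bar (0 if empty), and
#' `num_bars_B` the interval count.
#'
#' @param b a `rips_barcode`.
#' @return a length-1 numeric (integer for `num_bars_B`).
#' @export
integral_I <- function(b) {
  b <- as.matrix(b)
  if (nrow(b) == 0L) return(0)
  sum(b[, 2L] - b[, 1L])
}

#' @rdname integral_I
#' @export
max_bar_M <- function(b) {
  b <- as.matrix(b)
  if (nrow(b) == 0L) return(0)
  max(b[, 2L] - b[, 1L])
}

#' @rdname integral_I
#' @export
num_bars_B <- function(b) nrow(as.matrix(b))

#' Remove the short-lived vertex-angle spike bars
#'
#' Two consecutive unit edges meeting at an internal angle below
#' `arccos(3/4) ~ 41.4` degrees produce a short-lived dimension-1 class in
#' the Rips filtration of the sampled cloud, born just after the sample
#' spacing 0.1.  This filter drops intervals with birth in
#' `[birth_lo, birth_hi]` and persistence at most `max_persistence`; the
#' defaults cover the spike geometry for spacing 0.1.  The filter is
#' idempotent.
#'
#' @param b a `rips_barcode`.
#' @param birth_lo,birth_hi birth window of the spike.
#' @param max_persistence maximal persistence of a discarded bar.
#' @return the filtered `rips_barcode`.
#' @export
spike_filter <- function(b, birth_lo = 0.10, birth_hi = 0.13,
                         max_persistence = 0.05) {
  if (birth_lo > birth_hi) stop("birth_lo must be <= birth_hi")
  if (max_persistence < 0) stop("max_persistence must be >= 0")
  m <- as.matrix(b)
  if (nrow(m) == 0L) return(new_barcode(m))
  keep <- !(m[, 1L] >= birth_lo & m[, 1L] <= birth_hi &
              (m[, 2L] - m[, 1L]) <= max_persistence)
  new_barcode(m[keep, , drop = FALSE])
}

#' Average of Betti curves
#'
#' Pointwise mean of step curves on the merged breakpoint grid; the result
#' is a real-valued step curve of the same form.
#'
#' @param curves non-empty list of `betti_curve` objects.
#' @return a `betti_curve` with real values.
#' @export
average_betti_curve <- function(curves) {
  if (length(curves) == 0L) stop("need at least one curve")
  brk <- sort(unique(unlist(lapply(curves, function(cv) cv$breaks))))
  if (length(brk) == 0L)
    return(structure(list(breaks = numeric(0), values = numeric(0)),
                     class = "betti_curve"))
  vals <- rowMeans(vapply(curves, function(cv) betti_at(cv, brk),
                          numeric(length(brk))))
  structure(list(breaks = brk, values = vals), class = "betti_curve")
}

#' Location and height of a curve's maximum
#'
#' Returns the smallest breakpoint attaining the maximal value of the step
#' curve.
#'
#' @param curve a `betti_curve`.
#' @return list with `t` and `value`.
#' @export
curve_max <- function(curve) {
  if (length(curve$values) == 0L) return(list(t = 0, value = 0))
  i <- which.max(curve$values)  # first index attaining the maximum
  list(t = curve$breaks[i], value = curve$values[i])
}

#' Critical vertex angle of the Rips spike
#'
#' The largest internal angle between two consecutive unit edges, sampled at
#' `spacing`, for which the local point configuration carries an extra
#' short-lived dimension-1 Rips class.  Located by bisection on the angle,
#' deciding presence by running the persistence engine on the two-segment
#' cloud.  The closed-form critical angle is `arccos(3/4)`: the class exists
#' while the distance between the two second samples, `4 d sin(theta/2)`,
#' is below the cross distance `d sqrt(5 - 4 cos theta)`.
#'
#' @param spacing sample spacing along the segments.
#' @param lower,upper initial bisection bracket in degrees.
#' @param tol_deg bisection tolerance in degrees.
#' @return the critical angle in degrees.
#' @export
critical_spike_angle <- function(spacing = 0.1, lower = 20, upper = 60,
                                 tol_deg = 0.01) {
  has_class <- function(theta_deg) {
    th <- theta_deg * pi / 180
    r <- seq(0, 1, by = spacing)
    cloud <- rbind(cbind(r, 0, 0),
                   cbind(rev(r[-1L]) * cos(th), rev(r[-1L]) * sin(th), 0))
    nrow(rips_h1_barcode(cloud)) > 0L
  }
  if (!has_class(lower) || has_class(upper))
    stop("bisection bracket does not straddle the critical angle")
  while (upper - lower > tol_deg) {
    mid <- (lower + upper) / 2
    if (has_class(mid)) lower <- mid else upper <- mid
  }
  (lower + upper) / 2
}
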
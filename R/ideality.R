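#' Support of a Betti curve
#'
#' The largest filtration value at which the curve is still positive, i.e.
#' the largest death in the underlying barcode.
#'
#' @param curve a `betti_curve`, not identically zero.
#' @return a length-1 numeric.
#' @export
support_S <- function(curve) {
  if (length(curve$values) == 0L || all(curve$values == 0))
    stop("support undefined: curve is identically zero")
  j <- max(which(curve$values > 0))
  if (j == length(curve$breaks))
    stop("curve does not return to zero")  # cannot happen for finite barcodes
  curve$breaks[j + 1L]
}

#' Linear cut-off weight
#'
#' The function equal to 1 at 0, decreasing linearly to 0 at `R - epsilon`,
#' and identically 0 on `(R - epsilon, R]`.  It preserves the contribution
#' of early bars and erases bars appearing towards the end of the support.
#'
#' @param R right end of the domain.
#' @param epsilon cut-off, `0 < epsilon < R`.
#' @param t evaluation points in `[0, R]`.
#' @return numeric vector of weights.
#' @export
weight_f <- function(R, epsilon, t) {
  if (epsilon <= 0 || epsilon >= R) stop("need 0 < epsilon < R")
  ifelse(t <= R - epsilon, pmax(0, 1 - t / (R - epsilon)), 0)
}

#' Deviation from ideality
#'
#' An ideal (ropelength-minimizing) embedding has a Betti curve pinned at 1
#' until the injectivity radius, where it jumps; deviations from ideality
#' show up as excess first homology spread over the support.  This statistic
#' averages the excess `max(beta1 - 1, 0)`, weighted by [weight_f()] so that
#' late-appearing bars do not contribute:
#' `delta = (1/S) integral_0^S f_{S,eps}(t) max(beta1(t) - 1, 0) dt`,
#' with `S` the support of the curve.  The integral is evaluated in closed
#' form piecewise over the step intervals.  The statistic is 0 exactly when
#' the weighted region never sees more than one homology class, and it is
#' invariant under rigid motions and uniform rescaling of the underlying
#' cloud.
#'
#' @param curve a `betti_curve` (integer or real valued), not identically 0.
#' @param epsilon cut-off of the weight, `0 < epsilon < S`.
#' @return an `ideality_result`: list with `S`, `epsilon`, `delta`.
#' @export
delta_ideality <- function(curve, epsilon = 0.1) {
  S <- support_S(curve)
  if (epsilon <= 0 || epsilon >= S) stop("need 0 < epsilon < S")
  Re <- S - epsilon
  brk <- curve$breaks
  val <- pmax(curve$values - 1, 0)
  total <- 0
  for (i in seq_len(length(brk) - 1L)) {
    if (val[i] == 0) next
    a <- brk[i]
    b <- min(brk[i + 1L], Re)
    if (b <= a) next
    # integral of (1 - t/Re) over [a, b]
    total <- total + val[i] * ((b - a) - (b^2 - a^2) / (2 * Re))
  }
  structure(list(S = S, epsilon = epsilon, delta = total / S),
            class = "ideality_result")
}

#' @export
print.ideality_result <- function(x, ...) {
  cat(sprintf("support S = %.4g, epsilon = %.3g, delta = %.6g\n",
              x$S, x$epsilon, x$delta))
  invisible(x)
}

#' Polygonal trefoil family
#'
#' Equilateral polygonal trefoils from the parametric (2,3) torus curve
#' `((R + r cos 3u) cos 2u, (R + r cos 3u) sin 2u, r sin 3u)`:
#' `balanced` uses `(R, r) = (2, 1)` (a well-proportioned embedding, the
#' stand-in for a near-ideal configuration), `elongated` uses
#' `(R, r) = (5, 1)` (longitude much longer than the meridian), and
#' `flattened` is the balanced curve with its `z` coordinate scaled by
#' 0.05 (close to planar).  The curve is resampled to `n` equal-arclength
#' points and projected to exact unit edges.
#'
#' @param kind one of `"balanced"`, `"elongated"`, `"flattened"`.
#' @param n number of edges, at least 30.
#' @return a [knot_polygon()].
#' @export
trefoil_family <- function(kind = c("balanced", "elongated", "flattened"),
                           n = 120L) {
  kind <- match.arg(kind)
  if (n < 30L) stop("n must be >= 30 to keep the knot type")
  Rr <- switch(kind, balanced = c(2, 1), elongated = c(5, 1), flattened = c(2, 1))
  zscale <- if (kind == "flattened") 0.05 else 1
  u <- seq(0, 2 * pi, length.out = 20000L + 1L)[-1L]
  curve <- cbind((Rr[1L] + Rr[2L] * cos(3 * u)) * cos(2 * u),
                 (Rr[1L] + Rr[2L] * cos(3 * u)) * sin(2 * u),
                 zscale * Rr[2L] * sin(3 * u))
  seg <- sqrt(rowSums((curve - rbind(curve[nrow(curve), ], curve[-nrow(curve), ]))^2))
  arc <- cumsum(seg)
  total <- arc[length(arc)]
  targets <- total * (seq_len(n) - 1L) / n
  idx <- findInterval(targets, c(0, arc))
  v <- curve[pmin(pmax(idx, 1L), nrow(curve)), , drop = FALSE]
  v <- v / (total / n)  # rescale so chords are near unit
  equilateralize(v, tol = 1e-12)
}
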
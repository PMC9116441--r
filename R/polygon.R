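#' Closed equilateral polygons in 3-space
#'
#' A `knot_polygon` is an ordered cycle of `n` vertices in 3-space in which
#' every edge (vertex `i` to vertex `i + 1`, cyclically) has unit length, so
#' the polygon's length equals its number of edges.  These piecewise-linear
#' curves are the knot embeddings the rest of the package analyses.
#'
#' @param vertices numeric `n x 3` matrix of vertex coordinates.
#' @param validate check the unit-edge and closure invariants.
#' @param tol absolute tolerance for the invariants.
#' @return an object of class `knot_polygon`: the vertex matrix with the
#'   class attribute set.
#' @export
knot_polygon <- function(vertices, validate = TRUE, tol = 1e-9) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (nrow(vertices) < 3L) stop("a polygon needs at least 3 vertices")
  dimnames(vertices) <- list(NULL, c("x", "y", "z"))
  if (validate) {
    el <- edge_lengths(vertices)
    if (max(abs(el - 1)) > tol)
      stop(sprintf("edge lengths deviate from 1 by %.3g (tol %.3g)",
                   max(abs(el - 1)), tol))
    edges <- rbind(vertices[-1L, , drop = FALSE], vertices[1L, , drop = FALSE]) - vertices
    defect <- sqrt(sum(colSums(edges)^2))
    if (defect > tol)
      stop(sprintf("closure defect %.3g exceeds tolerance %.3g", defect, tol))
  }
  structure(vertices, class = "knot_polygon")
}

#' @export
print.knot_polygon <- function(x, ...) {
  el <- edge_lengths(x)
  cat(sprintf("closed equilateral polygon: %d unit edges (max |len-1| = %.2g)\n",
              nrow(x), max(abs(el - 1))))
  invisible(x)
}

#' @export
plot.knot_polygon <- function(x, ...) {
  v <- rbind(unclass(x), unclass(x)[1L, , drop = FALSE])
  graphics::plot(v[, 1L], v[, 2L], type = "l", asp = 1,
                 xlab = "x", ylab = "y", ...)
  invisible(x)
}

vertices_of <- function(p) {
  v <- unclass(as_knot_polygon(p, validate = FALSE))
  attr(v, "class") <- NULL
  v
}

as_knot_polygon <- function(p, validate = TRUE, tol = 1e-9) {
  if (inherits(p, "knot_polygon")) return(p)
  knot_polygon(p, validate = validate, tol = tol)
}

edge_lengths <- function(v) {
  v <- unclass(v)
  e <- rbind(v[-1L, , drop = FALSE], v[1L, , drop = FALSE]) - v
  sqrt(rowSums(e^2))
}

#' Planar regular polygon with unit edges
#'
#' The regular `n`-gon in the `z = 0` plane scaled so that every edge has
#' length exactly 1 (circumradius `1 / (2 sin(pi/n))`).  Used as the initial
#' state of the crankshaft Markov chain.
#'
#' @param n number of edges (at least 3).
#' @return a [knot_polygon()].
#' @export
regular_polygon <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 3L) stop("n must be an integer >= 3")
  r <- 1 / (2 * sin(pi / n))
  th <- 2 * pi * (seq_len(n) - 1L) / n
  knot_polygon(cbind(r * cos(th), r * sin(th), 0), validate = TRUE, tol = 1e-9)
}

#' Re-equilateralize a polygon
#'
#' Projects a nearly-equilateral closed polygon back onto the space of exactly
#' unit-edge closed polygons by alternating unit normalization of the edge
#' vectors with removal of the closure defect.  Used every
#' `reproject_every` crankshaft steps to control floating-point drift.
#'
#' @param p polygon or vertex matrix.
#' @param tol convergence tolerance on edge lengths and closure.
#' @return a [knot_polygon()].
#' @export
equilateralize <- function(p, tol = 1e-12) {
  v <- if (inherits(p, "knot_polygon")) vertices_of(p) else as.matrix(p)
  knot_polygon(equilateralize_cpp(v, tol), validate = TRUE, tol = 1e-9)
}

#' Single crankshaft move
#'
#' Chooses two distinct vertices uniformly at random and rigidly rotates the
#' sub-chain strictly between them (walking forward from the first) about the
#' chord through them, by an angle uniform on `[0, 2 pi)`.  The move is an
#' isometry of the sub-chain, so edge lengths and closure are preserved to
#' machine precision.  Uses R's random number generator.
#'
#' @param p a [knot_polygon()].
#' @return the moved [knot_polygon()].
#' @export
crankshaft_step <- function(p) {
  v <- vertices_of(p)
  n <- nrow(v)
  repeat {
    ij <- sample.int(n, 2L)
    chord <- v[ij[2L], ] - v[ij[1L], ]
    if (sqrt(sum(chord^2)) >= 1e-12) break
  }
  theta <- runif(1L, 0, 2 * pi)
  knot_polygon(rotate_subchain_cpp(v, ij[1L] - 1L, ij[2L] - 1L, theta),
               validate = TRUE, tol = 1e-9)
}

#' Sample a random closed equilateral polygon
#'
#' Runs a crankshaft Markov chain started from the planar regular polygon.
#' The chain is ergodic on the space of closed equilateral polygons and
#' approximates the uniform distribution after a burn-in of `n_steps` moves;
#' the default `30 * n` moves is a mixing heuristic (see the package
#' vignette).  Every 1000 steps, and at the end, the polygon is re-projected
#' to exact unit edges and closure.
#'
#' @param n number of edges.
#' @param n_steps number of crankshaft moves (default `30 * n`).
#' @param reproject_every drift-control interval.
#' @return a [knot_polygon()].
#' @export
sample_random_polygon <- function(n, n_steps = 30L * n, reproject_every = 1000L) {
  if (n_steps < 1L) stop("n_steps must be >= 1")
  v <- vertices_of(regular_polygon(n))
  knot_polygon(crankshaft_chain_cpp(v, as.integer(n_steps),
                                    as.integer(reproject_every)),
               validate = TRUE, tol = 1e-9)
}

#' Sample a polygon of fixed knot type by rejection
#'
#' Draws random polygons with [sample_random_polygon()] and keeps the first
#' whose classified knot type (see [classify_knot()]) matches `type`.
#'
#' @param n number of edges.
#' @param type a label among `0_1, 3_1, 4_1, 5_1, 5_2, 6_1, 6_2, 6_3,
#'   unknown`.
#' @param max_attempts rejection budget.
#' @param n_steps,n_tries passed to the sampler and the classifier.
#' @return a [knot_polygon()] with attribute `attempts` (number of draws).
#' @export
sample_fixed_type <- function(n, type, max_attempts = 10000L,
                              n_steps = 30L * n, n_tries = 5L) {
  if (!type %in% c(knot_type_labels(), "unknown"))
    stop("unsupported knot type label: ", type)
  if (max_attempts < 1L) stop("max_attempts must be >= 1")
  for (attempt in seq_len(max_attempts)) {
    p <- sample_random_polygon(n, n_steps)
    if (classify_knot(p, n_tries = n_tries) == type) {
      attr(p, "attempts") <- attempt
      return(p)
    }
  }
  stop(sprintf("no %s found among %d polygons of length %d",
               type, max_attempts, n))
}
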
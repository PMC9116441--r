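#' Knot diagrams from generic planar projection
#'
#' Projects the polygon orthogonally onto the plane normal to `direction`,
#' finds all transverse crossings of the projected edges, orders them along
#' the curve, and assigns over/under by depth along `direction` and crossing
#' signs by the right-hand convention.  Projections within `tol` of a
#' degeneracy (a crossing at a vertex image, equal depths, near-parallel
#' overlapping edges, an edge parallel to the direction) raise a
#' `knotph_degenerate_projection` condition; callers retry with a fresh
#' random direction.
#'
#' @param p a [knot_polygon()] (or vertex matrix).
#' @param direction unit 3-vector to project along.
#' @param tol degeneracy tolerance in projected coordinates.
#' @return a `knot_diagram`: data frame with columns `crossing`, `over`,
#'   `sign`, one row per passage in order along the curve.
#' @export
project_to_diagram <- function(p, direction, tol = 1e-9) {
  v <- vertices_of(p)
  direction <- as.numeric(direction)
  nd <- sqrt(sum(direction^2))
  if (abs(nd - 1) > 1e-6) stop("direction must be a unit vector")
  res <- project_diagram_cpp(v, direction, tol)
  if (isTRUE(res$degenerate)) {
    cond <- structure(
      class = c("knotph_degenerate_projection", "error", "condition"),
      list(message = "degenerate projection", call = sys.call()))
    stop(cond)
  }
  k <- length(res$edge_a)
  if (k == 0L) return(new_knot_diagram(integer(0), logical(0), integer(0)))
  # two passages per crossing, ordered along the curve by (edge, parameter)
  pos_edge <- c(res$edge_a, res$edge_b)
  pos_par <- c(res$s_a, res$s_b)
  crossing <- c(seq_len(k), seq_len(k))
  over <- c(res$a_over == 1L, res$a_over != 1L)
  sgn <- c(res$sign, res$sign)
  ord <- order(pos_edge, pos_par)
  new_knot_diagram(crossing[ord], over[ord], sgn[ord])
}

new_knot_diagram <- function(crossing, over, sign) {
  d <- data.frame(crossing = as.integer(crossing), over = as.logical(over),
                  sign = as.integer(sign))
  class(d) <- c("knot_diagram", "data.frame")
  d
}

#' @export
print.knot_diagram <- function(x, ...) {
  cat(sprintf("knot diagram with %d crossings\n", nrow(x) / 2L))
  if (nrow(x)) {
    code <- paste0(ifelse(x$over, "O", "U"), x$crossing,
                   ifelse(x$sign > 0, "+", "-"), collapse = " ")
    cat(strwrap(code, width = 70), sep = "\n")
  }
  invisible(x)
}

n_crossings <- function(d) nrow(d) / 2L

#' Simplify a Gauss code by Reidemeister I and II moves
#'
#' Repeatedly removes kinks (a crossing whose two passages are cyclically
#' adjacent) and cancelling pairs (two crossings adjacent on both strands
#' with one strand passing over at both and the other under at both) until
#' neither rule fires.  Both moves preserve the knot type; the point is to
#' shrink the Alexander matrix.
#'
#' @param d a `knot_diagram`.
#' @return the simplified `knot_diagram`.
#' @export
simplify_gauss <- function(d) {
  crossing <- d$crossing; over <- d$over; sgn <- d$sign
  repeat {
    m <- length(crossing)
    if (m == 0L) break
    nxt <- c(seq_len(m)[-1L], 1L)
    removed <- FALSE
    # Reidemeister I: the two passages of one crossing are adjacent
    for (i in seq_len(m)) {
      j <- nxt[i]
      if (crossing[i] == crossing[j]) {
        keep <- crossing != crossing[i]
        crossing <- crossing[keep]; over <- over[keep]; sgn <- sgn[keep]
        removed <- TRUE
        break
      }
    }
    if (removed) next
    # Reidemeister II: ids a, b adjacent at two loci; one strand passes over
    # at both, hence (each id having one over and one under passage) the
    # other locus is automatically all-under
    for (i in seq_len(m)) {
      j <- nxt[i]
      a <- crossing[i]; b <- crossing[j]
      if (a == b || over[i] != over[j]) next
      ka <- setdiff(which(crossing == a), i)
      kb <- setdiff(which(crossing == b), j)
      if (nxt[ka] == kb || nxt[kb] == ka) {
        keep <- !(crossing %in% c(a, b))
        crossing <- crossing[keep]; over <- over[keep]; sgn <- sgn[keep]
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }
  new_knot_diagram(crossing, over, sgn)
}

#' Alexander polynomial of a knot diagram
#'
#' Builds the Wirtinger/Fox-calculus Alexander matrix of the diagram (one
#' relation per crossing over the arcs), deletes one row and one column, and
#' evaluates the determinant over the prime field with `p = 2^31 - 1` at
#' enough points to interpolate the polynomial exactly.  The result is
#' normalized so the lowest degree is 0 and the value at `t = 1` is `+1`;
#' for a knot the normalized coefficient sequence is palindromic.
#'
#' @param d a `knot_diagram` (ideally after [simplify_gauss()]).
#' @return integer vector of coefficients, constant term first.  The empty
#'   diagram gives `1`.
#' @export
alexander_poly <- function(d) {
  if (nrow(d) == 0L) return(1L)
  tab <- table(d$crossing)
  if (any(tab != 2L)) stop("invalid Gauss code: each crossing must appear twice")
  co <- alexander_coeffs_cpp(match(d$crossing, sort(unique(d$crossing))),
                             as.integer(d$over), as.integer(d$sign))
  if (length(co) == 0L)
    stop("Alexander normalization failed (|Delta(1)| != 1)")
  co
}

# normalized Alexander coefficient sequences (value +1 at t = 1) for the
# prime knot types through six crossings; all eight are pairwise distinct,
# so the lookup identifies them uniquely
alexander_table <- list(
  "0_1" = c(1L),
  "3_1" = c(1L, -1L, 1L),
  "4_1" = c(-1L, 3L, -1L),
  "5_1" = c(1L, -1L, 1L, -1L, 1L),
  "5_2" = c(2L, -3L, 2L),
  "6_1" = c(-2L, 5L, -2L),
  "6_2" = c(-1L, 3L, -3L, 3L, -1L),
  "6_3" = c(1L, -3L, 5L, -3L, 1L)
)

knot_type_labels <- function() names(alexander_table)

lookup_alexander <- function(co) {
  key <- paste(co, collapse = " ")
  for (lab in names(alexander_table))
    if (identical(key, paste(alexander_table[[lab]], collapse = " "))) return(lab)
  "unknown"
}

random_unit_vector <- function() {
  repeat {
    u <- rnorm(3L)
    nu <- sqrt(sum(u^2))
    if (nu > 1e-6) return(u / nu)
  }
}

#' Classify the knot type of a polygon
#'
#' For up to `n_tries` random projection directions: project to a diagram,
#' simplify, and compute the normalized Alexander polynomial; degenerate
#' projections are redrawn (budget `max_directions`).  The label is the
#' majority vote over successful projections of the lookup among the prime
#' knot types through six crossings; sequences matching none are "unknown",
#' and ties vote "unknown".  A trivial polynomial is labelled `0_1` (the
#' Alexander polynomial cannot distinguish certain large knots from the
#' unknot; the first examples have 11 crossings, far beyond the lengths
#' studied here).
#'
#' @param p a [knot_polygon()].
#' @param n_tries number of independent projections to vote over.
#' @param tol projection degeneracy tolerance.
#' @param max_directions total direction budget across retries.
#' @return a character label, with attribute `alexander` holding the
#'   coefficient vector of the last successful projection.
#' @export
classify_knot <- function(p, n_tries = 5L, tol = 1e-9, max_directions = 20L) {
  v <- vertices_of(p)
  labels <- character(0)
  co <- NULL
  draws <- 0L
  while (length(labels) < n_tries && draws < max_directions) {
    draws <- draws + 1L
    res <- tryCatch(project_to_diagram(v, random_unit_vector(), tol),
                    knotph_degenerate_projection = function(e) NULL)
    if (is.null(res)) next
    co <- alexander_poly(simplify_gauss(res))
    labels <- c(labels, lookup_alexander(co))
  }
  if (length(labels) == 0L) stop("classification failed: all projections degenerate")
  counts <- sort(table(labels), decreasing = TRUE)
  lab <- if (length(counts) > 1L && counts[1L] == counts[2L]) "unknown"
         else names(counts)[1L]
  structure(lab, alexander = co)
}
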
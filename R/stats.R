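#' Full feature record of one polygon
#'
#' Computes every per-knot descriptor used in the statistical analyses: the
#' knot type label, the dimension-1 Rips barcode features of the
#' interpolated cloud (`I`, `M`, `num_bars`), the deviation-from-ideality
#' statistic, and the geometric compactness measures.
#'
#' @param p a [knot_polygon()].
#' @param s samples per edge for the point cloud.
#' @param epsilon cut-off for [delta_ideality()].
#' @param acn_dirs directions for the Monte-Carlo ACN.
#' @param classify compute the knot type label (set `FALSE` to skip the
#'   projection classifier when labels are not needed).
#' @param n_tries projections voted over by the classifier.
#' @param use_spike_filter drop the short-lived vertex-angle bars before
#'   computing features (the default keeps them; see the vignette).
#' @return a one-row data frame; the polygon's Betti curve is attached as
#'   attribute `curve`.
#' @export
knot_features <- function(p, s = 10L, epsilon = 0.1, acn_dirs = 100L,
                          classify = TRUE, n_tries = 5L,
                          use_spike_filter = FALSE) {
  p <- as_knot_polygon(p)
  bc <- rips_h1_barcode(interpolate_polygon(p, s))
  if (use_spike_filter) bc <- spike_filter(bc)
  curve <- betti_curve(bc)
  delta <- if (num_bars_B(bc) > 0L) {
    S <- support_S(curve)
    if (epsilon < S) delta_ideality(curve, epsilon)$delta else NA_real_
  } else NA_real_
  geo <- geometric_summary(p, acn_dirs)
  out <- cbind(data.frame(length = nrow(p),
                          type = if (classify) as.character(classify_knot(p, n_tries))
                                 else NA_character_,
                          I = integral_I(bc), M = max_bar_M(bc),
                          num_bars = num_bars_B(bc), delta_epsilon = delta,
                          stringsAsFactors = FALSE),
               geo)
  attr(out, "curve") <- curve
  out
}

# derive a per-polygon seed from the root seed and a counter (kept below
# 2^31 so it is a valid R seed)
derive_seed <- function(seed, counter) {
  (as.numeric(seed) + 1000003 * as.numeric(counter)) %% 2147483647
}

#' Random-knot dataset across lengths
#'
#' Emulates the study's first dataset: for each length, samples
#' `n_per_length` random closed equilateral polygons and computes all
#' feature-record fields.  Each polygon runs on its own seed derived from
#' `seed` and a counter, so datasets are reproducible record by record.
#'
#' @param lengths integer vector of polygon lengths (study protocol:
#'   10 to 100 in steps of 10).
#' @param n_per_length polygons per length (study scale 10^4; desk scale
#'   200).
#' @param seed root seed.
#' @param ... passed to [knot_features()].
#' @return a `knot_dataset`: list with `features` (data frame, one row per
#'   polygon) and `curves` (list of Betti curves, aligned with rows).
#' @export
build_dataset1 <- function(lengths = seq(10L, 100L, by = 10L),
                           n_per_length = 200L, seed = 1L, ...) {
  if (length(lengths) == 0L) stop("lengths must be non-empty")
  rows <- list()
  curves <- list()
  counter <- 0L
  for (n in lengths) {
    for (k in seq_len(n_per_length)) {
      counter <- counter + 1L
      set.seed(derive_seed(seed, counter))
      p <- sample_random_polygon(n)
      fr <- knot_features(p, ...)
      fr$polygon_id <- sprintf("L%03d_%05d", n, k)
      rows[[counter]] <- fr
      curves[[counter]] <- attr(fr, "curve")
    }
  }
  feats <- do.call(rbind, rows)
  rownames(feats) <- NULL
  structure(list(features = feats, curves = curves), class = "knot_dataset")
}

#' Fixed-type dataset across lengths
#'
#' Emulates the study's second dataset: for each knot type and length,
#' rejection-samples `n_per_cell` polygons of that classified type.  Cells
#' whose rejection budget is exhausted are reported as incomplete in the
#' `incomplete` attribute, never padded.
#'
#' @param types character vector of type labels.
#' @param lengths integer vector of lengths (study protocol: 50 to 200 in
#'   steps of 50).
#' @param n_per_cell polygons per (type, length) cell (study scale 10^3).
#' @param seed root seed.
#' @param max_attempts rejection budget per polygon.
#' @param ... passed to [knot_features()].
#' @return a `knot_dataset` as in [build_dataset1()], with an `incomplete`
#'   data frame attribute listing unfilled cells.
#' @export
build_dataset2 <- function(types = c("0_1", "3_1", "4_1"),
                           lengths = seq(50L, 200L, by = 50L),
                           n_per_cell = 50L, seed = 1L,
                           max_attempts = 2000L, ...) {
  rows <- list()
  curves <- list()
  incomplete <- list()
  counter <- 0L
  idx <- 0L
  for (ty in types) {
    for (n in lengths) {
      got <- 0L
      for (k in seq_len(n_per_cell)) {
        counter <- counter + 1L
        set.seed(derive_seed(seed, counter))
        p <- tryCatch(sample_fixed_type(n, ty, max_attempts = max_attempts),
                      error = function(e) NULL)
        if (is.null(p)) next
        fr <- knot_features(p, ...)
        fr$type <- ty  # rejection guarantees the label
        fr$attempts <- attr(p, "attempts")  # rejection cost, auditable per row
        fr$polygon_id <- sprintf("%s_L%03d_%05d", ty, n, k)
        idx <- idx + 1L
        rows[[idx]] <- fr
        curves[[idx]] <- attr(fr, "curve")
        got <- got + 1L
      }
      if (got < n_per_cell)
        incomplete[[length(incomplete) + 1L]] <-
          data.frame(type = ty, length = n, requested = n_per_cell, got = got)
    }
  }
  feats <- if (idx > 0L) do.call(rbind, rows) else NULL
  if (!is.null(feats)) rownames(feats) <- NULL
  structure(list(features = feats, curves = curves), class = "knot_dataset",
            incomplete = if (length(incomplete)) do.call(rbind, incomplete)
                         else NULL)
}

#' @export
print.knot_dataset <- function(x, ...) {
  f <- x$features
  cat(sprintf("knot dataset: %d polygons, lengths %s\n",
              if (is.null(f)) 0L else nrow(f),
              if (is.null(f)) "-" else paste(sort(unique(f$length)), collapse = ", ")))
  inc <- attr(x, "incomplete")
  if (!is.null(inc)) {
    cat("incomplete cells:\n")
    print(inc)
  }
  invisible(x)
}

cor_row <- function(group, xn, yn, x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  pt <- suppressWarnings(cor.test(x, y, method = "pearson"))
  st <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  data.frame(group = group, x = xn, y = yn,
             pearson = unname(pt$estimate), spearman = unname(st$estimate),
             n = length(x), p_pearson = pt$p.value, p_spearman = st$p.value,
             stringsAsFactors = FALSE)
}

correlations_by <- function(ds, x, y, by) {
  f <- if (inherits(ds, "knot_dataset")) ds$features else ds
  if (!all(c(x, y, by) %in% names(f))) stop("unknown feature column")
  groups <- sort(unique(f[[by]]))
  rows <- list()
  for (g in groups) {
    sub <- f[f[[by]] == g, , drop = FALSE]
    ok <- stats::complete.cases(sub[[x]], sub[[y]])
    if (sum(ok) < 3L) {
      warning(sprintf("group %s skipped: fewer than 3 complete records", g))
      next
    }
    rows[[length(rows) + 1L]] <- cor_row(g, x, y, sub[[x]], sub[[y]])
  }
  if (length(rows) == 0L)
    rows <- list(data.frame(group = f[[by]][0], x = character(0),
                            y = character(0), pearson = numeric(0),
                            spearman = numeric(0), n = integer(0),
                            p_pearson = numeric(0), p_spearman = numeric(0),
                            stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  class(out) <- c("correlation_table", "data.frame")
  out
}

#' Per-group correlations between features
#'
#' Pearson and Spearman correlations between two feature columns, grouped
#' by polygon length or knot type; groups with fewer than 3 complete
#' records are skipped with a warning.
#'
#' @param ds a `knot_dataset` (or its `features` data frame).
#' @param x,y feature column names.
#' @return a data frame with columns `group`, `x`, `y`, `pearson`,
#'   `spearman`, `n`, `p_pearson`, `p_spearman`.
#' @export
correlations_by_length <- function(ds, x = "I", y = "V_hull")
  correlations_by(ds, x, y, "length")

#' @rdname correlations_by_length
#' @export
correlations_by_type <- function(ds, x = "I", y = "V_hull")
  correlations_by(ds, x, y, "type")

#' Least-squares line fit
#'
#' Slope, intercept and coefficient of determination of `y` on `x`.
#' A constant response has undefined R-squared, reported as 0 with
#' `degenerate = TRUE`.
#'
#' @param x,y numeric vectors.
#' @return list with `slope`, `intercept`, `r_squared`, `degenerate`.
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) stop("need >= 2 paired values")
  if (stats::var(y) == 0)
    return(list(slope = 0, intercept = y[1L], r_squared = 0, degenerate = TRUE))
  fit <- lm(y ~ x)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn in summary.lm
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r_squared = r2, degenerate = FALSE)
}

#' Per-cell averaged summaries
#'
#' For every (type, length) cell: the mean Betti-curve integral, the
#' averaged Betti curve, and the location/height of its maximum.
#'
#' @param ds a `knot_dataset` with curves.
#' @return a data frame with columns `type`, `length`, `mean_I`,
#'   `curve_max_t`, `curve_max_value`, `n`; the averaged curves are in the
#'   `curves` attribute (named `type:length`).
#' @export
average_summaries <- function(ds) {
  f <- ds$features
  key <- paste(f$type, f$length, sep = ":")
  rows <- list()
  avg_curves <- list()
  for (k in unique(key)) {
    sel <- which(key == k)
    avg <- average_betti_curve(ds$curves[sel])
    cm <- curve_max(avg)
    rows[[length(rows) + 1L]] <-
      data.frame(type = f$type[sel[1L]], length = f$length[sel[1L]],
                 mean_I = mean(f$I[sel]), curve_max_t = cm$t,
                 curve_max_value = cm$value, n = length(sel),
                 stringsAsFactors = FALSE)
    avg_curves[[k]] <- avg
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$type, out$length), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "curves") <- avg_curves
  out
}

#' Split-half robustness of the correlation analysis
#'
#' Randomly halves the dataset, recomputes the per-group correlations on
#' each half, and reports the maximal absolute discrepancy in the Pearson
#' and Spearman coefficients across groups present in both halves.
#'
#' @param ds a `knot_dataset` (or features data frame).
#' @param x,y feature columns.
#' @param by grouping column (`"length"` or `"type"`).
#' @param seed seed for the random halving.
#' @return list with `half1`, `half2` (correlation tables) and
#'   `max_abs_diff`.
#' @export
split_half_robustness <- function(ds, x = "I", y = "V_hull", by = "length",
                                  seed = 1L) {
  f <- if (inherits(ds, "knot_dataset")) ds$features else ds
  set.seed(seed)
  pick <- sample(c(TRUE, FALSE), nrow(f), replace = TRUE)
  h1 <- correlations_by(f[pick, , drop = FALSE], x, y, by)
  h2 <- correlations_by(f[!pick, , drop = FALSE], x, y, by)
  common <- intersect(h1$group, h2$group)
  d <- max(abs(h1$pearson[match(common, h1$group)] -
               h2$pearson[match(common, h2$group)]),
           abs(h1$spearman[match(common, h1$group)] -
               h2$spearman[match(common, h2$group)]))
  list(half1 = h1, half2 = h2, max_abs_diff = d)
}
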
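#' Read and write polygon coordinates
#'
#' Plain-text coordinate files: XYZ style (one `x y z` line per vertex) or
#' CSV with header `x,y,z`.  Writing uses 17 significant digits so a
#' write-read round trip reproduces the coordinates bit-exactly.  Reading
#' validates equilaterality within `tol` and either fails or, with
#' `renormalize = TRUE`, projects the polygon back to exact unit edges.
#'
#' @param path file path.
#' @param renormalize re-equilateralize on read instead of failing.
#' @param tol equilaterality tolerance for validation.
#' @return `read_coords`: a [knot_polygon()].
#' @export
read_coords <- function(path, renormalize = FALSE, tol = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  csv <- length(lines) > 0L && grepl(",", lines[1L])
  if (csv && grepl("[a-zA-Z]", lines[1L])) lines <- lines[-1L]  # header
  vals <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(trimws(lines[i]), if (csv) "," else "[[:space:]]+")[[1L]]
    num <- suppressWarnings(as.numeric(parts))
    if (length(num) != 3L || anyNA(num))
      stop(sprintf("parse error at line %d: expected 3 numbers", i))
    num
  })
  v <- do.call(rbind, vals)
  if (nrow(v) < 3L) stop("need at least 3 vertices")
  el <- edge_lengths(v)
  if (max(abs(el - 1)) > tol) {
    if (!renormalize)
      stop(sprintf("polygon is not equilateral (max |len-1| = %.3g); use renormalize = TRUE",
                   max(abs(el - 1))))
    return(equilateralize(v))
  }
  knot_polygon(v, validate = FALSE)
}

#' @rdname read_coords
#' @param p a [knot_polygon()].
#' @param format `"xyz"` or `"csv"`.
#' @export
write_coords <- function(p, path, format = c("xyz", "csv")) {
  format <- match.arg(format)
  v <- vertices_of(p)
  txt <- apply(v, 1L, function(r) paste(sprintf("%.17g", r),
                                        collapse = if (format == "csv") "," else " "))
  if (format == "csv") txt <- c("x,y,z", txt)
  writeLines(txt, path)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles every knob of a reproducible run: the root seed (all per-polygon
#' seeds derive from it by counter), dataset sizes, lengths, types,
#' interpolation density, spike-filter thresholds, the ideality cut-off and
#' the ACN direction count.
#'
#' @param seed root seed.
#' @param lengths1,n_per_length dataset-1 protocol.
#' @param types,lengths2,n_per_cell,max_attempts dataset-2 protocol.
#' @param samples_per_edge interpolation density.
#' @param epsilon ideality cut-off.
#' @param acn_dirs Monte-Carlo ACN directions.
#' @param use_spike_filter apply [spike_filter()] before features.
#' @param out_dir output directory for [run_pipeline()].
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       lengths1 = seq(10L, 100L, by = 10L), n_per_length = 200L,
                       types = c("0_1", "3_1", "4_1"),
                       lengths2 = seq(50L, 200L, by = 50L), n_per_cell = 50L,
                       max_attempts = 2000L, samples_per_edge = 10L,
                       epsilon = 0.1, acn_dirs = 100L,
                       use_spike_filter = FALSE, out_dir = "knotph-out") {
  bad <- setdiff(types, c(knot_type_labels(), "unknown"))
  if (length(bad)) stop("invalid type label(s): ", paste(bad, collapse = ", "))
  structure(list(seed = seed, lengths1 = lengths1, n_per_length = n_per_length,
                 types = types, lengths2 = lengths2, n_per_cell = n_per_cell,
                 max_attempts = max_attempts, samples_per_edge = samples_per_edge,
                 epsilon = epsilon, acn_dirs = acn_dirs,
                 use_spike_filter = use_spike_filter, out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON file whose fields override the [run_config()] defaults.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required to read JSON configurations")
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' Multi-polygon coordinate batches
#'
#' CSV with columns `polygon_id,x,y,z`; one block of rows per polygon, in
#' vertex order.
#'
#' @param polygons named list of [knot_polygon()] objects.
#' @param path CSV path.
#' @return `read_coords_batch`: a named list of [knot_polygon()] objects.
#' @export
write_coords_batch <- function(polygons, path) {
  rows <- lapply(names(polygons), function(id) {
    v <- vertices_of(polygons[[id]])
    data.frame(polygon_id = id, x = sprintf("%.17g", v[, 1L]),
               y = sprintf("%.17g", v[, 2L]), z = sprintf("%.17g", v[, 3L]))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_coords_batch
#' @export
read_coords_batch <- function(path) {
  df <- utils::read.csv(path, colClasses = c(polygon_id = "character"))
  ids <- unique(df$polygon_id)
  out <- lapply(ids, function(id) {
    knot_polygon(as.matrix(df[df$polygon_id == id, c("x", "y", "z")]))
  })
  names(out) <- ids
  out
}

#' Run the full analysis pipeline
#'
#' Generates both datasets under the configuration, writes the feature
#' tables, barcode-free correlation tables and averaged summaries as CSV
#' under `config$out_dir`, and returns the datasets invisibly.  The whole
#' run is a pure function of the configuration.
#'
#' @param config a [run_config()].
#' @param which `"both"`, `"dataset1"` or `"dataset2"`.
#' @return invisibly, a list with the generated datasets and tables.
#' @export
run_pipeline <- function(config = run_config(), which = "both") {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  if (which %in% c("both", "dataset1")) {
    ds1 <- build_dataset1(config$lengths1, config$n_per_length, config$seed,
                          s = config$samples_per_edge, epsilon = config$epsilon,
                          acn_dirs = config$acn_dirs,
                          use_spike_filter = config$use_spike_filter)
    write.csv(ds1$features, file.path(config$out_dir, "dataset1_features.csv"),
              row.names = FALSE)
    for (yv in c("V_hull", "V_sphere", "Rg", "acn")) {
      ct <- correlations_by_length(ds1, "I", yv)
      write.csv(ct, file.path(config$out_dir,
                              sprintf("dataset1_cor_I_%s.csv", yv)),
                row.names = FALSE)
    }
    out$dataset1 <- ds1
  }
  if (which %in% c("both", "dataset2")) {
    ds2 <- build_dataset2(config$types, config$lengths2, config$n_per_cell,
                          config$seed, max_attempts = config$max_attempts,
                          s = config$samples_per_edge, epsilon = config$epsilon,
                          acn_dirs = config$acn_dirs,
                          use_spike_filter = config$use_spike_filter)
    if (!is.null(ds2$features)) {
      write.csv(ds2$features, file.path(config$out_dir, "dataset2_features.csv"),
                row.names = FALSE)
      write.csv(average_summaries(ds2),
                file.path(config$out_dir, "dataset2_averages.csv"),
                row.names = FALSE)
    }
    inc <- attr(ds2, "incomplete")
    if (!is.null(inc))
      write.csv(inc, file.path(config$out_dir, "dataset2_incomplete.csv"),
                row.names = FALSE)
    out$dataset2 <- ds2
  }
  invisible(out)
}

#' Barcode table helpers
#'
#' `barcode_to_df` flattens barcodes into the interchange format with
#' columns `polygon_id`, `dim`, `birth`, `death` (dimension always 1);
#' `write_barcodes` writes the CSV.
#'
#' @param barcodes named list of `rips_barcode` objects.
#' @return a data frame.
#' @export
barcode_to_df <- function(barcodes) {
  rows <- lapply(names(barcodes), function(id) {
    m <- as.matrix(barcodes[[id]])
    if (nrow(m) == 0L) return(NULL)
    data.frame(polygon_id = id, dim = 1L, birth = m[, 1L], death = m[, 2L])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname barcode_to_df
#' @param path output CSV path.
#' @export
write_barcodes <- function(barcodes, path) {
  write.csv(barcode_to_df(barcodes), path, row.names = FALSE)
  invisible(path)
}

#' Convert between diameter and radius filtration scales
#'
#' All filtration values in this package are pairwise distances (the
#' "diameter" scale used by Rips engines).  The neighbourhood-radius scale
#' of the thickened-curve picture is half of it.
#'
#' @param t numeric filtration values.
#' @return the converted values.
#' @export
diameter_to_radius <- function(t) t / 2

#' @rdname diameter_to_radius
#' @export
radius_to_diameter <- function(t) 2 * t
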
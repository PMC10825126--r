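# Spatial detection-frequency surfaces by inverse distance weighting.

#' Per-site detection frequency
#'
#' The proportion of survey replicates in which the species was detected at
#' each site: `y_total[i] / n[i]`. This is the point value interpolated into
#' the detection-probability map.
#'
#' @param history a [build_detection_history()] result.
#' @param covariates data.frame with `site_id`, `x`, `y` supplying the
#'   planar site coordinates (m).
#' @return data.frame with columns `site_id, x, y, value`.
#' @export
site_detection_frequency <- function(history, covariates) {
  stopifnot(inherits(history, "detection_history"))
  idx <- match(history$sites, covariates$site_id)
  if (anyNA(idx))
    stop("coordinates missing for site(s): ",
         paste(history$sites[is.na(idx)], collapse = ", "))
  if (any(history$n < 1)) stop("sites with no surveyed occasions")
  data.frame(site_id = history$sites,
             x = covariates$x[idx],
             y = covariates$y[idx],
             value = history$y_total / history$n,
             stringsAsFactors = FALSE)
}

#' Define a raster grid
#'
#' @param origin `c(x, y)` of the lower-left corner of the lower-left cell.
#' @param cell_size cell edge length (m), > 0.
#' @param n_rows,n_cols grid dimensions.
#' @param nodata marker for empty cells (default -9999).
#' @return object of class `raster_grid` (values unset until interpolated).
#' @export
raster_grid <- function(origin, cell_size, n_rows, n_cols, nodata = -9999) {
  stopifnot_scalar_number(cell_size, "cell_size", positive = TRUE)
  structure(list(origin = as.numeric(origin), cell_size = cell_size,
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 values = NULL, nodata = nodata),
            class = "raster_grid")
}

#' Grid spec covering a set of points
#'
#' Convenience constructor: a grid of roughly `n_cells` columns spanning the
#' points' bounding box with a half-cell margin.
#'
#' @param points data.frame with `x`, `y`.
#' @param cell_size cell edge length; if `NULL`, chosen so the longer side
#'   has `n_cells` cells.
#' @param n_cells cells along the longer axis when `cell_size` is `NULL`.
#' @return a [raster_grid()].
#' @export
grid_over_points <- function(points, cell_size = NULL, n_cells = 100) {
  rx <- range(points$x); ry <- range(points$y)
  if (is.null(cell_size))
    cell_size <- max(diff(rx), diff(ry), 1e-9) / n_cells
  raster_grid(origin = c(rx[1] - cell_size / 2, ry[1] - cell_size / 2),
              cell_size = cell_size,
              n_rows = max(1L, ceiling((diff(ry) + cell_size) / cell_size)),
              n_cols = max(1L, ceiling((diff(rx) + cell_size) / cell_size)))
}

#' Inverse-distance-weighted interpolation
#'
#' Fills a raster grid from scattered point values with IDW: each cell
#' centre takes the weighted mean `sum(w_k v_k) / sum(w_k)` with
#' `w_k = d_k^(-power)` over all points (or the `max_points` nearest when
#' set). A cell closer than `eps` to a data point takes that point's value
#' exactly, so the surface honours the data; every interpolated value lies
#' within the range of the input values.
#'
#' @param points data.frame with `x`, `y`, `value` (duplicate coordinates
#'   with conflicting values are an error).
#' @param grid a [raster_grid()] (e.g. from [grid_over_points()]).
#' @param power distance-decay exponent (default 2, the common tool default).
#' @param max_points optionally, use only this many nearest points per cell.
#' @param eps distance below which a cell is considered coincident with a
#'   point (default 1e-9).
#' @return the grid with `values` set: an `n_rows x n_cols` matrix, row 1 =
#'   southernmost row.
#' @export
idw_interpolate <- function(points, grid, power = 2, max_points = NULL,
                            eps = 1e-9) {
  stopifnot(inherits(grid, "raster_grid"))
  if (nrow(points) < 1) stop("no points to interpolate")
  if (any(!is.finite(points$x)) || any(!is.finite(points$y)))
    stop("non-finite coordinates")
  key <- paste(points$x, points$y)
  if (anyDuplicated(key)) {
    agg <- tapply(points$value, key, function(v) diff(range(v)))
    if (any(agg > 0))
      stop("duplicate coordinates with conflicting values")
    keep <- !duplicated(key)
    points <- points[keep, , drop = FALSE]
  }
  cx <- grid$origin[1] + (seq_len(grid$n_cols) - 0.5) * grid$cell_size
  cy <- grid$origin[2] + (seq_len(grid$n_rows) - 0.5) * grid$cell_size
  cells <- cbind(x = rep(cx, times = grid$n_rows),
                 y = rep(cy, each = grid$n_cols))
  d2 <- outer(cells[, 1], points$x, "-")^2 +
    outer(cells[, 2], points$y, "-")^2
  d <- sqrt(d2)
  vals <- numeric(nrow(cells))
  hit <- d < eps
  exact <- rowSums(hit) > 0
  if (any(exact))
    vals[exact] <- points$value[apply(d[exact, , drop = FALSE], 1,
                                      which.min)]
  rest <- which(!exact)
  if (length(rest)) {
    w <- d[rest, , drop = FALSE]^(-power)
    if (!is.null(max_points) && max_points < nrow(points)) {
      for (i in seq_len(nrow(w))) {
        drop_idx <- order(w[i, ], decreasing = TRUE)[-seq_len(max_points)]
        w[i, drop_idx] <- 0
      }
    }
    vals[rest] <- drop(w %*% points$value) / rowSums(w)
  }
  grid$values <- matrix(vals, nrow = grid$n_rows, ncol = grid$n_cols,
                        byrow = TRUE)
  grid
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("raster_grid: %d x %d cells of %g, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin[1], x$origin[2]))
  if (!is.null(x$values))
    cat(sprintf("  values in [%.4f, %.4f]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text `.asc` format readable by standard GIS tools: a six-line
#' header (`ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value`)
#' followed by rows of cell values from the northern edge down.
#'
#' @param grid an interpolated [raster_grid()].
#' @param path output file path.
#' @param digits significant digits written (default 6).
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(grid, path, digits = 6) {
  stopifnot(inherits(grid, "raster_grid"), !is.null(grid$values))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", grid$n_cols),
               sprintf("nrows %d", grid$n_rows),
               sprintf("xllcorner %.10g", grid$origin[1]),
               sprintf("yllcorner %.10g", grid$origin[2]),
               sprintf("cellsize %.10g", grid$cell_size),
               sprintf("NODATA_value %g", grid$nodata)), con)
  for (r in rev(seq_len(grid$n_rows)))
    writeLines(paste(signif(grid$values[r, ], digits), collapse = " "), con)
  invisible(path)
}

#' Long-format dump of a raster
#'
#' @param grid an interpolated [raster_grid()].
#' @return data.frame with cell-centre `x, y, value`.
#' @export
raster_to_df <- function(grid) {
  stopifnot(inherits(grid, "raster_grid"), !is.null(grid$values))
  cx <- grid$origin[1] + (seq_len(grid$n_cols) - 0.5) * grid$cell_size
  cy <- grid$origin[2] + (seq_len(grid$n_rows) - 0.5) * grid$cell_size
  data.frame(x = rep(cx, times = grid$n_rows),
             y = rep(cy, each = grid$n_cols),
             value = as.vector(t(grid$values)))
}
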
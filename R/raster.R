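#' Construct a raster grid
#'
#' A north-up raster with square cells, anchored at its top-left corner: row 1
#' of `values` is the northmost row, column 1 the westmost column. This is the
#' shape of surface a collaborator returns from a hotspot analysis (kernel
#' density, interpolation) of masked points.
#'
#' @param values numeric matrix of cell values; `NA` marks nodata.
#' @param top_left numeric `c(x, y)` of the grid's upper-left corner, metres.
#' @param cell_size square cell edge, metres; `> 0`.
#' @param crs optional CRS string.
#' @param nodata sentinel used when writing to disk (default -9999).
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, top_left, cell_size, crs = NA_character_,
                        nodata = -9999) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(top_left) || length(top_left) != 2 || any(!is.finite(top_left)))
    stop("top_left must be a finite numeric (x, y) pair")
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    stop("cell_size must be a single positive number")
  structure(list(values = unname(values),
                 top_left = c(x = top_left[[1]], y = top_left[[2]]),
                 cell_size = as.numeric(cell_size),
                 crs = crs, nodata = nodata),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("<raster_grid> %d rows x %d cols, cell %g m, top-left (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              x$top_left[["x"]], x$top_left[["y"]]))
  invisible(x)
}

#' Extent of a raster grid
#' @param grid a [raster_grid()].
#' @return an [extent()] covering the full grid.
#' @export
raster_extent <- function(grid) {
  extent(grid$top_left[["x"]],
         grid$top_left[["y"]] - nrow(grid$values) * grid$cell_size,
         grid$top_left[["x"]] + ncol(grid$values) * grid$cell_size,
         grid$top_left[["y"]])
}

#' Cell-center coordinates of a raster grid
#' @param grid a [raster_grid()].
#' @return a data frame of `row`, `col`, `x`, `y` (one row per cell).
#' @export
raster_cell_centers <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  rows <- rep(seq_len(nr), times = nc)
  cols <- rep(seq_len(nc), each = nr)
  data.frame(row = rows, col = cols,
             x = grid$top_left[["x"]] + (cols - 0.5) * grid$cell_size,
             y = grid$top_left[["y"]] - (rows - 0.5) * grid$cell_size)
}

#' Rotate a raster value matrix by a quarter turn
#'
#' An exact array rotation — values are permuted, never resampled or changed —
#' matching the anticlockwise geometric re-rotation applied to coordinates
#' when unmasking. Angles of 90 and 270 swap the row and column counts.
#'
#' @param values numeric matrix.
#' @param theta_deg 90, 180 or 270 (anticlockwise).
#' @return the rotated matrix.
#' @examples
#' rotate_raster_values(rbind(c(1, 2), c(3, 4)), 180)  # rbind(c(4,3), c(2,1))
#' @export
rotate_raster_values <- function(values, theta_deg) {
  theta_deg <- check_quarter_angle(theta_deg, allow_zero = TRUE)
  m <- as.matrix(values)
  rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]  # one anticlockwise turn
  for (i in seq_len(theta_deg / 90)) m <- rot90(m)
  m
}

#' Unadjusted top-left corner of a re-transformed raster
#'
#' First step of raster re-transformation: the masked raster's corner
#' coordinates are re-rotated anticlockwise by the stored angle about the
#' origin, and the top-left corner (min x, max y) of the rotated footprint is
#' re-translated by the stored offset. For a 180-degree mask this is exactly
#' the masked raster's bottom-right corner rotated anticlockwise; taking the
#' rotated footprint's bounding box generalizes the same construction to 90
#' and 270 degrees.
#'
#' @param masked_raster a [raster_grid()] computed in the masked geography.
#' @param record the [mask_key_record()] of the masking.
#' @return numeric `c(x, y)`: the unadjusted top-left in original geography.
#' @export
unadjusted_topleft <- function(masked_raster, record) {
  e <- raster_extent(masked_raster)
  corners <- rbind(c(e$xmin, e$ymin), c(e$xmin, e$ymax),
                   c(e$xmax, e$ymin), c(e$xmax, e$ymax))
  rot <- rotate_about_origin(corners, record$theta_deg, "anticlockwise")
  iv <- record$intervals
  tx <- record$r * (iv$x2 - iv$x1) + iv$x1
  ty <- record$r * (iv$y2 - iv$y1) + iv$y1
  c(x = min(rot[, "x"]) - tx, y = max(rot[, "y"]) - ty)
}

#' Extent adjustment between masked points and the collaborator's raster
#'
#' The collaborator's raster generally does not coincide with the masked
#' points' bounding rectangle (tools pad or snap their analysis extent). The
#' adjustment compares the two extents side by side in the masked geography —
#' left, right, top, bottom differences — and sums opposite sides:
#' `x_adj = (points_left - raster_left) + (points_right - raster_right)` and
#' likewise for y with top and bottom. Symmetric padding cancels to zero.
#'
#' @param points_extent the masked points' [extent()] (as stored in the key
#'   record).
#' @param raster_extent_ the [extent()] of the raster computed from them.
#' @return numeric `c(x_adj, y_adj)`, metres.
#' @export
extent_adjustment <- function(points_extent, raster_extent_) {
  p <- as_extent(points_extent); g <- as_extent(raster_extent_)
  x_ldiff <- p$xmin - g$xmin
  x_rdiff <- p$xmax - g$xmax
  y_tdiff <- p$ymax - g$ymax
  y_bdiff <- p$ymin - g$ymin
  c(x_adj = x_ldiff + x_rdiff, y_adj = y_tdiff + y_bdiff)
}

#' Re-transform a masked raster to the original geography
#'
#' Maps a surface computed by a collaborator on masked points back onto the
#' original geography: the value matrix is rotated anticlockwise by the stored
#' angle (an exact permutation), the unadjusted top-left corner is obtained by
#' rotating and re-translating the raster's corner coordinates, and finally
#' the extent adjustment between the stored masked-point extent and the
#' raster's own extent repositions the corner:
#' `X_left = X'''_left - x_adj`, and `Y_top = Y'''_top + y_adj` when
#' `y_adj < 0`, else `Y'''_top - y_adj`. Note the y rule subtracts the
#' magnitude of the adjustment in both sign cases while x subtracts the signed
#' value; both reduce to the unadjusted corner when the raster is snapped to
#' the masked-point extent. Cell size and values are untouched; the CRS of the
#' original data is restored.
#'
#' @param masked_raster a [raster_grid()] computed in the masked geography
#'   (north-up, square cells).
#' @param key the key the underlying points were masked under.
#' @param store the [key_store()].
#' @return the re-transformed [raster_grid()].
#' @export
retransform_raster <- function(masked_raster, key, store) {
  if (!inherits(masked_raster, "raster_grid"))
    stop("masked_raster must be a raster_grid")
  record <- load_record(store, key)
  tl <- unadjusted_topleft(masked_raster, record)
  adj <- extent_adjustment(record$masked_extent, raster_extent(masked_raster))
  x_left <- tl[["x"]] - adj[["x_adj"]]
  y_top <- if (adj[["y_adj"]] < 0) tl[["y"]] + adj[["y_adj"]]
           else tl[["y"]] - adj[["y_adj"]]
  raster_grid(rotate_raster_values(masked_raster$values, record$theta_deg),
              top_left = c(x_left, y_top),
              cell_size = masked_raster$cell_size,
              crs = record$crs, nodata = masked_raster$nodata)
}
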
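# Shared grid construction: a north-up square-cell grid anchored at the
# top-left of `ext`, with enough whole cells to cover it. A tiny tolerance
# makes widths that are integer multiples of cell_size (the snapped
# verification case) yield exactly that many cells despite rounding.
grid_dims <- function(ext, cell_size) {
  nc <- max(1L, as.integer(ceiling(extent_width(ext) / cell_size - 1e-9)))
  nr <- max(1L, as.integer(ceiling(extent_height(ext) / cell_size - 1e-9)))
  list(n_rows = nr, n_cols = nc, top_left = c(ext$xmin, ext$ymax))
}

grid_centers <- function(dims, cell_size) {
  cx <- dims$top_left[[1]] + (seq_len(dims$n_cols) - 0.5) * cell_size
  cy <- dims$top_left[[2]] - (seq_len(dims$n_rows) - 0.5) * cell_size
  list(cx = cx, cy = cy)
}

#' Kernel density estimate surface
#'
#' A hotspot intensity surface from a point pattern, using the quartic
#' (biweight) kernel: the value at a cell center `c` is
#' `sum_i (3 / (pi h^2)) (1 - (d_i / h)^2)^2` over points within bandwidth
#' `h` of `c`, in units of points per square metre. Each point contributes
#' unit mass, so summing cell values times cell area approximates the point
#' count when the bandwidth is well resolved by the grid and points sit away
#' from the surface edge.
#'
#' @param points a [point_set()].
#' @param bandwidth kernel radius `h`, metres; `> 0`.
#' @param cell_size output cell edge, metres; `> 0`.
#' @param extent_ optional [extent()] for the surface; default is the points'
#'   bounding rectangle padded outward by one bandwidth.
#' @return a [raster_grid()] of densities.
#' @export
kde_surface <- function(points, bandwidth, cell_size, extent_ = NULL) {
  if (!is.numeric(bandwidth) || bandwidth <= 0) stop("bandwidth must be positive")
  if (!is.numeric(cell_size) || cell_size <= 0) stop("cell_size must be positive")
  if (!nrow(points)) stop("cannot build a surface from an empty point set")
  if (is.null(extent_)) {
    e <- point_extent(points)
    extent_ <- extent(e$xmin - bandwidth, e$ymin - bandwidth,
                      e$xmax + bandwidth, e$ymax + bandwidth)
  }
  dims <- grid_dims(as_extent(extent_), cell_size)
  ctr <- grid_centers(dims, cell_size)
  vals <- matrix(0, dims$n_rows, dims$n_cols)
  scale <- 3 / (pi * bandwidth^2)
  for (i in seq_len(nrow(points))) {
    u2 <- (outer(ctr$cy, points$x[i] - ctr$cx, function(y, dx) dx^2 + (points$y[i] - y)^2)) / bandwidth^2
    inside <- u2 < 1
    if (any(inside)) vals[inside] <- vals[inside] + scale * (1 - u2[inside])^2
  }
  raster_grid(vals, top_left = dims$top_left, cell_size = cell_size,
              crs = point_crs(points))
}

#' Inverse distance weighted interpolation surface
#'
#' Shepard interpolation of a numeric point attribute onto a grid: the value
#' at a cell center is the weighted mean of all point values with weights
#' `d^-power`; a cell center coinciding with a data point takes that point's
#' value exactly. Interpolated values always lie within the range of the data
#' values.
#'
#' @param points a [point_set()].
#' @param value_field name of the numeric attribute column to interpolate.
#' @param power distance-decay exponent; `> 0`, default 2.
#' @param cell_size output cell edge, metres.
#' @param extent_ optional [extent()]; default is the points' bounding
#'   rectangle.
#' @return a [raster_grid()] of interpolated values.
#' @export
idw_surface <- function(points, value_field, power = 2, cell_size,
                        extent_ = NULL) {
  if (!is.numeric(power) || power <= 0) stop("power must be positive")
  if (!is.numeric(cell_size) || cell_size <= 0) stop("cell_size must be positive")
  if (!value_field %in% names(points))
    stop("no attribute column named ", sQuote(value_field))
  v <- points[[value_field]]
  if (!is.numeric(v) || anyNA(v))
    stop("attribute ", sQuote(value_field), " must be numeric with no missing values")
  if (is.null(extent_)) extent_ <- point_extent(points)
  dims <- grid_dims(as_extent(extent_), cell_size)
  ctr <- grid_centers(dims, cell_size)
  vals <- matrix(NA_real_, dims$n_rows, dims$n_cols)
  for (col in seq_len(dims$n_cols)) {
    d2 <- outer(ctr$cy, points$y, function(cy, py) (cy - py)^2) +
      matrix((ctr$cx[col] - points$x)^2, dims$n_rows, nrow(points), byrow = TRUE)
    hit <- d2 == 0
    w <- d2^(-power / 2)
    num <- w %*% v
    den <- rowSums(w)
    cell <- num / den
    exact_rows <- which(rowSums(hit) > 0)
    for (rr in exact_rows) cell[rr] <- mean(v[hit[rr, ]])
    vals[, col] <- cell
  }
  raster_grid(vals, top_left = dims$top_left, cell_size = cell_size,
              crs = point_crs(points))
}
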
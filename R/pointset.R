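#' Construct a point set
#'
#' A `point_set` is the package's container for planar point data: an ordered
#' data frame with an `id` column (unique tokens), numeric `x` and `y`
#' coordinates in metres, and any number of additional attribute columns that
#' are carried through masking untouched. The coordinate reference system is an
#' opaque string held in the `"crs"` attribute; masking requires a projected
#' (planar, metric) CRS and rejects geographic longitude/latitude data.
#'
#' @param x,y numeric vectors of planar coordinates in metres.
#' @param id unique identifiers, one per point; defaults to `"p1"`, `"p2"`, ...
#' @param attrs optional data frame (or list) of attribute columns, recycled
#'   rules as in [data.frame()].
#' @param crs coordinate-reference identifier (free-form string, e.g. a WKT
#'   definition or `"EPSG:32615"`). `NA` means unknown.
#' @return an object of class `point_set` (a data frame).
#' @examples
#' ps <- point_set(x = c(0, 10), y = c(0, 5), crs = local_metric_crs())
#' n_points(ps)
#' @export
point_set <- function(x, y, id = NULL, attrs = NULL, crs = NA_character_) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (is.null(id)) id <- paste0("p", seq_along(x), recycle0 = TRUE)
  id <- as.character(id)
  if (length(id) != length(x)) stop("id must match the number of points")
  if (anyDuplicated(id)) stop("point ids must be unique")
  if (length(x) && any(!is.finite(x) | !is.finite(y)))
    stop("coordinates must be finite")
  df <- data.frame(id = id, x = x, y = y, stringsAsFactors = FALSE)
  if (!is.null(attrs)) {
    attrs <- as.data.frame(attrs, stringsAsFactors = FALSE)
    if (nrow(attrs) && nrow(attrs) != nrow(df))
      stop("attrs must have one row per point")
    bad <- intersect(names(attrs), names(df))
    if (length(bad)) stop("attribute names clash with reserved columns: ",
                          paste(bad, collapse = ", "))
    df <- cbind(df, attrs)
  }
  structure(df, crs = crs, class = c("point_set", "data.frame"))
}

#' @export
print.point_set <- function(x, n = 6L, ...) {
  cat(sprintf("<point_set> %d points, %d attribute column(s), crs: %s\n",
              nrow(x), ncol(x) - 3L,
              if (is.na(point_crs(x))) "<unknown>" else substr(point_crs(x), 1, 60)))
  print.data.frame(utils::head(x, n), ...)
  if (nrow(x) > n) cat(sprintf("# ... %d more point(s)\n", nrow(x) - n))
  invisible(x)
}

#' Number of points in a point set
#' @param points a [point_set()].
#' @return integer count.
#' @export
n_points <- function(points) nrow(points)

#' Coordinate reference system of a point set
#' @param points a [point_set()].
#' @return the CRS string (possibly `NA`).
#' @export
point_crs <- function(points) {
  crs <- attr(points, "crs", exact = TRUE)
  if (is.null(crs)) NA_character_ else crs
}

#' A minimal projected CRS identifier for synthetic data
#'
#' Synthetic point patterns generated by this package live on an abstract
#' metric plane rather than any real datum; this well-known-text stub marks
#' them as projected (so masking accepts them) and round-trips through `.prj`
#' sidecar files.
#' @return a WKT string.
#' @export
local_metric_crs <- function() {
  'PROJCS["Local metric grid",GEOGCS["Abstract",DATUM["Unknown",SPHEROID["Sphere",6371000,0]],PRIMEM["Greenwich",0],UNIT["degree",0.0174532925199433]],PROJECTION["Transverse_Mercator"],UNIT["metre",1]]'
}

#' Is a CRS geographic (longitude/latitude)?
#'
#' Masking rotates and translates coordinates as planar metric quantities, so
#' geographic coordinates are rejected. Detection is heuristic over the opaque
#' CRS string: well-known text whose outermost object is `GEOGCS`/`GEOGCRS`,
#' proj strings containing `longlat`, and the common geographic EPSG codes
#' 4326/4269 are treated as geographic. An unknown (`NA`) CRS is *not* treated
#' as geographic; callers may warn instead.
#' @param crs a CRS string or `NA`.
#' @return `TRUE`/`FALSE`.
#' @export
is_geographic_crs <- function(crs) {
  if (is.null(crs) || length(crs) == 0 || is.na(crs)) return(FALSE)
  crs <- trimws(crs)
  grepl("^GEOGCR?S", crs) ||
    grepl("longlat", crs, fixed = TRUE) ||
    grepl("EPSG: ?(4326|4269)$", crs) ||
    crs %in% c("4326", "4269")
}

stop_if_geographic <- function(points, what = "this operation") {
  if (is_geographic_crs(point_crs(points)))
    stop(sprintf(
      "%s requires a projected (planar, metric) CRS; got geographic coordinates (%s). Reproject first.",
      what, point_crs(points)))
  invisible(points)
}

#' Axis-aligned extent (bounding rectangle)
#'
#' @param xmin,ymin,xmax,ymax rectangle bounds in metres.
#' @return an object of class `extent`.
#' @export
extent <- function(xmin, ymin, xmax, ymax) {
  v <- c(xmin = as.numeric(xmin), ymin = as.numeric(ymin),
         xmax = as.numeric(xmax), ymax = as.numeric(ymax))
  if (any(!is.finite(v))) stop("extent bounds must be finite")
  if (v[["xmax"]] < v[["xmin"]] || v[["ymax"]] < v[["ymin"]])
    stop("extent requires xmax >= xmin and ymax >= ymin")
  structure(as.list(v), class = "extent")
}

#' @export
print.extent <- function(x, ...) {
  cat(sprintf("<extent> x: [%g, %g]  y: [%g, %g]\n",
              x$xmin, x$xmax, x$ymin, x$ymax))
  invisible(x)
}

#' Bounding rectangle of a point set
#' @param points a [point_set()] with at least one point.
#' @return an [extent()].
#' @export
point_extent <- function(points) {
  if (!nrow(points)) stop("cannot take the extent of an empty point set")
  extent(min(points$x), min(points$y), max(points$x), max(points$y))
}

extent_width  <- function(e) e$xmax - e$xmin
extent_height <- function(e) e$ymax - e$ymin
extent_area   <- function(e) extent_width(e) * extent_height(e)

as_extent <- function(e) {
  if (inherits(e, "extent")) return(e)
  if (is.numeric(e) && length(e) == 4) return(extent(e[1], e[2], e[3], e[4]))
  if (is.list(e) && all(c("xmin", "ymin", "xmax", "ymax") %in% names(e)))
    return(extent(e$xmin, e$ymin, e$xmax, e$ymax))
  stop("cannot interpret object as an extent")
}

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
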
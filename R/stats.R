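#' Average nearest neighbour (Clark–Evans) analysis
#'
#' Compares the observed mean nearest-neighbour distance of a point pattern
#' with its expectation under complete spatial randomness (CSR) over a study
#' area `A`: `omd = mean_i min_{j != i} d_ij`, `emd = 0.5 / sqrt(n / A)`,
#' ratio `nnr = omd / emd` and standard score
#' `z = (omd - emd) / (0.26136 / sqrt(n^2 / A))`. A ratio below 1 indicates
#' clustering, near 1 randomness, above 1 dispersion. Distances are Euclidean
#' throughout; because the geomask is a rigid motion and a quarter-turn maps
#' the bounding rectangle onto a rectangle of equal area, every field of this
#' result is invariant under masking.
#'
#' @param points a [point_set()] with at least two points.
#' @param area study-area size in square metres. By default the area of the
#'   minimum enclosing axis-aligned rectangle of the points (the common
#'   desktop-GIS convention); `area = "hull"` uses the convex hull instead.
#' @return a list of class `ann_result` with fields `omd`, `emd`, `nnr`, `z`,
#'   `p` (two-sided normal p-value), `area`, `n`.
#' @export
average_nearest_neighbor <- function(points, area = NULL) {
  n <- nrow(points)
  if (n < 2) stop("average nearest neighbour needs at least two points")
  A <- resolve_area(points, area)
  if (A <= 0) stop("study area must be positive (degenerate point extent?)")
  omd <- mean(nearest_neighbor_distances(points$x, points$y))
  emd <- 0.5 / sqrt(n / A)
  se <- 0.26136 / sqrt(n^2 / A)
  z <- (omd - emd) / se
  structure(list(omd = omd, emd = emd, nnr = omd / emd, z = z,
                 p = 2 * stats::pnorm(-abs(z)), area = A, n = n),
            class = "ann_result")
}

#' @export
print.ann_result <- function(x, ...) {
  verdict <- if (x$nnr < 1) "clustered" else if (x$nnr > 1) "dispersed" else "random"
  cat(sprintf(
    "Average nearest neighbour (n = %d, area = %.6g m^2)\n  OMD %.4f m  EMD %.4f m  NNR %.6f (%s)\n  z = %.4f, p = %.2f%s\n",
    x$n, x$area, x$omd, x$emd, x$nnr, verdict, x$z, x$p,
    if (x$p < 1e-15) "  (p < 1e-15)" else ""))
  invisible(x)
}

resolve_area <- function(points, area) {
  if (is.null(area)) return(extent_area(point_extent(points)))
  if (identical(area, "hull")) {
    h <- grDevices::chull(points$x, points$y)
    xx <- points$x[h]; yy <- points$y[h]
    # shoelace formula
    return(abs(sum(xx * c(yy[-1], yy[1]) - c(xx[-1], xx[1]) * yy)) / 2)
  }
  as.numeric(area)
}

# Chunked O(n^2) nearest-neighbour distances; memory stays bounded for large n.
nearest_neighbor_distances <- function(x, y, chunk = 512L) {
  n <- length(x)
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d2 <- outer(x[idx], x, "-")^2 + outer(y[idx], y, "-")^2
    d2[cbind(seq_along(idx), idx)] <- Inf  # exclude self
    out[idx] <- sqrt(apply(d2, 1, min))
  }
  out
}

#' Ripley's K function with L transform
#'
#' Cumulative second-order statistic of a point pattern at a ladder of
#' distance bands: `K(d) = A * #{ordered pairs with d_ij <= d} / (n (n - 1))`,
#' `L(d) = sqrt(K(d) / pi)` and `Diff = L(d) - d`. Positive `Diff` indicates
#' clustering at that scale. Band `b` sits at `b * max_d / n_bands`. No edge
#' correction is applied by default; the reduced-sample ("border") correction
#' is available via `correction`.
#'
#' @param points a [point_set()] with at least two points.
#' @param n_bands number of evenly spaced distance bands (default 10).
#' @param max_d largest band distance, metres; defaults to a quarter of the
#'   shorter side of the points' bounding rectangle.
#' @param area study area, square metres; defaults to the bounding rectangle.
#' @param correction `"none"` (default) or `"border"`.
#' @return a list of class `ripley_result` with a data frame `bands`
#'   (`d`, `k`, `l`, `diff`) plus `n`, `area`, `correction`.
#' @export
ripleys_k <- function(points, n_bands = 10, max_d = NULL, area = NULL,
                      correction = c("none", "border")) {
  correction <- match.arg(correction)
  n <- nrow(points)
  if (n < 2) stop("Ripley's K needs at least two points")
  A <- resolve_area(points, area)
  if (A <= 0) stop("study area must be positive")
  e <- point_extent(points)
  if (is.null(max_d))
    max_d <- min(extent_width(e), extent_height(e)) / 4
  if (max_d <= 0) stop("max_d must be positive")
  d_bands <- seq_len(n_bands) * (max_d / n_bands)

  dmat <- pair_distances(points$x, points$y)
  if (correction == "none") {
    k <- vapply(d_bands, function(d) {
      A * sum(dmat <= d) / (n * (n - 1))
    }, numeric(1))
  } else {
    # reduced-sample estimator: only points further than d from the window
    # boundary contribute as reference points
    border <- pmin(points$x - e$xmin, e$xmax - points$x,
                   points$y - e$ymin, e$ymax - points$y)
    k <- vapply(d_bands, function(d) {
      keep <- border > d
      if (!any(keep)) return(NA_real_)
      A * sum(dmat[keep, , drop = FALSE] <= d) / (sum(keep) * (n - 1))
    }, numeric(1))
  }
  l <- sqrt(k / pi)
  structure(list(bands = data.frame(d = d_bands, k = k, l = l, diff = l - d_bands),
                 n = n, area = A, correction = correction),
            class = "ripley_result")
}

#' @export
print.ripley_result <- function(x, ...) {
  cat(sprintf("Ripley's K (n = %d, area = %.6g m^2, correction = %s)\n",
              x$n, x$area, x$correction))
  print(format(x$bands, digits = 6), row.names = FALSE)
  invisible(x)
}

# full n x n distance matrix with Inf diagonal; chunking unnecessary here
# because K is only run at verification sizes (thousands of points)
pair_distances <- function(x, y) {
  d <- sqrt(outer(x, x, "-")^2 + outer(y, y, "-")^2)
  diag(d) <- Inf
  d
}

#' Point-by-point distance report
#'
#' Matches two point sets by id and reports the Euclidean distance between
#' each pair — the paper-and-pencil check that a mask/unmask round trip
#' returned every point to its origin.
#'
#' @param a,b [point_set()]s over the same ids.
#' @return a list with `distances` (data frame `id`, `distance`) and `max`.
#' @export
point_distance_report <- function(a, b) {
  if (!setequal(a$id, b$id) || nrow(a) != nrow(b))
    stop("point sets must carry the same ids")
  m <- b[match(a$id, b$id), ]
  d <- sqrt((m$x - a$x)^2 + (m$y - a$y)^2)
  list(distances = data.frame(id = a$id, distance = d, stringsAsFactors = FALSE),
       max = max(d))
}
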
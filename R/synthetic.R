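#' Parameters for a Thomas cluster process
#'
#' The synthetic stand-in for clustered epidemic point data (e.g. mortality
#' locations in an urban outbreak): parent locations form a homogeneous
#' Poisson process over a rectangular window, and each parent spawns a
#' Poisson-distributed brood of offspring scattered around it with an
#' isotropic Gaussian displacement. The defaults emulate a ~5 x 5 km urban
#' extent with a few tens of cluster centres and tight (150 m) case clusters.
#'
#' @param window an [extent()]; default a 5000 x 5000 m window at the origin.
#' @param parent_intensity expected parents per square metre (default 8e-7,
#'   i.e. 20 parents in the default window).
#' @param offspring_mean expected offspring per parent (default 30).
#' @param offspring_sd Gaussian scatter of offspring around their parent,
#'   metres (default 150).
#' @param seed integer seed for reproducibility.
#' @return a list of class `cluster_params`.
#' @export
cluster_params <- function(window = extent(0, 0, 5000, 5000),
                           parent_intensity = 8e-7,
                           offspring_mean = 30,
                           offspring_sd = 150,
                           seed = 1L) {
  window <- as_extent(window)
  if (extent_area(window) <= 0) stop("window must be non-degenerate")
  stopifnot(parent_intensity > 0, offspring_mean > 0, offspring_sd > 0)
  structure(list(window = window, parent_intensity = parent_intensity,
                 offspring_mean = offspring_mean, offspring_sd = offspring_sd,
                 seed = as.integer(seed)),
            class = "cluster_params")
}

#' Generate a clustered (Thomas process) point pattern
#'
#' Parents are Poisson in number and uniform over the window; each spawns a
#' Poisson number of offspring displaced by independent Gaussian offsets, and
#' offspring falling outside the window are discarded. Only the offspring are
#' returned. The realization is deterministic given the seed; an empty
#' realization is retried with derived seeds up to 10 times before erroring.
#'
#' @param params a [cluster_params()].
#' @return a [point_set()] with sequential ids and [local_metric_crs()].
#' @export
generate_thomas_cluster <- function(params) {
  if (!inherits(params, "cluster_params")) stop("params must be cluster_params")
  w <- params$window
  for (attempt in 0:9) {
    pts <- with_seed(params$seed + attempt * 1000003L, {
      n_parents <- stats::rpois(1, params$parent_intensity * extent_area(w))
      if (n_parents == 0) NULL else {
        px <- stats::runif(n_parents, w$xmin, w$xmax)
        py <- stats::runif(n_parents, w$ymin, w$ymax)
        brood <- stats::rpois(n_parents, params$offspring_mean)
        if (sum(brood) == 0) NULL else {
          ox <- rep(px, brood) + stats::rnorm(sum(brood), 0, params$offspring_sd)
          oy <- rep(py, brood) + stats::rnorm(sum(brood), 0, params$offspring_sd)
          keep <- ox >= w$xmin & ox <= w$xmax & oy >= w$ymin & oy <= w$ymax
          if (!any(keep)) NULL else cbind(ox[keep], oy[keep])
        }
      }
    })
    if (!is.null(pts))
      return(point_set(x = pts[, 1], y = pts[, 2], crs = local_metric_crs()))
  }
  stop("Thomas process produced an empty pattern after 10 seed attempts; ",
       "increase parent_intensity or offspring_mean")
}

#' Generate complete spatial randomness (CSR)
#'
#' `n` points placed independently and uniformly in the window — the null
#' model against which clustering statistics are judged.
#'
#' @param window an [extent()].
#' @param n number of points, `>= 1`.
#' @param seed integer seed.
#' @return a [point_set()].
#' @export
generate_csr <- function(window, n, seed = 1L) {
  window <- as_extent(window)
  if (n < 1) stop("n must be at least 1")
  with_seed(seed, {
    point_set(x = stats::runif(n, window$xmin, window$xmax),
              y = stats::runif(n, window$ymin, window$ymax),
              crs = local_metric_crs())
  })
}

#' Attach a synthetic numeric attribute to a point set
#'
#' Evaluates a smooth surface at each point and adds Gaussian noise —
#' synthetic "measurements" for interpolation experiments.
#'
#' @param points a [point_set()].
#' @param field name of the new attribute column; must not already exist.
#' @param surface a function of `(x, y)` returning the noiseless value.
#' @param noise_sd standard deviation of additive Gaussian noise (0 for none).
#' @param seed integer seed.
#' @return the point set with the new column.
#' @export
attach_values <- function(points, field, surface, noise_sd = 0, seed = 1L) {
  if (field %in% names(points))
    stop("attribute ", sQuote(field), " already present")
  if (!is.function(surface)) stop("surface must be a function(x, y)")
  vals <- surface(points$x, points$y)
  vals <- rep_len(as.numeric(vals), nrow(points))
  if (noise_sd > 0)
    vals <- vals + with_seed(seed, stats::rnorm(nrow(points), 0, noise_sd))
  points[[field]] <- vals
  points
}
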
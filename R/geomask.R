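#' Translation offset intervals
#'
#' The geomask translates every point by the same random offset drawn from
#' user-supplied intervals: `x + r*(x2 - x1) + x1` along the easting and
#' `y + r*(y2 - y1) + y1` along the northing, with a single random number
#' `r` in `[0, 1)` shared by both axes. With non-negative `x1`, `y1` the
#' translation alone therefore displaces every point by at least
#' `sqrt(x1^2 + y1^2)` metres — the donut-style minimum-displacement
#' guarantee of the method.
#'
#' @param x1,x2 lower/upper translation bound along x, metres; `x2 >= x1`.
#' @param y1,y2 lower/upper translation bound along y, metres; `y2 >= y1`.
#' @return an object of class `offset_intervals`.
#' @examples
#' offset_intervals(1000, 2000, 3000, 5000)
#' @export
offset_intervals <- function(x1, x2, y1, y2) {
  v <- vapply(list(x1, x2, y1, y2), as.numeric, numeric(1))
  if (any(!is.finite(v))) stop("offset intervals must be finite")
  if (v[2] < v[1]) stop("offset intervals require x2 >= x1")
  if (v[4] < v[3]) stop("offset intervals require y2 >= y1")
  if (v[1] == v[2] && v[3] == v[4])
    warning("degenerate offset intervals (x1 == x2 and y1 == y2): ",
            "the translation is a fixed, guessable offset, which weakens privacy")
  structure(list(x1 = v[1], x2 = v[2], y1 = v[3], y2 = v[4]),
            class = "offset_intervals")
}

#' @export
print.offset_intervals <- function(x, ...) {
  cat(sprintf("<offset_intervals> x: {%g, %g}  y: {%g, %g}\n",
              x$x1, x$x2, x$y1, x$y2))
  invisible(x)
}

# exact integer cosine/sine for quarter-turn angles
quarter_cos <- c(`0` = 1, `90` = 0, `180` = -1, `270` = 0)
quarter_sin <- c(`0` = 0, `90` = 1, `180` = 0, `270` = -1)

#' Rotate coordinates about the origin by a quarter-turn angle
#'
#' Rotation is restricted to multiples of 90 degrees so that the rotation
#' matrix entries are exactly -1, 0 or 1: the transform is then exactly
#' invertible in floating point, and rotating a north-up raster never requires
#' resampling.
#'
#' @param coords a two-column matrix (or data frame) of x, y coordinates.
#' @param theta_deg rotation angle in degrees; one of 0, 90, 180, 270.
#' @param direction `"clockwise"` or `"anticlockwise"`.
#' @return a two-column numeric matrix of rotated coordinates.
#' @examples
#' rotate_about_origin(cbind(1, 0), 90, "anticlockwise")  # (0, 1)
#' @export
rotate_about_origin <- function(coords, theta_deg,
                                direction = c("clockwise", "anticlockwise")) {
  direction <- match.arg(direction)
  theta_deg <- check_quarter_angle(theta_deg, allow_zero = TRUE)
  m <- as.matrix(coords)
  if (ncol(m) != 2) stop("coords must have two columns (x, y)")
  storage.mode(m) <- "double"
  co <- quarter_cos[[as.character(theta_deg)]]
  si <- quarter_sin[[as.character(theta_deg)]]
  if (direction == "clockwise") si <- -si
  # anticlockwise: x' = x cos - y sin ; y' = x sin + y cos
  out <- cbind(m[, 1] * co - m[, 2] * si,
               m[, 1] * si + m[, 2] * co)
  dimnames(out) <- list(NULL, c("x", "y"))
  out
}

check_quarter_angle <- function(theta_deg, allow_zero = FALSE) {
  ok <- c(if (allow_zero) 0, 90, 180, 270)
  if (length(theta_deg) != 1 || !is.finite(theta_deg) || !(theta_deg %in% ok))
    stop("rotation angle must be one of {", paste(ok, collapse = ", "),
         "} degrees, got: ", paste(theta_deg, collapse = ", "))
  as.integer(theta_deg)
}

#' Mask (obfuscate) a point set
#'
#' Applies the keyed affine geomask: every point is first translated by the
#' same random offset `(r*(x2 - x1) + x1, r*(y2 - y1) + y1)` — one random
#' number `r` drawn per dataset — and then rotated clockwise about the
#' coordinate origin by an angle drawn uniformly from 90, 180 or 270 degrees.
#' The secret needed to undo the mask (`r`, the angle, the intervals and the
#' masked points' extent) is persisted in `store` under `key`; the masked
#' coordinates themselves carry no trace of it. Ids and attribute columns pass
#' through unchanged.
#'
#' If `min_displacement > 0`, the draw is repeated (up to `max_retries` times)
#' until every point has moved at least that far from its original location —
#' the rotation can, for unlucky draws, return a point near its origin even
#' though the translation alone respects its componentwise minimum offsets.
#'
#' @param points a [point_set()] in a projected CRS; must be non-empty.
#' @param intervals an [offset_intervals()].
#' @param key user-chosen string identifying this masking in the key store.
#' @param store a [key_store()].
#' @param seed optional integer; makes the draw of `(r, theta)` reproducible.
#' @param min_displacement minimum allowed displacement of any point, metres.
#' @param max_retries redraw budget for the minimum-displacement guarantee.
#' @param theta,r verification hooks overriding the random draws (`theta` may
#'   then also be 0). Fixing them in production weakens the mask — anyone who
#'   knows the angle needs only the translation to invert it.
#' @return a list with components `points` (the masked [point_set()]) and
#'   `record` (the [mask_key_record()] that was saved).
#' @seealso [unmask_points()], [displacement_check()]
#' @export
mask_points <- function(points, intervals, key, store,
                        seed = NULL, min_displacement = 0, max_retries = 100,
                        theta = NULL, r = NULL) {
  if (!inherits(points, "point_set")) stop("points must be a point_set")
  if (!nrow(points)) stop("cannot mask an empty point set")
  if (!inherits(intervals, "offset_intervals"))
    stop("intervals must be an offset_intervals object")
  stop_if_geographic(points, "masking")
  if (is.na(point_crs(points)))
    warning("point set has no CRS; assuming projected metric coordinates")
  if (key_exists(store, key))
    stop("key collision: key ", sQuote(key), " already exists in the key store")
  if (!is.null(theta)) check_quarter_angle(theta, allow_zero = TRUE)
  if (!is.null(r) && (r < 0 || r >= 1)) stop("r must lie in [0, 1)")

  draw <- with_seed(seed, {
    tries <- 0L
    repeat {
      tries <- tries + 1L
      r_i <- if (is.null(r)) stats::runif(1) else r
      th_i <- if (is.null(theta)) sample(c(90L, 180L, 270L), 1) else as.integer(theta)
      masked <- apply_mask(points, intervals, r_i, th_i)
      disp <- sqrt((masked$x - points$x)^2 + (masked$y - points$y)^2)
      if (min_displacement <= 0 || all(disp >= min_displacement)) break
      if ((!is.null(r) && !is.null(theta)) || tries >= max_retries)
        stop("could not satisfy min_displacement = ", min_displacement,
             " m after ", tries, " draw(s); widen the offset intervals")
    }
    list(r = r_i, theta = th_i, masked = masked, tries = tries)
  })

  record <- mask_key_record(
    key = key, r = draw$r, theta_deg = draw$theta, intervals = intervals,
    masked_extent = point_extent(draw$masked), crs = point_crs(points))
  save_record(store, record)
  list(points = draw$masked, record = record)
}

apply_mask <- function(points, intervals, r, theta_deg) {
  tx <- r * (intervals$x2 - intervals$x1) + intervals$x1
  ty <- r * (intervals$y2 - intervals$y1) + intervals$y1
  rot <- rotate_about_origin(cbind(points$x + tx, points$y + ty),
                             theta_deg, "clockwise")
  out <- points
  out$x <- rot[, "x"]
  out$y <- rot[, "y"]
  out
}

#' Unmask (re-transform) a masked point set
#'
#' Inverts [mask_points()] using the secret stored under `key`: an
#' anticlockwise re-rotation by the stored angle brings the coordinates back
#' to the original orientation, then the stored random offset is subtracted
#' (`x = X - r*(x2 - x1) - x1`, likewise for y). The result matches the
#' original coordinates per id to within floating-point rounding.
#'
#' The masked set may be a subset of the points originally masked (a
#' collaborator may return fewer records); a message notes the count.
#'
#' @param masked a masked [point_set()].
#' @param key the key the data was masked under.
#' @param store the [key_store()] holding the mask record.
#' @return the re-transformed [point_set()], CRS restored from the record.
#' @export
unmask_points <- function(masked, key, store) {
  if (!inherits(masked, "point_set")) stop("masked must be a point_set")
  record <- load_record(store, key)
  rot <- rotate_about_origin(cbind(masked$x, masked$y),
                             record$theta_deg, "anticlockwise")
  iv <- record$intervals
  tx <- record$r * (iv$x2 - iv$x1) + iv$x1
  ty <- record$r * (iv$y2 - iv$y1) + iv$y1
  out <- masked
  out$x <- rot[, "x"] - tx
  out$y <- rot[, "y"] - ty
  attr(out, "crs") <- record$crs
  out
}

#' Per-point displacement report
#'
#' Checks the donut-style guarantee: the Euclidean displacement of every
#' masked point from its original location, matched by id, against a required
#' minimum distance.
#'
#' @param original,masked [point_set()]s over the same ids.
#' @param min_distance required minimum displacement, metres.
#' @return a list with `displacements` (data frame of `id`, `distance`),
#'   `min`, `max`, and logical `pass` (every displacement `>= min_distance`).
#' @export
displacement_check <- function(original, masked, min_distance) {
  if (!setequal(original$id, masked$id) || nrow(original) != nrow(masked))
    stop("original and masked point sets must carry the same ids")
  m <- masked[match(original$id, masked$id), ]
  d <- sqrt((m$x - original$x)^2 + (m$y - original$y)^2)
  list(displacements = data.frame(id = original$id, distance = d,
                                  stringsAsFactors = FALSE),
       min = min(d), max = max(d),
       pass = all(d >= min_distance))
}
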
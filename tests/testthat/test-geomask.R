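# Forward obfuscation and exact inverse of the keyed affine mask.

test_that("translation step follows the offset formula exactly", {
  p <- point_set(10, 20, crs = local_metric_crs())
  iv <- offset_intervals(100, 200, 300, 500)

  # rotation suppressed: pure translation with r = 0.5
  m <- mask_points(p, iv, "t1", tmp_store(), r = 0.5, theta = 0)
  expect_equal(c(m$points$x, m$points$y), c(160, 420))

  # all-zero intervals and no rotation: identity
  iv0 <- suppressWarnings(offset_intervals(0, 0, 0, 0))
  m0 <- mask_points(p, iv0, "t2", tmp_store(), r = 0, theta = 0)
  expect_identical(c(m0$points$x, m0$points$y), c(10, 20))

  # 180-degree rotation negates the translated coordinates
  m180 <- mask_points(p, iv, "t3", tmp_store(), r = 0.5, theta = 180)
  expect_equal(c(m180$points$x, m180$points$y), c(-160, -420))
})

test_that("quarter-turn rotation matches its definition and is exactly invertible", {
  expect_equal(rotate_about_origin(cbind(1, 0), 90, "anticlockwise"),
               cbind(x = 0, y = 1))
  ab <- cbind(c(3, -2.5), c(4, 7))
  expect_equal(rotate_about_origin(ab, 180, "clockwise"),
               rotate_about_origin(ab, 180, "anticlockwise"))
  expect_equal(unname(rotate_about_origin(ab, 180, "clockwise")), unname(-ab))

  set.seed(99)
  pts <- cbind(runif(40, -1e5, 1e5), runif(40, -1e5, 1e5))
  for (th in c(0, 90, 180, 270)) {
    back <- rotate_about_origin(rotate_about_origin(pts, th, "clockwise"),
                                th, "anticlockwise")
    expect_identical(max(abs(back - pts)), 0)  # exact, not just close
  }
  expect_error(rotate_about_origin(cbind(1, 1), 45), "angle")
})

test_that("mask then unmask restores every point exactly, for all angles and seeds", {
  pts <- clustered_points(seed = 4)
  for (th in c(90, 180, 270)) {
    for (seed in c(1, 17)) {
      st <- tmp_store()
      res <- mask_points(pts, default_intervals(), "k", st,
                         seed = seed, theta = th)
      back <- unmask_points(res$points, "k", st)
      expect_lt(point_distance_report(pts, back)$max, 1e-6)
      expect_identical(back$id, pts$id)
    }
  }
})

test_that("masking is an isometry and preserves the bounding-box area", {
  pts <- clustered_points(seed = 8)
  st <- tmp_store()
  res <- mask_points(pts, default_intervals(), "k", st, seed = 2)
  i <- seq(1, nrow(pts), by = 7)
  j <- seq(2, nrow(pts), by = 11)
  n <- min(length(i), length(j))
  d0 <- sqrt((pts$x[i[1:n]] - pts$x[j[1:n]])^2 + (pts$y[i[1:n]] - pts$y[j[1:n]])^2)
  d1 <- sqrt((res$points$x[i[1:n]] - res$points$x[j[1:n]])^2 +
             (res$points$y[i[1:n]] - res$points$y[j[1:n]])^2)
  expect_lt(max(abs(d1 - d0)), 1e-6)
  a0 <- extent_area(point_extent(pts))
  a1 <- extent_area(point_extent(res$points))
  expect_lt(abs(a1 - a0) / a0, 1e-12)
})

test_that("ids and attributes pass through masking byte-identical", {
  pts <- tiny_points()
  st <- tmp_store()
  res <- mask_points(pts, default_intervals(), "k", st, seed = 3)
  back <- unmask_points(res$points, "k", st)
  for (col in c("id", "age", "weight", "town")) {
    expect_identical(res$points[[col]], pts[[col]])
    expect_identical(back[[col]], pts[[col]])
  }
  expect_identical(point_crs(back), point_crs(pts))
})

test_that("same key material and seed give bit-identical masked output", {
  pts <- clustered_points(seed = 12)
  r1 <- mask_points(pts, default_intervals(), "k", tmp_store(), seed = 5)
  r2 <- mask_points(pts, default_intervals(), "k", tmp_store(), seed = 5)
  expect_identical(r1$points$x, r2$points$x)
  expect_identical(r1$points$y, r2$points$y)
  expect_identical(r1$record$r, r2$record$r)
  expect_identical(r1$record$theta_deg, r2$record$theta_deg)
})

test_that("unmasking with a wrong-but-existing key does not recover the points", {
  pts <- clustered_points(seed = 6)
  st <- tmp_store()
  res <- mask_points(pts, default_intervals(), "right", st, seed = 1, theta = 90)
  mask_points(pts, default_intervals(), "wrong", st, seed = 2, theta = 180)
  wrong <- unmask_points(res$points, "wrong", st)
  min_offset <- sqrt(1000^2 + 3000^2)
  expect_gt(point_distance_report(pts, wrong)$max, min_offset)
  right <- unmask_points(res$points, "right", st)
  expect_lt(point_distance_report(pts, right)$max, 1e-6)
})

test_that("masking rejects bad inputs", {
  st <- tmp_store()
  pts <- clustered_points(seed = 2)
  mask_points(pts, default_intervals(), "dup", st, seed = 1)
  expect_error(mask_points(pts, default_intervals(), "dup", st, seed = 1),
               "collision")
  expect_error(mask_points(point_set(numeric(0), numeric(0)),
                           default_intervals(), "e", st),
               "empty")
  lonlat <- point_set(-90.07, 29.95, crs = "GEOGCS[\"WGS 84\"]")
  expect_error(mask_points(lonlat, default_intervals(), "g", st),
               "projected")
  expect_error(unmask_points(pts, "absent", st), "absent")
  expect_error(offset_intervals(10, 5, 0, 1), "x2 >= x1")
  expect_warning(offset_intervals(5, 5, 5, 5), "privacy")
})

test_that("displacement guarantee: translation floor, redraw enforcement, report", {
  pts <- clustered_points(seed = 9)

  # identity mask passes a zero minimum with all-zero displacements
  iv0 <- suppressWarnings(offset_intervals(0, 0, 0, 0))
  id_mask <- mask_points(pts, iv0, "k0", tmp_store(), r = 0, theta = 0)
  chk <- displacement_check(pts, id_mask$points, 0)
  expect_true(chk$pass)
  expect_identical(chk$max, 0)

  # translation-only stage displaces at least sqrt(x1^2 + y1^2)
  iv <- offset_intervals(100, 200, 300, 500)
  tr <- mask_points(pts, iv, "k1", tmp_store(), seed = 4, theta = 0)
  expect_true(displacement_check(pts, tr$points, sqrt(100^2 + 300^2))$pass)

  # full mask with a demanding minimum: satisfied within the retry budget,
  # verified by explicit distance computation
  e <- point_extent(pts)
  min_d <- 10 * max(extent_width(e), extent_height(e))
  big <- offset_intervals(min_d, 2 * min_d, min_d, 2 * min_d)
  full <- mask_points(pts, big, "k2", tmp_store(), seed = 4,
                      min_displacement = min_d)
  d <- sqrt((full$points$x - pts$x)^2 + (full$points$y - pts$y)^2)
  expect_true(all(d >= min_d))

  expect_error(displacement_check(pts, pts[-1, ], 0), "ids")
})
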
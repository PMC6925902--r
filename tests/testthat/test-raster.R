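# Raster re-transformation: value rotation, corner placement, extent
# adjustment arithmetic.

test_that("quarter-turn value rotation permutes cells exactly", {
  m <- rbind(c(1, 2), c(3, 4))
  expect_identical(rotate_raster_values(m, 180), rbind(c(4, 3), c(2, 1)))
  r <- m
  for (i in 1:4) r <- rotate_raster_values(r, 90)
  expect_identical(r, m)
  expect_identical(rotate_raster_values(matrix(7), 270), matrix(7))
  rect <- matrix(1:6, 2, 3)
  expect_identical(dim(rotate_raster_values(rect, 90)), c(3L, 2L))
  expect_identical(sort(c(rotate_raster_values(rect, 90))), sort(c(rect)))
  expect_error(rotate_raster_values(m, 45), "angle")
})

test_that("unadjusted top-left follows rotation plus re-translation", {
  # masked raster spanning x [-170,-150], y [-430,-410]; 180-degree mask with
  # r = 0.5 over intervals {100,200} x {300,500}
  grid <- raster_grid(matrix(0, 2, 2), top_left = c(-170, -410), cell_size = 10)
  rec <- mask_key_record("k", 0.5, 180, offset_intervals(100, 200, 300, 500),
                         raster_extent(grid))
  expect_equal(unname(unadjusted_topleft(grid, rec)), c(0, 30))

  # oracle: unmasking the bottom-right corner coordinate gives the same point
  st <- tmp_store(); save_record(st, rec)
  corner <- point_set(-150, -430)
  expect_equal(unname(unadjusted_topleft(grid, rec)),
               c(unmask_points(corner, "k", st)$x,
                 unmask_points(corner, "k", st)$y))

  # zero intervals and r = 0: pure 180 rotation negates the bottom-right
  iv0 <- suppressWarnings(offset_intervals(0, 0, 0, 0))
  rec0 <- mask_key_record("k0", 0, 180, iv0, raster_extent(grid))
  expect_equal(unname(unadjusted_topleft(grid, rec0)), c(150, 430))

  # identity record: the corner comes back unchanged as the top-left
  recid <- mask_key_record("ki", 0, 0, iv0, raster_extent(grid))
  expect_equal(unname(unadjusted_topleft(grid, recid)), c(-170, -410))
})

test_that("extent adjustment arithmetic", {
  e <- extent(0, 0, 100, 50)
  expect_equal(unname(extent_adjustment(e, e)), c(0, 0))
  pad <- extent(-5, -5, 105, 55)                  # symmetric padding cancels
  expect_equal(unname(extent_adjustment(e, pad)), c(0, 0))
  shifted <- extent(5, 0, 105, 50)                # +5 m in x only
  expect_equal(unname(extent_adjustment(e, shifted)), c(-10, 0))
})

test_that("final top-left applies the printed sign rule for y", {
  # hand-computed: tl = (0, 30) from the unadjusted case above; then shift the
  # raster extent relative to the stored point extent to force adjustments
  grid <- raster_grid(matrix(1:4, 2, 2), top_left = c(-170, -410), cell_size = 10)
  iv <- offset_intervals(100, 200, 300, 500)
  st <- tmp_store()
  # stored point extent deliberately offset from the raster footprint:
  # x_adj = (3-0)+(3-0) = 6, y_adj = (-4-0)+(-4-0) = -8  (y_adj < 0 branch)
  save_record(st, mask_key_record("k", 0.5, 180, iv,
                                  extent(-167, -434, -147, -414)))
  out <- retransform_raster(grid, "k", st)
  expect_equal(unname(out$top_left), c(0 - 6, 30 + (-8)))
  # y_adj >= 0 branch
  save_record(st, mask_key_record("k2", 0.5, 180, iv,
                                  extent(-170, -426, -150, -406)))
  out2 <- retransform_raster(grid, "k2", st)
  expect_equal(unname(out2$top_left), c(0, 30 - 8))
})

test_that("a 1x1 raster re-transforms with value and origin intact", {
  pts <- point_set(c(10, 20), c(30, 44), crs = local_metric_crs())
  st <- tmp_store()
  res <- mask_points(pts, default_intervals(), "k", st, seed = 2, theta = 180)
  e <- point_extent(res$points)
  g <- raster_grid(matrix(42), top_left = c(e$xmin, e$ymax),
                   cell_size = max(extent_width(e), extent_height(e)))
  out <- retransform_raster(g, "k", st)
  expect_identical(out$values, matrix(42))
  expect_identical(out$cell_size, g$cell_size)
  expect_identical(out$crs, local_metric_crs())
})

test_that("value multiset is conserved and cell centers land on unmasked positions", {
  pts <- pinned_points(seed = 5)
  for (th in c(90, 180, 270)) {
    st <- tmp_store()
    res <- mask_points(pts, default_intervals(), "k", st, seed = 7, theta = th)
    e <- point_extent(res$points)
    g <- kde_surface(res$points, bandwidth = 500, cell_size = 250, extent_ = e)
    out <- retransform_raster(g, "k", st)
    expect_identical(sort(c(out$values)), sort(c(g$values)))

    # every re-transformed cell center is the unmasked image of a masked one
    cm <- raster_cell_centers(g)
    masked_centers <- point_set(cm$x, cm$y, id = paste(cm$row, cm$col))
    um <- unmask_points(masked_centers, "k", st)
    co <- raster_cell_centers(out)
    gap <- vapply(seq_len(nrow(co)), function(i) {
      min(sqrt((um$x - co$x[i])^2 + (um$y - co$y[i])^2))
    }, numeric(1))
    expect_lt(max(gap), 1e-6)
  }
})

test_that("non-raster inputs and unknown keys are rejected", {
  st <- tmp_store()
  expect_error(retransform_raster(matrix(1), "k", st), "raster_grid")
  g <- raster_grid(matrix(1), top_left = c(0, 1), cell_size = 1)
  expect_error(retransform_raster(g, "absent", st), "absent")
})
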
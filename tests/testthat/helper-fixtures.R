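# Shared fixtures, built in code at test time.

tmp_store <- function() key_store(tempfile(fileext = ".jsonl"))

default_intervals <- function() offset_intervals(1000, 2000, 3000, 5000)

# A clustered pattern in the default 5 x 5 km window.
clustered_points <- function(seed = 1L, ...) {
  generate_thomas_cluster(cluster_params(seed = seed, ...))
}

# Clustered pattern whose bounding box is pinned to the window by adding the
# four window corners as points: the masked bounding box is then the exact
# geometric image of the original one, which is what makes surface grids in
# the two geographies exact images of each other (see the methods vignette).
pinned_points <- function(seed = 1L, window = extent(0, 0, 5000, 5000)) {
  pts <- generate_thomas_cluster(cluster_params(window = window, seed = seed))
  point_set(x = c(pts$x, window$xmin, window$xmax, window$xmin, window$xmax),
            y = c(pts$y, window$ymin, window$ymin, window$ymax, window$ymax),
            crs = local_metric_crs())
}

# A tiny deterministic point set with attributes, for I/O and unit examples.
tiny_points <- function() {
  point_set(x = c(10, 250.5, -30, 1024),
            y = c(20, -40.25, 512, 7),
            id = c("a", "b", "c", "d"),
            attrs = data.frame(age = c(1L, 2L, 3L, 4L),
                               weight = c(1.5, 2.25, 3.125, 4.0625),
                               town = c("n", "s", "e", "w"),
                               stringsAsFactors = FALSE),
            crs = local_metric_crs())
}

max_rel_diff <- function(a, b) {
  max(abs(a - b) / pmax(abs(a), abs(b), .Machine$double.eps))
}
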
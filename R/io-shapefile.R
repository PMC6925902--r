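# ESRI shapefile I/O for point layers. The geometry files (.shp/.shx) follow
# the published shapefile layout for shape type 1 (Point); the attribute table
# (.dbf) goes through foreign::read.dbf/write.dbf; the CRS travels in a .prj
# sidecar as an opaque string. Only point layers are supported — this is a
# point-masking tool.

SHP_MAGIC <- 9994L
SHP_VERSION <- 1000L
SHP_TYPE_POINT <- 1L

shp_paths <- function(path) {
  base <- sub("\\.shp$", "", path, ignore.case = TRUE)
  list(shp = paste0(base, ".shp"), shx = paste0(base, ".shx"),
       dbf = paste0(base, ".dbf"), prj = paste0(base, ".prj"))
}

write_shp_header <- function(con, file_length_words, n_pts, x, y) {
  writeBin(SHP_MAGIC, con, size = 4, endian = "big")
  writeBin(integer(5), con, size = 4, endian = "big")
  writeBin(as.integer(file_length_words), con, size = 4, endian = "big")
  writeBin(SHP_VERSION, con, size = 4, endian = "little")
  writeBin(SHP_TYPE_POINT, con, size = 4, endian = "little")
  bbox <- if (n_pts) c(min(x), min(y), max(x), max(y)) else numeric(4)
  writeBin(c(bbox, 0, 0, 0, 0), con, size = 8, endian = "little")
}

#' Write a point set as an ESRI shapefile
#'
#' Writes `.shp`/`.shx`/`.dbf` (and `.prj` when a CRS is present). The
#' attribute table holds the `id` column followed by the point set's
#' attribute columns; masked outputs therefore carry the same schema as
#' their input, and no masking metadata of any kind.
#'
#' @param points a [point_set()].
#' @param path output path (with or without the `.shp` extension).
#' @return the `.shp` path, invisibly.
#' @export
write_points <- function(points, path) {
  if (!inherits(points, "point_set")) stop("points must be a point_set")
  p <- shp_paths(path)
  n <- nrow(points)
  rec_words <- 10L                       # point record content: 4 + 8 + 8 bytes
  file_words <- 50L + n * (4L + rec_words)

  con <- file(p$shp, "wb"); on.exit(close(con), add = TRUE)
  write_shp_header(con, file_words, n, points$x, points$y)
  for (i in seq_len(n)) {
    writeBin(i, con, size = 4, endian = "big")
    writeBin(rec_words, con, size = 4, endian = "big")
    writeBin(SHP_TYPE_POINT, con, size = 4, endian = "little")
    writeBin(c(points$x[i], points$y[i]), con, size = 8, endian = "little")
  }

  shx <- file(p$shx, "wb"); on.exit(close(shx), add = TRUE)
  write_shp_header(shx, 50L + n * 4L, n, points$x, points$y)
  offsets <- 50L + (seq_len(n) - 1L) * (4L + rec_words)
  for (i in seq_len(n)) {
    writeBin(offsets[i], shx, size = 4, endian = "big")
    writeBin(rec_words, shx, size = 4, endian = "big")
  }

  tab <- as.data.frame(points, stringsAsFactors = FALSE)
  class(tab) <- "data.frame"
  tab <- tab[, setdiff(names(tab), c("x", "y")), drop = FALSE]
  if (n == 0L) suppressWarnings(foreign::write.dbf(tab, p$dbf))
  else foreign::write.dbf(tab, p$dbf)

  crs <- point_crs(points)
  if (!is.na(crs)) writeLines(crs, p$prj)
  invisible(p$shp)
}

#' Read a point shapefile
#'
#' Reads a shape-type-1 (Point) layer back into a [point_set()]: coordinates
#' from `.shp`, attributes from `.dbf` (a column named `id`, if present, is
#' used as the point ids), CRS from `.prj` when present.
#'
#' @param path path to the `.shp` file (extension optional).
#' @return a [point_set()].
#' @export
read_points <- function(path) {
  p <- shp_paths(path)
  if (!file.exists(p$shp)) stop("no such shapefile: ", p$shp)
  con <- file(p$shp, "rb"); on.exit(close(con), add = TRUE)
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (!identical(magic, SHP_MAGIC)) stop(p$shp, " is not a shapefile")
  readBin(con, "integer", 5, size = 4, endian = "big")
  file_words <- readBin(con, "integer", 1, size = 4, endian = "big")
  version <- readBin(con, "integer", 1, size = 4, endian = "little")
  shp_type <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!identical(shp_type, SHP_TYPE_POINT))
    stop("unsupported shape type ", shp_type, " (only Point layers are read)")
  readBin(con, "double", 8, size = 8, endian = "little")

  xs <- ys <- numeric(0)
  words_read <- 50L
  while (words_read < file_words) {
    readBin(con, "integer", 1, size = 4, endian = "big")          # record no.
    clen <- readBin(con, "integer", 1, size = 4, endian = "big")
    rtype <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (!identical(rtype, SHP_TYPE_POINT))
      stop("malformed shapefile: record of shape type ", rtype)
    xy <- readBin(con, "double", 2, size = 8, endian = "little")
    xs <- c(xs, xy[1]); ys <- c(ys, xy[2])
    words_read <- words_read + 4L + clen
  }
  if (!length(xs)) stop("shapefile ", p$shp, " contains no points")

  attrs <- NULL; ids <- NULL
  if (file.exists(p$dbf)) {
    tab <- foreign::read.dbf(p$dbf, as.is = TRUE)
    if (nrow(tab) != length(xs))
      stop("attribute table has ", nrow(tab), " rows for ", length(xs), " points")
    if ("id" %in% names(tab)) {
      ids <- as.character(tab$id)
      tab <- tab[, setdiff(names(tab), "id"), drop = FALSE]
    }
    if (ncol(tab)) attrs <- tab
  }
  crs <- if (file.exists(p$prj)) paste(readLines(p$prj, warn = FALSE), collapse = "")
         else NA_character_
  point_set(x = xs, y = ys, id = ids, attrs = attrs, crs = crs)
}
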
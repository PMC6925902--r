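# Raster I/O in the ESRI ASCII grid (.asc) interchange format: a plain-text
# header (ncols, nrows, corner, cellsize, nodata) followed by the value matrix
# north row first. The format carries exactly the fields of a north-up,
# square-cell raster_grid, is readable by standard GIS software, and being
# text it diffs and version-controls cleanly. CRS travels in a .prj sidecar.

#' Write a raster grid as an ESRI ASCII grid
#'
#' @param grid a [raster_grid()].
#' @param path output path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path) {
  if (!inherits(grid, "raster_grid")) stop("grid must be a raster_grid")
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  e <- raster_extent(grid)
  header <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.17g", e$xmin),
    sprintf("yllcorner %.17g", e$ymin),
    sprintf("cellsize %.17g", grid$cell_size),
    sprintf("NODATA_value %.17g", grid$nodata))
  v[is.na(v)] <- grid$nodata
  rows <- apply(v, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(header, rows), path)
  if (!is.null(grid$crs) && !is.na(grid$crs))
    writeLines(grid$crs, paste0(sub("\\.asc$", "", path, ignore.case = TRUE), ".prj"))
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path path to the `.asc` file.
#' @return a [raster_grid()]; nodata cells become `NA`.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("no such raster file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- suppressWarnings(as.numeric(parts[2]))
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop(path, " is not an ESRI ASCII grid (missing ",
         paste(setdiff(need, names(hdr)), collapse = ", "), ")")
  if (is.null(hdr$xllcorner) || is.null(hdr$yllcorner)) {
    if (!is.null(hdr$xllcenter)) {
      # center-anchored variant of the format
      hdr$xllcorner <- hdr$xllcenter - hdr$cellsize / 2
      hdr$yllcorner <- hdr$yllcenter - hdr$cellsize / 2
    } else stop(path, ": no lower-left corner in header")
  }
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop(path, ": expected ", nr * nc, " cell values, found ", length(vals))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  prj <- paste0(sub("\\.asc$", "", path, ignore.case = TRUE), ".prj")
  crs <- if (file.exists(prj)) paste(readLines(prj, warn = FALSE), collapse = "")
         else NA_character_
  raster_grid(m, top_left = c(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize),
              cell_size = hdr$cellsize, crs = crs, nodata = nodata)
}
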
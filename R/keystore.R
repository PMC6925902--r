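#' Mask key record
#'
#' The secret state of one masking run: the random number `r`, the rotation
#' angle, the offset intervals, the extent of the masked points (needed for
#' raster re-transformation), and the original CRS. Everything required to
#' re-transform points or rasters; nothing of it is ever written into masked
#' outputs.
#'
#' @param key user key string.
#' @param r the random number in `[0, 1)` used for the translation.
#' @param theta_deg the clockwise rotation angle applied at masking time; one
#'   of 90, 180, 270 (0 allowed for verification records).
#' @param intervals an [offset_intervals()].
#' @param masked_extent the [extent()] of the masked points.
#' @param crs the CRS of the original data (restored on re-transformation).
#' @param created creation time (POSIXct); defaults to now.
#' @return an object of class `mask_key_record`.
#' @export
mask_key_record <- function(key, r, theta_deg, intervals, masked_extent,
                            crs = NA_character_, created = Sys.time()) {
  if (!nzchar(key)) stop("key must be a non-empty string")
  if (!is.numeric(r) || r < 0 || r >= 1) stop("r must lie in [0, 1)")
  theta_deg <- check_quarter_angle(theta_deg, allow_zero = TRUE)
  if (!inherits(intervals, "offset_intervals"))
    stop("intervals must be an offset_intervals object")
  masked_extent <- as_extent(masked_extent)
  structure(list(key = as.character(key), r = as.numeric(r),
                 theta_deg = theta_deg, intervals = intervals,
                 masked_extent = masked_extent,
                 crs = if (is.null(crs)) NA_character_ else as.character(crs),
                 created = as.POSIXct(created)),
            class = "mask_key_record")
}

#' @export
print.mask_key_record <- function(x, ...) {
  cat(sprintf("<mask_key_record> key: %s  created: %s  (secret fields hidden; use str() to inspect)\n",
              sQuote(x$key), format(x$created, "%Y-%m-%d %H:%M:%S")))
  invisible(x)
}

KEYSTORE_FORMAT  <- "isomask-keystore"
KEYSTORE_VERSION <- 1L

#' Open (or create) a local key store
#'
#' The key store is the data guardian's local secret database: a single
#' append-only text file of JSON records (one per line) under a versioned
#' header line. Keys are unique — saving under an existing key is an error,
#' never a silent overwrite, because losing a record makes the masked data
#' unrecoverable. The file persists across sessions; numeric fields round-trip
#' at full double precision.
#'
#' @param path file path; created (with parent directories) if absent. The
#'   default lives under the user's application-data directory as given by
#'   [tools::R_user_dir()].
#' @return an object of class `key_store`.
#' @export
key_store <- function(path = file.path(tools::R_user_dir("isomask", "data"),
                                       "keystore.jsonl")) {
  if (!file.exists(path)) {
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    header <- jsonlite::toJSON(list(format = KEYSTORE_FORMAT,
                                    version = KEYSTORE_VERSION),
                               auto_unbox = TRUE)
    writeLines(as.character(header), path)
  } else {
    first <- readLines(path, n = 1L, warn = FALSE)
    hd <- tryCatch(jsonlite::fromJSON(first), error = function(e) NULL)
    if (is.null(hd) || !identical(hd$format, KEYSTORE_FORMAT))
      stop("file ", sQuote(path), " is not an isomask key store")
    if (hd$version > KEYSTORE_VERSION)
      stop("key store ", sQuote(path), " has schema version ", hd$version,
           "; this build reads versions <= ", KEYSTORE_VERSION)
  }
  structure(list(path = normalizePath(path)), class = "key_store")
}

#' @export
print.key_store <- function(x, ...) {
  cat(sprintf("<key_store> %s (%d record(s))\n", x$path, nrow(list_keys(x))))
  invisible(x)
}

read_store_lines <- function(store) {
  lines <- readLines(store$path, warn = FALSE)
  lines[-1][nzchar(lines[-1])]
}

record_to_json <- function(record) {
  payload <- list(
    key = record$key, r = record$r, theta_deg = record$theta_deg,
    intervals = record$intervals[c("x1", "x2", "y1", "y2")],
    masked_extent = record$masked_extent[c("xmin", "ymin", "xmax", "ymax")],
    crs = record$crs,
    created = format(record$created, "%Y-%m-%dT%H:%M:%OS6%z"))
  # 17 significant digits round-trip doubles (notably r) exactly
  as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17),
                                na = "null"))
}

json_to_record <- function(line) {
  p <- jsonlite::fromJSON(line)
  mask_key_record(
    key = p$key, r = p$r, theta_deg = p$theta_deg,
    intervals = suppressWarnings(
      offset_intervals(p$intervals$x1, p$intervals$x2,
                       p$intervals$y1, p$intervals$y2)),
    masked_extent = extent(p$masked_extent$xmin, p$masked_extent$ymin,
                           p$masked_extent$xmax, p$masked_extent$ymax),
    crs = if (is.null(p$crs)) NA_character_ else p$crs,
    created = as.POSIXct(p$created, format = "%Y-%m-%dT%H:%M:%OS%z"))
}

# Records are serialized with `key` as the first field, so a line for `key`
# starts with its exact serialization; that prefix test is the fast path for
# lookups (the store is append-only, written by this package). A full parse
# of every line is the fallback so foreign-but-valid files still work.
key_prefix <- function(key) {
  paste0('{"key":', as.character(jsonlite::toJSON(key, auto_unbox = TRUE)), ",")
}

find_key_line <- function(store, key) {
  lines <- read_store_lines(store)
  hit <- which(startsWith(lines, key_prefix(key)))
  if (length(hit)) return(lines[hit[1]])
  needle <- as.character(jsonlite::toJSON(key, auto_unbox = TRUE))
  for (line in grep(needle, lines, fixed = TRUE, value = TRUE))
    if (identical(jsonlite::fromJSON(line)$key, key)) return(line)
  NULL
}

store_keys <- function(store) {
  lines <- read_store_lines(store)
  vapply(lines, function(l) jsonlite::fromJSON(l)$key, character(1),
         USE.NAMES = FALSE)
}

#' Does a key exist in the store?
#' @param store a [key_store()].
#' @param key key string.
#' @return `TRUE`/`FALSE`.
#' @export
key_exists <- function(store, key) !is.null(find_key_line(store, key))

#' Save a mask record
#'
#' Appends one record to the store. Duplicate keys are refused.
#' @param store a [key_store()].
#' @param record a [mask_key_record()].
#' @return the store, invisibly.
#' @export
save_record <- function(store, record) {
  if (!inherits(record, "mask_key_record"))
    stop("record must be a mask_key_record")
  if (key_exists(store, record$key))
    stop("key collision: key ", sQuote(record$key),
         " already exists in the key store (records are never overwritten)")
  cat(record_to_json(record), "\n", sep = "",
      file = store$path, append = TRUE)
  invisible(store)
}

#' Load a mask record by key
#' @param store a [key_store()].
#' @param key key string.
#' @return the stored [mask_key_record()].
#' @export
load_record <- function(store, key) {
  line <- find_key_line(store, key)
  if (is.null(line))
    stop("no record for key ", sQuote(key), " in key store ", sQuote(store$path))
  json_to_record(line)
}

#' List stored keys
#' @param store a [key_store()].
#' @return a data frame of `key` and `created`, in insertion (creation) order.
#' @export
list_keys <- function(store) {
  lines <- read_store_lines(store)
  if (!length(lines))
    return(data.frame(key = character(), created = as.POSIXct(character()),
                      stringsAsFactors = FALSE))
  recs <- lapply(lines, json_to_record)
  data.frame(key = vapply(recs, `[[`, character(1), "key"),
             created = do.call(c, lapply(recs, `[[`, "created")),
             stringsAsFactors = FALSE)
}

#' Delete a mask record
#'
#' Deletion makes data masked under that key unrecoverable, so it must be
#' confirmed explicitly.
#' @param store a [key_store()].
#' @param key key to remove.
#' @param confirm must be `TRUE` to proceed.
#' @return the store, invisibly.
#' @export
delete_record <- function(store, key, confirm = FALSE) {
  if (!isTRUE(confirm))
    stop("refusing to delete record ", sQuote(key),
         " without confirm = TRUE (masked data becomes unrecoverable)")
  lines <- read_store_lines(store)
  keep <- vapply(lines, function(l) !identical(jsonlite::fromJSON(l)$key, key),
                 logical(1))
  if (all(keep)) stop("no record for key ", sQuote(key))
  header <- readLines(store$path, n = 1L, warn = FALSE)
  writeLines(c(header, lines[keep]), store$path)
  invisible(store)
}
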
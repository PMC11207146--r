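# Minimal planar raster-pair container: co-registered forest indicator and
# EVI grids at program start (t0) and survey year (t1). Row 1 is the
# southernmost row; cell (i, j) has its centre at
# origin + ((j - 0.5), (i - 0.5)) * cell_size.

#' Construct a co-registered forest/EVI raster pair
#'
#' @param forest_t0,forest_t1 integer matrices of 0/1 forest indicators.
#' @param evi_t0,evi_t1 numeric matrices of EVI values in \[-1, 1\]
#'   (NA allowed, typically where the forest indicator is 0).
#' @param cell_size cell edge length in metres (default 30, Landsat-like).
#' @param origin numeric length-2, coordinates of the south-west raster
#'   corner in site-local metres.
#' @param site optional site label.
#' @return object of class `raster_pair`.
#' @export
raster_pair <- function(forest_t0, forest_t1, evi_t0, evi_t1,
                        cell_size = 30, origin = c(0, 0), site = NA_character_) {
  dims <- list(dim(forest_t0), dim(forest_t1), dim(evi_t0), dim(evi_t1))
  if (length(unique(vapply(dims, paste, collapse = "x", FUN.VALUE = ""))) != 1L)
    abort_bad_input("all four grids must share the same dimensions")
  for (k in list(forest_t0, forest_t1)) {
    if (!all(k %in% c(0L, 1L)))
      abort_bad_input("forest indicator grids must be binary (0/1)")
  }
  for (e in list(evi_t0, evi_t1)) {
    if (any(e < -1 - 1e-9 | e > 1 + 1e-9, na.rm = TRUE))
      abort_bad_input("EVI grids must lie in [-1, 1]")
  }
  if (cell_size <= 0) abort_bad_input("cell_size must be positive")
  structure(
    list(forest_t0 = forest_t0, forest_t1 = forest_t1,
         evi_t0 = evi_t0, evi_t1 = evi_t1,
         cell_size = cell_size, origin = as.numeric(origin),
         site = site),
    class = "raster_pair")
}

#' @export
print.raster_pair <- function(x, ...) {
  d <- dim(x$forest_t0)
  cat(sprintf("<raster_pair> %d x %d cells @ %g m, origin (%g, %g), site %s\n",
              d[1], d[2], x$cell_size, x$origin[1], x$origin[2], x$site))
  cat(sprintf("  forest fraction t0 %.3f -> t1 %.3f\n",
              mean(x$forest_t0), mean(x$forest_t1)))
  invisible(x)
}

raster_extent <- function(rp) {
  d <- dim(rp$forest_t0)
  c(xmin = rp$origin[1], xmax = rp$origin[1] + d[2] * rp$cell_size,
    ymin = rp$origin[2], ymax = rp$origin[2] + d[1] * rp$cell_size)
}

#' Write / read a raster pair as plain text
#'
#' Serialises the four bands to a single CSV file whose first line is a
#' `#meta` comment carrying the georeferencing (cell size, origin, site) as
#' JSON. The round trip `read_raster_pair(write_raster_pair(x))` is exact.
#'
#' @param rp a [raster_pair()].
#' @param path file path.
#' @return `write_raster_pair` returns `path` invisibly; `read_raster_pair`
#'   returns a `raster_pair`.
#' @export
write_raster_pair <- function(rp, path) {
  stopifnot(inherits(rp, "raster_pair"))
  d <- dim(rp$forest_t0)
  meta <- jsonlite::toJSON(list(cell_size = rp$cell_size, origin = rp$origin,
                                nrow = d[1], ncol = d[2], site = rp$site),
                           auto_unbox = TRUE, digits = NA)
  df <- data.frame(
    row = as.vector(row(rp$forest_t0)), col = as.vector(col(rp$forest_t0)),
    forest_t0 = as.vector(rp$forest_t0), forest_t1 = as.vector(rp$forest_t1),
    evi_t0 = as.vector(rp$evi_t0), evi_t1 = as.vector(rp$evi_t1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#meta ", meta), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_raster_pair
#' @export
read_raster_pair <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#meta "))
    abort_bad_input("not a raster-pair file: missing #meta header")
  meta <- jsonlite::fromJSON(sub("^#meta ", "", first))
  df <- read.csv(path, comment.char = "#")
  need <- c("row", "col", "forest_t0", "forest_t1", "evi_t0", "evi_t1")
  if (!all(need %in% names(df)))
    abort_bad_input(sprintf("raster file must carry 4 bands (%s)",
                            paste(setdiff(need, names(df)), collapse = ", ")))
  for (b in c("forest_t0", "forest_t1"))
    if (!all(df[[b]] %in% c(0L, 1L)))
      abort_bad_input(sprintf("forest band %s is not binary", b))
  grid <- function(v) {
    m <- matrix(NA_real_, meta$nrow, meta$ncol)
    m[cbind(df$row, df$col)] <- v
    m
  }
  raster_pair(grid(df$forest_t0), grid(df$forest_t1),
              grid(df$evi_t0), grid(df$evi_t1),
              cell_size = meta$cell_size, origin = as.numeric(meta$origin),
              site = meta$site %||% NA_character_)
}

# cell-centre coordinates for a window of cells (rows, cols)
cell_centres <- function(rp, rows, cols) {
  list(x = rp$origin[1] + (cols - 0.5) * rp$cell_size,
       y = rp$origin[2] + (rows - 0.5) * rp$cell_size)
}
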
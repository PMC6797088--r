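#' Georeferenced multispectral raster
#'
#' Lightweight in-memory container for a north-up multispectral image:
#' a `rows x cols x bands` array of top-of-atmosphere radiance with a
#' [band_set()] and a geotransform (top-left corner easting/northing and
#' square pixel size in meters). Missing observations are held as `NA`.
#'
#' Row/column indices are 1-based, as usual in R. The center of pixel
#' `(r, c)` is at easting `origin_x + (c - 0.5) * pixel_size` and northing
#' `origin_y - (r - 0.5) * pixel_size` (rows increase southwards).
#'
#' @param values numeric array `rows x cols x bands` (a matrix is accepted
#'   for a single band).
#' @param band_set a [band_set()]; its length must match `dim(values)[3]`.
#' @param origin_x,origin_y easting/northing of the top-left raster corner,
#'   in meters of a projected CRS.
#' @param pixel_size pixel size in meters. Defaults to the band set's
#'   multispectral pixel size.
#' @return An object of class `ms_raster`.
#' @export
ms_raster <- function(values, band_set, origin_x = 0, origin_y = NULL,
                      pixel_size = NULL) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (dim(values)[3] != nrow(band_set))
    stop(sprintf("band count mismatch: raster has %d bands, band_set has %d",
                 dim(values)[3], nrow(band_set)))
  if (is.null(pixel_size)) pixel_size <- attr(band_set, "ms_pixel_size")
  if (is.null(origin_y)) origin_y <- dim(values)[1] * pixel_size
  r <- list(values = values, band_set = band_set,
            origin_x = origin_x, origin_y = origin_y,
            pixel_size = pixel_size)
  class(r) <- "ms_raster"
  r
}

#' Georeferenced panchromatic raster
#'
#' Single-band counterpart of [ms_raster()]: a matrix of radiance with the
#' same north-up geotransform convention.
#'
#' @param values numeric matrix.
#' @param origin_x,origin_y top-left corner coordinates in meters.
#' @param pixel_size pixel size in meters.
#' @return An object of class `pan_raster`.
#' @export
pan_raster <- function(values, origin_x = 0, origin_y = NULL, pixel_size = 0.5) {
  stopifnot(is.matrix(values))
  if (is.null(origin_y)) origin_y <- nrow(values) * pixel_size
  r <- list(values = values, origin_x = origin_x, origin_y = origin_y,
            pixel_size = pixel_size)
  class(r) <- "pan_raster"
  r
}

#' @export
print.ms_raster <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<ms_raster> %d x %d pixels, %d bands, %g m pixels\n",
              d[1], d[2], d[3], x$pixel_size))
  cat(sprintf("  origin (%.2f, %.2f), %d NA cells\n",
              x$origin_x, x$origin_y, sum(is.na(x$values))))
  invisible(x)
}

#' @export
print.pan_raster <- function(x, ...) {
  cat(sprintf("<pan_raster> %d x %d pixels, %g m pixels, origin (%.2f, %.2f)\n",
              nrow(x$values), ncol(x$values), x$pixel_size,
              x$origin_x, x$origin_y))
  invisible(x)
}

#' @export
dim.ms_raster <- function(x) dim(x$values)

#' @export
dim.pan_raster <- function(x) dim(x$values)

#' Pixel-center coordinates
#'
#' Easting/northing of the centers of the given (row, col) pixels of a raster.
#'
#' @param raster an [ms_raster()] or [pan_raster()].
#' @param row,col 1-based pixel indices (vectors of equal length).
#' @return A data frame with columns `easting`, `northing`.
#' @export
pixel_centers <- function(raster, row, col) {
  data.frame(
    easting  = raster$origin_x + (col - 0.5) * raster$pixel_size,
    northing = raster$origin_y - (row - 0.5) * raster$pixel_size
  )
}

#' Block-average a fine grid to a coarser grid
#'
#' Averages non-overlapping `factor x factor` blocks of a matrix; the input
#' dimensions must be multiples of `factor`. `NA` cells propagate into the
#' block mean.
#'
#' @param m numeric matrix.
#' @param factor integer block edge length.
#' @return Matrix of dimension `dim(m) / factor`.
#' @export
block_average <- function(m, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1L, nrow(m) %% factor == 0L, ncol(m) %% factor == 0L)
  if (factor == 1L) return(m)
  nr <- nrow(m) %/% factor
  nc <- ncol(m) %/% factor
  # sum over row blocks, then column blocks
  rg <- rep(seq_len(nr), each = factor)
  cg <- rep(seq_len(nc), each = factor)
  out <- t(rowsum(t(rowsum(m, rg)), cg)) / factor^2
  dimnames(out) <- NULL
  out
}

#' Bilinear upsampling to a finer aligned grid
#'
#' Interpolates a matrix onto a grid `factor` times finer, with pixel-center
#' registration (the two grids share the same outer extent). Values beyond
#' the outermost coarse pixel centers are edge-clamped.
#'
#' @param m numeric matrix.
#' @param factor integer refinement factor.
#' @return Matrix of dimension `dim(m) * factor`.
#' @export
bilinear_upsample <- function(m, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1L)
  if (factor == 1L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  # fine center j sits at coarse coordinate (j - 0.5)/factor measured from
  # the top/left edge; coarse center i sits at i - 0.5
  fr <- (seq_len(nr * factor) - 0.5) / factor
  fc <- (seq_len(nc * factor) - 0.5) / factor
  ri <- pmin(pmax(fr + 0.5, 1), nr)   # coarse row coordinate in [1, nr]
  ci <- pmin(pmax(fc + 0.5, 1), nc)
  r0 <- pmin(pmax(floor(ri), 1L), nr - 1L); r1 <- r0 + 1L
  c0 <- pmin(pmax(floor(ci), 1L), nc - 1L); c1 <- c0 + 1L
  wr <- ri - r0; wc <- ci - c0
  if (nr == 1L) { r0 <- r1 <- rep(1L, length(ri)); wr <- rep(0, length(ri)) }
  if (nc == 1L) { c0 <- c1 <- rep(1L, length(ci)); wc <- rep(0, length(ci)) }
  a <- m[r0, c0, drop = FALSE]; b <- m[r0, c1, drop = FALSE]
  d <- m[r1, c0, drop = FALSE]; e <- m[r1, c1, drop = FALSE]
  WR <- matrix(wr, length(wr), length(wc))
  WC <- matrix(wc, length(wr), length(wc), byrow = TRUE)
  a * (1 - WR) * (1 - WC) + b * (1 - WR) * WC + d * WR * (1 - WC) + e * WR * WC
}

# ---- ESRI ASCII grid I/O -----------------------------------------------

write_asc <- function(m, path, origin_x, origin_y, pixel_size,
                      nodata = -9999) {
  v <- m
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", origin_x),
    sprintf("yllcorner %.10g", origin_y - nrow(m) * pixel_size),
    sprintf("cellsize %.10g", pixel_size),
    sprintf("NODATA_value %g", nodata)
  ), con)
  utils::write.table(format(v, trim = TRUE, digits = 9, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

read_asc <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- strsplit(trimws(hdr), "[[:space:]]+")
  key <- tolower(vapply(kv, `[`, "", 1L))
  val <- as.numeric(vapply(kv, `[`, "", 2L))
  names(val) <- key
  m <- as.matrix(utils::read.table(path, skip = 6L))
  dimnames(m) <- NULL
  stopifnot(nrow(m) == val[["nrows"]], ncol(m) == val[["ncols"]])
  m[m == val[["nodata_value"]]] <- NA
  list(values = m,
       origin_x = val[["xllcorner"]],
       origin_y = val[["yllcorner"]] + val[["nrows"]] * val[["cellsize"]],
       pixel_size = val[["cellsize"]])
}

#' Read and write rasters as ESRI ASCII grids
#'
#' A multispectral raster is written as one plain-text `.asc` grid per band
#' (`<stem>_b01.asc`, ...) plus a JSON sidecar `<stem>_bands.json` holding
#' the band names, center wavelengths and pixel sizes; a panchromatic raster
#' is a single `<stem>.asc`. The ASCII grid format is plain text and readable
#' by standard GIS software.
#'
#' @param raster an [ms_raster()] or [pan_raster()].
#' @param stem output path stem (without extension).
#' @return `write_raster` returns the path stem invisibly; `read_ms_raster`
#'   and `read_pan_raster` return the reconstructed raster.
#' @export
write_raster <- function(raster, stem) {
  if (inherits(raster, "pan_raster")) {
    write_asc(raster$values, paste0(stem, ".asc"),
              raster$origin_x, raster$origin_y, raster$pixel_size)
    return(invisible(stem))
  }
  stopifnot(inherits(raster, "ms_raster"))
  bs <- raster$band_set
  for (b in seq_len(nrow(bs))) {
    write_asc(raster$values[, , b], sprintf("%s_b%02d.asc", stem, b),
              raster$origin_x, raster$origin_y, raster$pixel_size)
  }
  meta <- list(
    bands = data.frame(index = bs$index, name = bs$name,
                       center_nm = bs$center_nm),
    ms_pixel_size = attr(bs, "ms_pixel_size"),
    pan_pixel_size = attr(bs, "pan_pixel_size")
  )
  jsonlite::write_json(meta, paste0(stem, "_bands.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_raster
#' @export
read_ms_raster <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, "_bands.json"), simplifyVector = TRUE)
  bs <- band_set(meta$bands$name, meta$bands$center_nm,
                 ms_pixel_size = meta$ms_pixel_size,
                 pan_pixel_size = meta$pan_pixel_size)
  grids <- lapply(seq_len(nrow(bs)), function(b)
    read_asc(sprintf("%s_b%02d.asc", stem, b)))
  vals <- array(NA_real_, c(dim(grids[[1]]$values), nrow(bs)))
  for (b in seq_along(grids)) vals[, , b] <- grids[[b]]$values
  g <- grids[[1]]
  ms_raster(vals, bs, origin_x = g$origin_x, origin_y = g$origin_y,
            pixel_size = g$pixel_size)
}

#' @rdname write_raster
#' @export
read_pan_raster <- function(stem) {
  g <- read_asc(paste0(stem, ".asc"))
  pan_raster(g$values, origin_x = g$origin_x, origin_y = g$origin_y,
             pixel_size = g$pixel_size)
}
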
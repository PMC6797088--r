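#' Normalized Difference Water Index
#'
#' Computes `NDWI = (green - nir) / (green + nir)` per pixel. Water is
#' strongly positive (high green, very low NIR radiance), land negative.
#' Cells where both bands are zero, and nodata cells, are `NA`.
#'
#' @param ms an [ms_raster()].
#' @param green_band,nir_band band indices; defaults 3 (green, 546 nm) and
#'   7 (NIR1, 833 nm) on the [wv2_band_set()] layout.
#' @return A numeric matrix of values in `[-1, 1]` (with `NA`s).
#' @export
compute_ndwi <- function(ms, green_band = 3L, nir_band = 7L) {
  stopifnot(inherits(ms, "ms_raster"))
  nb <- dim(ms$values)[3]
  if (green_band < 1 || green_band > nb || nir_band < 1 || nir_band > nb)
    stop("band index out of range")
  if (green_band == nir_band)
    stop("green and NIR band indices must differ")
  g <- ms$values[, , green_band]
  n <- ms$values[, , nir_band]
  den <- g + n
  out <- (g - n) / den
  out[den == 0] <- NA_real_
  out
}

#' Threshold an NDWI raster into a water mask
#'
#' @param ndwi a matrix from [compute_ndwi()].
#' @param threshold NDWI cutoff in `(-1, 1)`; a pixel is water iff
#'   `ndwi > threshold` (default 0, the standard zero crossing).
#' @return An object of class `water_mask`: a logical matrix (`NA` where the
#'   index is undefined) with attribute `ndwi_threshold`.
#' @export
extract_water_mask <- function(ndwi, threshold = 0) {
  stopifnot(is.matrix(ndwi), threshold > -1, threshold < 1)
  if (all(is.na(ndwi))) stop("all-nodata NDWI input")
  w <- ndwi > threshold
  attr(w, "ndwi_threshold") <- threshold
  class(w) <- c("water_mask", class(w))
  w
}

#' Metric buffer around the land-water boundary
#'
#' Boundary pixels are land pixels with at least one water pixel in their
#' 4-neighborhood. A pixel belongs to the buffer iff the Euclidean distance
#' from its center to the nearest boundary pixel center is at most
#' `distance_m`, optionally restricted to one side of the coastline
#' (`landward` keeps land pixels only, `seaward` water pixels only, `both`
#' keeps both, the default — stranded carcasses sit beached or partially
#' afloat on either side of the waterline).
#'
#' The distance field is an exact Euclidean distance transform
#' (`EBImage::distmap`) with the boundary pixels as sources.
#'
#' @param mask a [extract_water_mask()] result (`TRUE` = water); `NA` cells
#'   are treated as land for boundary finding and excluded from the buffer.
#' @param distance_m buffer distance in meters (default 5, the coastal strip
#'   the detector is restricted to).
#' @param pixel_size_m pixel size of the mask's grid in meters.
#' @param side one of `"both"`, `"landward"`, `"seaward"`.
#' @return An object of class `coastal_buffer`: a logical matrix with
#'   attributes `distance_m`, `side`. If the mask is all water or all land
#'   the buffer is empty and a warning is issued.
#' @export
build_coastal_buffer <- function(mask, distance_m = 5, pixel_size_m,
                                 side = c("both", "landward", "seaward")) {
  side <- match.arg(side)
  stopifnot(is.matrix(mask), distance_m >= 0, pixel_size_m > 0)
  water <- mask
  water[is.na(water)] <- FALSE
  rows <- nrow(water); cols <- ncol(water)
  land <- !water
  nbw <- matrix(FALSE, rows, cols)
  if (rows > 1L) {
    nbw[-1, ] <- nbw[-1, ] | water[-rows, ]
    nbw[-rows, ] <- nbw[-rows, ] | water[-1, ]
  }
  if (cols > 1L) {
    nbw[, -1] <- nbw[, -1] | water[, -cols]
    nbw[, -cols] <- nbw[, -cols] | water[, -1]
  }
  boundary <- land & nbw
  if (!any(boundary)) {
    warning("mask has no land-water boundary; buffer is empty")
    buf <- matrix(FALSE, rows, cols)
  } else {
    src <- matrix(1, rows, cols)
    src[boundary] <- 0
    d <- as.matrix(EBImage::distmap(src, metric = "euclidean"))
    buf <- d * pixel_size_m <= distance_m + 1e-9
  }
  if (side == "landward") buf <- buf & !water
  if (side == "seaward") buf <- buf & water
  buf[is.na(mask)] <- FALSE
  attr(buf, "distance_m") <- distance_m
  attr(buf, "side") <- side
  class(buf) <- c("coastal_buffer", class(buf))
  buf
}

#' Write a boolean mask as an ESRI ASCII grid (0/1)
#'
#' @param mask logical matrix (water mask or coastal buffer).
#' @param path output `.asc` path.
#' @param origin_x,origin_y,pixel_size geotransform of the mask's grid.
#' @return The path, invisibly.
#' @export
write_mask <- function(mask, path, origin_x = 0, origin_y = NULL,
                       pixel_size = 2) {
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  if (is.null(origin_y)) origin_y <- nrow(m) * pixel_size
  write_asc(m, path, origin_x, origin_y, pixel_size)
}
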
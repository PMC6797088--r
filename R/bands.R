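#' Multispectral band definition
#'
#' A `band_set` records the spectral bands of a sensor (index, name, center
#' wavelength) together with the multispectral and panchromatic ground sample
#' distances. Center wavelengths must be strictly increasing and the
#' multispectral pixel size must be an integer multiple of the panchromatic
#' pixel size.
#'
#' @param names character vector of band names.
#' @param centers_nm numeric vector of band center wavelengths in nanometers,
#'   strictly increasing, same length as `names`.
#' @param ms_pixel_size multispectral pixel size in meters.
#' @param pan_pixel_size panchromatic pixel size in meters; `ms_pixel_size`
#'   must be an integer multiple of it.
#' @return An object of class `band_set`: a data frame with columns `index`,
#'   `name`, `center_nm`, and attributes `ms_pixel_size`, `pan_pixel_size`.
#' @seealso [wv2_band_set()] for the default 8-band layout.
#' @export
band_set <- function(names, centers_nm, ms_pixel_size = 2, pan_pixel_size = 0.5) {
  if (length(names) != length(centers_nm))
    stop("'names' and 'centers_nm' must have the same length")
  if (length(centers_nm) < 1L) stop("at least one band is required")
  if (any(diff(centers_nm) <= 0))
    stop("band center wavelengths must be strictly increasing")
  if (!(ms_pixel_size > 0 && pan_pixel_size > 0))
    stop("pixel sizes must be positive")
  k <- ms_pixel_size / pan_pixel_size
  if (abs(k - round(k)) > 1e-9 || round(k) < 1)
    stop("ms_pixel_size must be an integer multiple (>= 1) of pan_pixel_size")
  bs <- data.frame(index = seq_along(names), name = as.character(names),
                   center_nm = as.numeric(centers_nm),
                   stringsAsFactors = FALSE)
  attr(bs, "ms_pixel_size") <- ms_pixel_size
  attr(bs, "pan_pixel_size") <- pan_pixel_size
  class(bs) <- c("band_set", "data.frame")
  bs
}

#' Default WorldView2-like band set
#'
#' Eight bands at 2 m with a 0.5 m panchromatic band. Band centers follow the
#' WorldView2 layout (coastal through NIR2); band 7 (NIR1) sits at 833 nm, the
#' near-infrared band in which decomposing carcasses show a reflectance peak.
#'
#' @param ms_pixel_size multispectral pixel size in meters (default 2).
#' @param pan_pixel_size panchromatic pixel size in meters (default 0.5).
#'   Use 1.24/0.31 for a WorldView3-like resolution preset.
#' @return A [band_set()] with 8 bands.
#' @export
wv2_band_set <- function(ms_pixel_size = 2, pan_pixel_size = 0.5) {
  band_set(
    names = c("coastal", "blue", "green", "yellow",
              "red", "rededge", "nir1", "nir2"),
    centers_nm = c(427, 478, 546, 608, 659, 724, 833, 949),
    ms_pixel_size = ms_pixel_size,
    pan_pixel_size = pan_pixel_size
  )
}

#' @export
print.band_set <- function(x, ...) {
  cat(sprintf("<band_set> %d bands, MS %g m / pan %g m\n",
              nrow(x), attr(x, "ms_pixel_size"), attr(x, "pan_pixel_size")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

resolution_ratio <- function(bs) {
  as.integer(round(attr(bs, "ms_pixel_size") / attr(bs, "pan_pixel_size")))
}
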
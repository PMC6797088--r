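#' Built-in spectral library for synthetic coastal scenes
#'
#' Per-band mean top-of-atmosphere radiance (dimensionless, on a 0-80 scale)
#' for the surface classes used by the scene generator, on the default
#' 8-band layout of [wv2_band_set()].
#'
#' Whale carcasses are modeled as a mixture of four decay states
#' (`whale_dark`, `whale_pink`, `whale_orange`, `whale_bleached`). All four
#' share the diagnostic shape of a decomposing carcass: radiance rising from
#' the blue through the red into the near infrared, peaking in NIR1
#' (band 7, 833 nm) and dipping in NIR2. Logs and wave foam have comparable
#' shapes and sizes in imagery but low red/NIR radiance relative to the
#' visible, which is the separability the detector exploits; sand is bright
#' and spectrally flat, and is the closest confounder to a bleached carcass.
#'
#' @return A named list of numeric length-8 radiance vectors with an
#'   attribute `whale_states` naming the carcass classes.
#' @export
spectral_library <- function() {
  lib <- list(
    water          = c(32, 30, 26, 18, 12,  8,  4,  3),
    sand           = c(48, 50, 52, 53, 53, 52, 51, 49),
    vegetation     = c(10, 11, 16, 14, 11, 28, 48, 42),
    rock           = c(22, 22, 23, 23, 23, 23, 23, 22),
    log            = c(14, 15, 17, 19, 20, 19, 17, 15),
    wave           = c(55, 56, 54, 48, 40, 28, 16, 11),
    cloud          = c(66, 67, 67, 66, 65, 63, 61, 59),
    whale_dark     = c( 8,  9, 11, 13, 15, 16, 19, 15),
    whale_pink     = c(22, 25, 31, 39, 47, 50, 56, 46),
    whale_orange   = c(18, 22, 30, 42, 52, 55, 60, 49),
    whale_bleached = c(33, 38, 46, 53, 60, 63, 70, 58)
  )
  attr(lib, "whale_states") <-
    c("whale_dark", "whale_pink", "whale_orange", "whale_bleached")
  lib
}
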
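#' Extract a spectral signature from chosen pixels
#'
#' Computes per-band mean, min, max and standard deviation of radiance over
#' an explicitly chosen pixel set — the way reference profiles are taken
#' from the un-shadowed center pixels of known carcasses. The per-band mean
#' vector is the end member used by [sam_classify()]; min/max/sd describe
#' the spread and are reported but not used in classification.
#'
#' @param raster an [ms_raster()].
#' @param pixels two-column matrix or data frame of (row, col) indices.
#' @param label signature name.
#' @param role `"target"` (spectra to find) or `"exclusion"` (spectra to
#'   reject, e.g. cloud).
#' @return An object of class `spectral_signature`: list with `label`,
#'   `role`, `stats` (data frame: band, mean, min, max, sd), `n_pixels`,
#'   `pixels`.
#' @export
extract_signature <- function(raster, pixels, label,
                              role = c("target", "exclusion")) {
  role <- match.arg(role)
  stopifnot(inherits(raster, "ms_raster"))
  pixels <- as.matrix(pixels)[, 1:2, drop = FALSE]
  if (nrow(pixels) < 1L) stop("at least one pixel is required")
  nb <- dim(raster$values)[3]
  spectra <- vapply(seq_len(nb),
                    function(b) raster$values[, , b][pixels], # n x 1 per band
                    numeric(nrow(pixels)))
  spectra <- matrix(spectra, nrow = nrow(pixels), ncol = nb)
  ok <- stats::complete.cases(spectra)
  if (!any(ok)) stop("all chosen pixels are nodata")
  spectra <- spectra[ok, , drop = FALSE]
  st <- data.frame(
    band = seq_len(nb),
    mean = colMeans(spectra),
    min = apply(spectra, 2, min),
    max = apply(spectra, 2, max),
    sd = if (nrow(spectra) > 1L) apply(spectra, 2, stats::sd) else rep(0, nb)
  )
  sig <- list(label = label, role = role, stats = st,
              n_pixels = nrow(spectra), pixels = pixels[ok, , drop = FALSE])
  class(sig) <- "spectral_signature"
  sig
}

#' @export
print.spectral_signature <- function(x, ...) {
  cat(sprintf("<spectral_signature> '%s' (%s), %d pixels\n",
              x$label, x$role, x$n_pixels))
  print(round(x$stats, 3), row.names = FALSE)
  invisible(x)
}

#' Extract whale target signatures from ground truth
#'
#' Convenience wrapper emulating the manual training step: for up to
#' `n_per_state` truth whales of each decay state, extract a target
#' signature from the whale's footprint pixels.
#'
#' @param ms an [ms_raster()].
#' @param truth a `truth_set` from [generate_scene()].
#' @param n_per_state training whales per decay state (default 1).
#' @return List of `spectral_signature` objects with role `"target"`.
#' @export
signatures_from_truth <- function(ms, truth, n_per_state = 1L) {
  whales <- which(truth$class == "whale")
  if (!length(whales)) stop("truth contains no whales to train on")
  fps <- attr(truth, "footprints")
  sigs <- list()
  for (st in unique(truth$state[whales])) {
    idx <- whales[truth$state[whales] == st]
    for (i in utils::head(idx, n_per_state)) {
      sigs[[length(sigs) + 1L]] <- extract_signature(
        ms, fps[[i]], label = sprintf("%s_w%d", st, truth$id[i]),
        role = "target")
    }
  }
  sigs
}

#' Spectral angle between two spectra
#'
#' `theta = arccos( <a, b> / (|a| |b|) )`, in radians. The angle depends
#' only on the shape of the spectra, not their magnitude, so differences in
#' total illumination do not affect it: it is zero exactly when one spectrum
#' is a positive scalar multiple of the other.
#'
#' @param a,b numeric vectors of equal length with nonzero norm.
#' @return Angle in radians, in `[0, pi]`.
#' @export
spectral_angle <- function(a, b) {
  if (length(a) != length(b)) stop("spectra must have the same length")
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) stop("zero-norm spectrum")
  acos(pmin(1, pmax(-1, sum(a * b) / (na * nb))))
}

#' Map a spectral angle to a 0-100 likelihood score
#'
#' The linear map `L = 100 * (1 - theta / theta_max)`, clipped to
#' `[0, 100]`: 100 at a perfect match, 0 at or beyond the angle threshold,
#' strictly decreasing in between. The underlying commercial tool reports a
#' 1-100 likelihood without defining it; this linear map is the simplest
#' monotone choice and is non-canonical.
#'
#' @param angle_rad spectral angle(s) in radians.
#' @param theta_max maximum acceptable angle in radians.
#' @return Likelihood value(s) in `[0, 100]`.
#' @export
angle_to_likelihood <- function(angle_rad, theta_max) {
  stopifnot(theta_max > 0)
  pmin(pmax(100 * (1 - angle_rad / theta_max), 0), 100)
}

#' SAM classification parameters
#'
#' @param theta_max maximum spectral angle (radians) for a pixel to be a
#'   candidate; must be in `(0, pi/2]`. Default 0.10 rad.
#' @param likelihood_thresholds ascending likelihood strata in `[0, 100]`
#'   used by reporting (default 0/40/65).
#' @return An object of class `sam_params`.
#' @export
sam_params <- function(theta_max = 0.10,
                       likelihood_thresholds = c(0, 40, 65)) {
  stopifnot(theta_max > 0, theta_max <= pi / 2,
            all(likelihood_thresholds >= 0),
            all(likelihood_thresholds <= 100),
            !is.unsorted(likelihood_thresholds, strictly = TRUE))
  p <- list(theta_max = theta_max,
            likelihood_thresholds = likelihood_thresholds)
  class(p) <- "sam_params"
  p
}

#' Spectral Angle Mapper target detection
#'
#' Scores every pixel of a multispectral raster against a set of target
#' end members (per-band signature means) and flags candidates. A pixel is
#' a candidate iff
#' * it lies inside `mask` (when a mask is given),
#' * its minimum spectral angle over the target signatures is at most
#'   `params$theta_max`, and
#' * that angle is strictly smaller than its minimum angle to every
#'   exclusion signature (so e.g. cloud pixels highlighted as an extra
#'   signature are removed from the result).
#'
#' Nodata pixels are never candidates. Each candidate carries the label of
#' its best-matching target, the angle, and the linear 0-100 likelihood of
#' [angle_to_likelihood()].
#'
#' @param raster an [ms_raster()].
#' @param signatures list of [extract_signature()] objects; at least one
#'   must have role `"target"`.
#' @param params a [sam_params()].
#' @param mask optional logical matrix (e.g. a [build_coastal_buffer()])
#'   restricting the search.
#' @return An object of class `candidate_pixels`: a data frame with columns
#'   `row`, `col`, `easting`, `northing`, `label`, `angle_rad`,
#'   `likelihood`, ordered by decreasing likelihood, with the source grid
#'   recorded in attribute `grid`.
#' @export
sam_classify <- function(raster, signatures, params = sam_params(),
                         mask = NULL) {
  stopifnot(inherits(raster, "ms_raster"), inherits(params, "sam_params"))
  roles <- vapply(signatures, function(s) s$role, "")
  targets <- signatures[roles == "target"]
  exclusions <- signatures[roles == "exclusion"]
  if (!length(targets)) stop("at least one target signature is required")
  nb <- dim(raster$values)[3]
  for (s in signatures)
    if (nrow(s$stats) != nb)
      stop(sprintf("signature '%s' has %d bands but the raster has %d",
                   s$label, nrow(s$stats), nb))
  d <- dim(raster$values)
  X <- matrix(raster$values, d[1] * d[2], nb)
  keep <- stats::complete.cases(X) & rowSums(X * X) > 0
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == d[1:2]))
    keep <- keep & as.vector(mask) %in% TRUE
  }
  idx <- which(keep)
  empty <- function() {
    out <- data.frame(row = integer(), col = integer(), easting = numeric(),
                      northing = numeric(), label = character(),
                      angle_rad = numeric(), likelihood = numeric())
    attr(out, "grid") <- list(rows = d[1], cols = d[2],
                              pixel_size = raster$pixel_size,
                              origin_x = raster$origin_x,
                              origin_y = raster$origin_y,
                              theta_max = params$theta_max)
    class(out) <- c("candidate_pixels", "data.frame")
    out
  }
  if (!length(idx)) return(empty())
  Xn <- X[idx, , drop = FALSE]
  Xn <- Xn / sqrt(rowSums(Xn * Xn))
  ang_to <- function(sigs) {
    M <- vapply(sigs, function(s) {
      m <- s$stats$mean
      m / sqrt(sum(m * m))
    }, numeric(nb))
    A <- Xn %*% M
    A[] <- acos(pmin(1, pmax(-1, A)))   # [] keeps the matrix shape
    A
  }
  ta <- ang_to(targets)
  best <- max.col(-ta, ties.method = "first")
  best_ang <- ta[cbind(seq_along(idx), best)]
  ok <- best_ang <= params$theta_max
  if (length(exclusions)) {
    ea <- ang_to(exclusions)
    min_ex <- do.call(pmin, lapply(seq_along(exclusions),
                                   function(j) ea[, j, drop = TRUE]))
    ok <- ok & (best_ang < min_ex)
  }
  sel <- which(ok)
  if (!length(sel)) return(empty())
  pix <- idx[sel]
  row <- ((pix - 1L) %% d[1]) + 1L
  col <- ((pix - 1L) %/% d[1]) + 1L
  ctr <- pixel_centers(raster, row, col)
  labels <- vapply(targets, function(s) s$label, "")
  out <- data.frame(row = row, col = col,
                    easting = ctr$easting, northing = ctr$northing,
                    label = labels[best[sel]],
                    angle_rad = best_ang[sel],
                    likelihood = angle_to_likelihood(best_ang[sel],
                                                     params$theta_max))
  out <- out[order(-out$likelihood, out$row, out$col), ]
  rownames(out) <- NULL
  attr(out, "grid") <- list(rows = d[1], cols = d[2],
                            pixel_size = raster$pixel_size,
                            origin_x = raster$origin_x,
                            origin_y = raster$origin_y,
                            theta_max = params$theta_max)
  class(out) <- c("candidate_pixels", "data.frame")
  out
}

#' @export
print.candidate_pixels <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("<candidate_pixels> %d pixels on a %d x %d grid (theta_max %.3g rad)\n",
              nrow(x), g$rows, g$cols, g$theta_max))
  if (nrow(x)) {
    cat(sprintf("  likelihood >= 40: %d, >= 65: %d\n",
                sum(x$likelihood >= 40), sum(x$likelihood >= 65)))
    print(utils::head(as.data.frame(x), 5), row.names = FALSE)
  }
  invisible(x)
}

#' Read and write spectral signatures as CSV
#'
#' Wide CSV with one row per signature: `label, role, n_pixels,
#' band_1_mean, ..., band_K_mean, band_1_min, ...` through the four
#' statistics.
#'
#' @param signatures list of `spectral_signature` objects.
#' @param path CSV path.
#' @return `write_signatures` the path invisibly; `read_signatures` a list
#'   of `spectral_signature` objects (without source pixel coordinates).
#' @export
write_signatures <- function(signatures, path) {
  rows <- lapply(signatures, function(s) {
    st <- s$stats
    v <- c(st$mean, st$min, st$max, st$sd)
    names(v) <- c(sprintf("band_%d_mean", st$band),
                  sprintf("band_%d_min", st$band),
                  sprintf("band_%d_max", st$band),
                  sprintf("band_%d_sd", st$band))
    cbind(data.frame(label = s$label, role = s$role, n_pixels = s$n_pixels),
          as.data.frame(as.list(v)))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signatures
#' @export
read_signatures <- function(path) {
  df <- utils::read.csv(path, colClasses = c(label = "character",
                                             role = "character"))
  nbands <- sum(grepl("^band_[0-9]+_mean$", names(df)))
  lapply(seq_len(nrow(df)), function(i) {
    st <- data.frame(
      band = seq_len(nbands),
      mean = as.numeric(df[i, sprintf("band_%d_mean", seq_len(nbands))]),
      min = as.numeric(df[i, sprintf("band_%d_min", seq_len(nbands))]),
      max = as.numeric(df[i, sprintf("band_%d_max", seq_len(nbands))]),
      sd = as.numeric(df[i, sprintf("band_%d_sd", seq_len(nbands))])
    )
    sig <- list(label = df$label[i], role = df$role[i], stats = st,
                n_pixels = df$n_pixels[i], pixels = NULL)
    class(sig) <- "spectral_signature"
    sig
  })
}

#' Write candidate pixels as CSV and GeoJSON points
#'
#' @param candidates a `candidate_pixels` data frame.
#' @param stem output path stem; writes `<stem>.csv` and `<stem>.geojson`.
#' @return The stem, invisibly.
#' @export
write_candidates <- function(candidates, stem) {
  utils::write.csv(as.data.frame(candidates), paste0(stem, ".csv"),
                   row.names = FALSE)
  feats <- lapply(seq_len(nrow(candidates)), function(i) list(
    type = "Feature",
    geometry = list(type = "Point",
                    coordinates = c(candidates$easting[i],
                                    candidates$northing[i])),
    properties = list(row = candidates$row[i], col = candidates$col[i],
                      label = candidates$label[i],
                      angle_rad = candidates$angle_rad[i],
                      likelihood = candidates$likelihood[i])))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       paste0(stem, ".geojson"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}
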
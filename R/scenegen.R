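#' Configuration for the synthetic coastal scene generator
#'
#' Describes one simulated coastal VHR acquisition: extent, band layout,
#' geotransform, how many whale carcasses and confounders to place, their
#' spectral model, and noise levels. The defaults emulate the conditions the
#' detection procedure assumes: 8 WorldView2-like bands at 2 m with a 0.5 m
#' panchromatic band, carcasses 7-20 m long and cigar-shaped lying on the
#' land-water boundary, a decay-state mixture with wide within-carcass
#' heterogeneity, and log/wave confounders whose spectra have low red/NIR
#' radiance relative to carcasses.
#'
#' @param rows,cols scene extent in multispectral pixels.
#' @param n_whales number of whale carcasses to place along the coastline.
#' @param whale_length_range carcass length range in meters (default 7-20).
#' @param whale_aspect_range carcass length:width aspect range (default 3-6).
#' @param decay_weights named mixture weights over the decay states of
#'   [spectral_library()] (dark, pink, orange, bleached).
#' @param within_cv within-carcass spectral heterogeneity: per-band
#'   multiplicative noise with standard deviation `within_cv * band mean`.
#' @param background_cv multiplicative texture of background classes.
#' @param noise_sd additive sensor noise standard deviation (radiance units),
#'   applied per band and to the panchromatic raster.
#' @param n_logs,n_waves,n_clouds confounder counts: stranded logs on the
#'   coastline, wave/foam streaks in open water, cloud patches.
#' @param allow_overlap if `TRUE`, whale footprints may touch or overlap
#'   (emulating crowded strandings); by default footprints are kept at least
#'   one pixel apart.
#' @param water_frac approximate fraction of scene width that is open water.
#' @param sand_width_px width of the sandy beach strip in MS pixels.
#' @param min_separation_m minimum distance between whale centroids when
#'   `allow_overlap = FALSE`.
#' @param band_set a [band_set()]; default [wv2_band_set()].
#' @param origin_x,origin_y projected coordinates of the top-left corner.
#' @param radiance_scale maximum expected radiance (dimensionless TOA scale).
#' @param pan_weights per-band weights used to synthesize the panchromatic
#'   signal (bands outside the pan passband get weight 0); normalized to
#'   sum 1 internally.
#' @param spectra spectral library, as from [spectral_library()].
#' @param seed integer seed making the scene reproducible.
#' @return An object of class `scene_config` (a validated list).
#' @export
scene_config <- function(rows = 256, cols = 256, n_whales = 20,
                         whale_length_range = c(7, 20),
                         whale_aspect_range = c(3, 6),
                         decay_weights = c(whale_dark = 0.15, whale_pink = 0.35,
                                           whale_orange = 0.30,
                                           whale_bleached = 0.20),
                         within_cv = 0.05, background_cv = 0.03,
                         noise_sd = 0.5,
                         n_logs = 5, n_waves = 5, n_clouds = 0,
                         allow_overlap = FALSE,
                         water_frac = 0.35, sand_width_px = 3,
                         min_separation_m = 20,
                         band_set = wv2_band_set(),
                         origin_x = 0, origin_y = NULL,
                         radiance_scale = 80,
                         pan_weights = c(0.05, 0.15, 0.2, 0.2, 0.2, 0.15, 0.05, 0),
                         spectra = spectral_library(),
                         seed = 1L) {
  stopifnot(rows >= 8, cols >= 8, n_whales >= 0,
            length(whale_length_range) == 2,
            whale_length_range[1] > 0,
            whale_length_range[1] < whale_length_range[2],
            whale_aspect_range[1] >= 1,
            whale_aspect_range[1] <= whale_aspect_range[2],
            within_cv >= 0, noise_sd >= 0,
            n_logs >= 0, n_waves >= 0, n_clouds >= 0,
            water_frac > 0, water_frac < 1,
            radiance_scale > 0,
            length(pan_weights) == nrow(band_set),
            all(pan_weights >= 0), sum(pan_weights) > 0)
  if (any(vapply(spectra, function(s) any(s < 0), TRUE)))
    stop("all spectral means must be non-negative")
  states <- attr(spectra, "whale_states")
  if (!all(names(decay_weights) %in% states))
    stop("decay_weights must be named after the library's whale states")
  cfg <- as.list(environment())
  cfg$pan_weights <- pan_weights / sum(pan_weights)
  if (is.null(cfg$origin_y))
    cfg$origin_y <- rows * attr(band_set, "ms_pixel_size")
  class(cfg) <- "scene_config"
  cfg
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf(paste0("<scene_config> %d x %d MS pixels (%g m), %d whales, ",
                     "%d logs / %d waves / %d clouds, seed %d\n"),
              x$rows, x$cols, attr(x$band_set, "ms_pixel_size"), x$n_whales,
              x$n_logs, x$n_waves, x$n_clouds, x$seed))
  invisible(x)
}

# pixels (row, col) whose centers fall inside a rotated ellipse given in
# MS-pixel units; theta in radians, measured from the column (easting) axis
ellipse_footprint <- function(center_r, center_c, a_px, b_px, theta,
                              rows, cols) {
  half <- ceiling(a_px) + 1L
  rr <- max(1L, floor(center_r - half)):min(rows, ceiling(center_r + half))
  cc <- max(1L, floor(center_c - half)):min(cols, ceiling(center_c + half))
  if (!length(rr) || !length(cc)) return(matrix(integer(), 0, 2))
  g <- expand.grid(row = rr, col = cc)
  dx <- g$col - center_c
  dy <- g$row - center_r
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  keep <- (u / a_px)^2 + (v / b_px)^2 <= 1
  as.matrix(g[keep, c("row", "col"), drop = FALSE])
}

# principal-axis extent of a pixel set, in meters; single pixel -> pixel size
measure_pixel_set <- function(px, pixel_size) {
  n <- nrow(px)
  if (n == 0L) stop("empty pixel set")
  if (n == 1L)
    return(list(length_m = pixel_size, width_m = pixel_size,
                orientation_deg = 0))
  xy <- cbind(px[, 2], -px[, 1]) * pixel_size   # easting-like, northing-like
  cv <- stats::cov(xy)
  eg <- eigen(cv, symmetric = TRUE)
  p1 <- xy %*% eg$vectors[, 1]
  p2 <- xy %*% eg$vectors[, 2]
  list(length_m = diff(range(p1)) + pixel_size,
       width_m = diff(range(p2)) + pixel_size,
       orientation_deg = (atan2(eg$vectors[2, 1], eg$vectors[1, 1]) * 180 / pi) %% 180)
}

# local coastline direction at a boundary pixel (radians, column-axis origin)
local_tangent <- function(boundary, r, c, radius = 5) {
  nb <- boundary[abs(boundary[, 1] - r) <= radius &
                 abs(boundary[, 2] - c) <= radius, , drop = FALSE]
  if (nrow(nb) < 3L) return(pi / 2)
  cv <- stats::cov(cbind(nb[, 2], nb[, 1]))
  eg <- eigen(cv, symmetric = TRUE)
  atan2(eg$vectors[2, 1], eg$vectors[1, 1])
}

#' Generate a synthetic coastal scene with ground truth
#'
#' Renders one annotated scene: a multispectral raster at the MS pixel size,
#' a panchromatic raster at the finer pan pixel size covering the same
#' extent, and a truth set recording every placed object (whales and
#' confounders) with footprint, centroid, length and orientation.
#'
#' The scene has open water on the west, a sinuous coastline, a sandy beach
#' strip, vegetated land with rock patches. Whale carcasses are rotated
#' ellipses placed on the land-water boundary, oriented along the local
#' coastline; each carcass draws a decay state from the configured mixture
#' and per-pixel multiplicative heterogeneity. The panchromatic raster is
#' the band-weighted MS brightness bilinearly upsampled to the pan grid plus
#' sensor noise. The whole simulation is driven by `config$seed`: identical
#' configurations produce bit-identical outputs.
#'
#' @param config a [scene_config()].
#' @return A list with elements `ms` ([ms_raster()]), `pan` ([pan_raster()])
#'   and `truth` (a `truth_set`: data frame of objects with a `footprints`
#'   attribute holding each object's MS pixel set).
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(config$seed)
  rows <- config$rows; cols <- config$cols
  bs <- config$band_set
  px <- attr(bs, "ms_pixel_size")
  k <- resolution_ratio(bs)
  nb <- nrow(bs)
  lib <- config$spectra
  states <- attr(lib, "whale_states")

  # --- coastline and background classes --------------------------------
  base_col <- config$water_frac * cols
  # three incommensurate harmonics give an in-folded, fjord-like coastline
  # with enough boundary length to host the configured object counts
  a1 <- 0.10 * cols; a2 <- 0.05 * cols; a3 <- 0.02 * cols
  p1 <- stats::runif(1, 0, 2 * pi); p2 <- stats::runif(1, 0, 2 * pi)
  p3 <- stats::runif(1, 0, 2 * pi)
  rr <- seq_len(rows)
  coast <- base_col + a1 * sin(2 * pi * rr / rows + p1) +
    a2 * sin(2 * pi * rr * 3.7 / rows + p2) +
    a3 * sin(2 * pi * rr * 9.1 / rows + p3)
  coast <- pmin(pmax(coast, 3), cols - 3)
  colg <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  coastg <- matrix(coast, rows, cols)
  class_map <- matrix("water", rows, cols)
  land <- colg > coastg
  class_map[land & (colg - coastg <= config$sand_width_px)] <- "sand"
  class_map[land & (colg - coastg > config$sand_width_px)] <- "vegetation"
  # a few rock patches inland
  n_rock <- 3L
  for (i in seq_len(n_rock)) {
    rc <- c(stats::runif(1, 1, rows), stats::runif(1, base_col, cols))
    fp <- ellipse_footprint(rc[1], rc[2], stats::runif(1, 3, 7),
                            stats::runif(1, 2, 5),
                            stats::runif(1, 0, pi), rows, cols)
    fp <- fp[class_map[fp] == "vegetation", , drop = FALSE]
    class_map[fp] <- "rock"
  }

  # --- land-water boundary (for object placement) ----------------------
  boundary_px <- function(cm) {
    w <- cm == "water"
    l <- !w
    nbw <- matrix(FALSE, rows, cols)
    nbw[-1, ] <- nbw[-1, ] | w[-rows, ]
    nbw[-rows, ] <- nbw[-rows, ] | w[-1, ]
    nbw[, -1] <- nbw[, -1] | w[, -cols]
    nbw[, -cols] <- nbw[, -cols] | w[, -1]
    which(l & nbw, arr.ind = TRUE)
  }
  boundary <- boundary_px(class_map)

  # --- object placement -------------------------------------------------
  occupied <- matrix(FALSE, rows, cols)   # footprints dilated by one pixel
  mark <- function(fp) {
    for (dr in -1:1) for (dc in -1:1) {
      r2 <- pmin(pmax(fp[, 1] + dr, 1L), rows)
      c2 <- pmin(pmax(fp[, 2] + dc, 1L), cols)
      occupied[cbind(r2, c2)] <<- TRUE
    }
  }
  objects <- list()
  add_object <- function(class, state, fp) {
    m <- measure_pixel_set(fp, px)
    ctr <- c(config$origin_x + (mean(fp[, 2]) - 0.5) * px,
             config$origin_y - (mean(fp[, 1]) - 0.5) * px)
    objects[[length(objects) + 1L]] <<- list(
      id = length(objects) + 1L, class = class, state = state,
      easting = ctr[1], northing = ctr[2],
      length_m = m$length_m, width_m = m$width_m,
      orientation_deg = m$orientation_deg,
      n_pixels = nrow(fp), footprint = fp)
  }

  place_elongated <- function(class, n, length_range_m, aspect_range,
                              sep_m, near_coast = TRUE, state_fun = NULL) {
    if (n == 0L) return(invisible())
    if (near_coast && nrow(boundary) < n)
      stop("scene extent too small: not enough coastline to place objects")
    centers <- matrix(numeric(), 0, 2)
    placed <- 0L
    attempts <- 0L
    max_attempts <- 400L * n
    while (placed < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop(sprintf("placement failure: placed %d of %d '%s' objects; %s",
                     placed, n, class,
                     "increase the extent or reduce object counts/separation"))
      if (near_coast) {
        bi <- boundary[sample.int(nrow(boundary), 1L), ]
        ctr <- bi + stats::runif(2, -0.5, 0.5)
        theta <- local_tangent(boundary, bi[1], bi[2]) +
          stats::rnorm(1, 0, 10 * pi / 180)
      } else {
        ctr <- c(stats::runif(1, 1, rows), stats::runif(1, 1, coast[1] - 3))
        # waves sit in open water, roughly shore-parallel
        ri <- round(pmin(pmax(ctr[1], 1), rows))
        ctr[2] <- stats::runif(1, 2, max(3, coast[ri] - 5))
        theta <- local_tangent(boundary, ctr[1], ctr[2], radius = 15) +
          stats::rnorm(1, 0, 15 * pi / 180)
      }
      if (!config$allow_overlap && nrow(centers) > 0 &&
          any((centers[, 1] - ctr[1])^2 + (centers[, 2] - ctr[2])^2 <
              (sep_m / px)^2)) next
      L <- stats::runif(1, length_range_m[1], length_range_m[2])
      asp <- stats::runif(1, aspect_range[1], aspect_range[2])
      a <- L / 2 / px
      b <- max(a / asp, 0.35)
      fp <- ellipse_footprint(ctr[1], ctr[2], a, b, theta, rows, cols)
      if (nrow(fp) < 2L) next
      if (any(occupied[fp])) next
      if (class == "whale") {
        realized <- measure_pixel_set(fp, px)$length_m
        if (realized < length_range_m[1] || realized > length_range_m[2]) next
      }
      state <- if (is.null(state_fun)) NA_character_ else state_fun()
      add_object(class, state, fp)
      if (!config$allow_overlap) mark(fp)
      centers <- rbind(centers, ctr)
      placed <- placed + 1L
    }
    invisible()
  }

  wts <- config$decay_weights[states[states %in% names(config$decay_weights)]]
  place_elongated("whale", config$n_whales, config$whale_length_range,
                  config$whale_aspect_range, config$min_separation_m,
                  near_coast = TRUE,
                  state_fun = function()
                    sample(names(wts), 1L, prob = as.numeric(wts)))
  place_elongated("log", config$n_logs, c(8, 15), c(8, 12),
                  sep_m = 10, near_coast = TRUE)
  place_elongated("wave", config$n_waves, c(15, 40), c(8, 15),
                  sep_m = 10, near_coast = FALSE)
  if (config$n_clouds > 0) {
    for (i in seq_len(config$n_clouds)) {
      fp <- ellipse_footprint(stats::runif(1, 1, rows),
                              stats::runif(1, 1, cols),
                              stats::runif(1, 5, 12), stats::runif(1, 4, 9),
                              stats::runif(1, 0, pi), rows, cols)
      fp <- fp[!occupied[fp], , drop = FALSE]
      if (nrow(fp) >= 2L) { add_object("cloud", NA_character_, fp); mark(fp) }
    }
  }

  # --- render multispectral values --------------------------------------
  spec_name <- class_map
  cv_map <- matrix(config$background_cv, rows, cols)
  for (ob in objects) {
    spec_name[ob$footprint] <-
      if (ob$class == "whale") ob$state else ob$class
    cv_map[ob$footprint] <-
      if (ob$class == "whale") config$within_cv else config$background_cv
  }
  palette <- unique(as.vector(spec_name))
  idx <- matrix(match(spec_name, palette), rows, cols)
  vals <- array(NA_real_, c(rows, cols, nb))
  for (b in seq_len(nb)) {
    mean_b <- vapply(palette, function(p) lib[[p]][b], 0)[idx]
    layer <- mean_b * (1 + stats::rnorm(rows * cols, 0, as.vector(cv_map))) +
      stats::rnorm(rows * cols, 0, config$noise_sd)
    vals[, , b] <- pmax(matrix(layer, rows, cols), 0)
  }

  ms <- ms_raster(vals, bs, origin_x = config$origin_x,
                  origin_y = config$origin_y, pixel_size = px)

  # --- panchromatic raster ----------------------------------------------
  w <- config$pan_weights
  bright <- matrix(0, rows, cols)
  for (b in seq_len(nb)) bright <- bright + w[b] * vals[, , b]
  pan_vals <- bilinear_upsample(bright, k) +
    stats::rnorm(rows * k * cols * k, 0, config$noise_sd)
  pan <- pan_raster(pmax(pan_vals, 0), origin_x = config$origin_x,
                    origin_y = config$origin_y, pixel_size = px / k)

  truth <- truth_set(objects, rows = rows, cols = cols, pixel_size = px,
                     origin_x = config$origin_x, origin_y = config$origin_y)
  list(ms = ms, pan = pan, truth = truth)
}

truth_set <- function(objects, rows, cols, pixel_size, origin_x, origin_y) {
  if (length(objects) == 0L) {
    df <- data.frame(id = integer(), class = character(),
                     state = character(), easting = numeric(),
                     northing = numeric(), length_m = numeric(),
                     width_m = numeric(), orientation_deg = numeric(),
                     n_pixels = integer())
    fps <- list()
  } else {
    df <- do.call(rbind, lapply(objects, function(o)
      data.frame(id = o$id, class = o$class, state = o$state,
                 easting = o$easting, northing = o$northing,
                 length_m = o$length_m, width_m = o$width_m,
                 orientation_deg = o$orientation_deg,
                 n_pixels = o$n_pixels)))
    fps <- lapply(objects, function(o) {
      fp <- o$footprint
      dimnames(fp) <- list(NULL, c("row", "col"))
      fp
    })
  }
  attr(df, "footprints") <- fps
  attr(df, "grid") <- list(rows = rows, cols = cols, pixel_size = pixel_size,
                           origin_x = origin_x, origin_y = origin_y)
  class(df) <- c("truth_set", "data.frame")
  df
}

#' @export
print.truth_set <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("<truth_set> %d objects on a %d x %d grid (%g m pixels)\n",
              nrow(x), g$rows, g$cols, g$pixel_size))
  if (nrow(x)) print(table(x$class))
  invisible(x)
}

#' Write and read ground-truth annotations
#'
#' `write_truth` writes a truth set as GeoJSON points (`<stem>_points.geojson`,
#' centroid features with class attributes), GeoJSON polygons
#' (`<stem>_polygons.geojson`, convex-hull footprint outlines), a CSV summary
#' (`<stem>.csv`: id, class, easting, northing, length_m, ...) and a CSV of
#' footprint pixels (`<stem>_footprints.csv`: id, row, col). `read_truth`
#' reconstructs the truth set from those files; centroids round-trip to
#' better than 1e-6 m.
#'
#' @param truth a `truth_set` from [generate_scene()].
#' @param stem output path stem.
#' @return `write_truth` returns `stem` invisibly; `read_truth` a `truth_set`.
#' @export
write_truth <- function(truth, stem) {
  g <- attr(truth, "grid")
  fps <- attr(truth, "footprints")
  feat_pts <- lapply(seq_len(nrow(truth)), function(i) list(
    type = "Feature",
    geometry = list(type = "Point",
                    coordinates = c(truth$easting[i], truth$northing[i])),
    properties = list(id = truth$id[i], class = truth$class[i],
                      state = truth$state[i], length_m = truth$length_m[i],
                      width_m = truth$width_m[i],
                      orientation_deg = truth$orientation_deg[i],
                      n_pixels = truth$n_pixels[i])))
  fc <- list(type = "FeatureCollection", features = feat_pts)
  jsonlite::write_json(fc, paste0(stem, "_points.geojson"),
                       auto_unbox = TRUE, digits = NA)
  feat_poly <- lapply(seq_len(nrow(truth)), function(i) {
    fp <- fps[[i]]
    # corners of all member pixel squares
    e <- g$origin_x + c(fp[, 2] - 1, fp[, 2], fp[, 2] - 1, fp[, 2]) * g$pixel_size
    n <- g$origin_y - c(fp[, 1] - 1, fp[, 1] - 1, fp[, 1], fp[, 1]) * g$pixel_size
    h <- grDevices::chull(e, n)
    ring <- cbind(e[h], n[h])
    ring <- rbind(ring, ring[1, , drop = FALSE])
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(j) ring[j, ]))),
         properties = list(id = truth$id[i], class = truth$class[i]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feat_poly),
                       paste0(stem, "_polygons.geojson"),
                       auto_unbox = TRUE, digits = NA)
  df <- as.data.frame(truth)
  utils::write.csv(df, paste0(stem, ".csv"), row.names = FALSE)
  if (length(fps)) {
    fpdf <- do.call(rbind, lapply(seq_along(fps), function(i)
      data.frame(id = truth$id[i], row = fps[[i]][, 1], col = fps[[i]][, 2])))
  } else {
    fpdf <- data.frame(id = integer(), row = integer(), col = integer())
  }
  utils::write.csv(fpdf, paste0(stem, "_footprints.csv"), row.names = FALSE)
  jsonlite::write_json(g, paste0(stem, "_grid.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_truth
#' @export
read_truth <- function(stem) {
  df <- utils::read.csv(paste0(stem, ".csv"),
                        colClasses = c(class = "character",
                                       state = "character"))
  fpdf <- utils::read.csv(paste0(stem, "_footprints.csv"))
  g <- jsonlite::read_json(paste0(stem, "_grid.json"), simplifyVector = TRUE)
  objects <- lapply(seq_len(nrow(df)), function(i) {
    fp <- as.matrix(fpdf[fpdf$id == df$id[i], c("row", "col"), drop = FALSE])
    dimnames(fp) <- NULL
    c(as.list(df[i, ]), list(footprint = fp))
  })
  truth_set(objects, rows = g$rows, cols = g$cols, pixel_size = g$pixel_size,
            origin_x = g$origin_x, origin_y = g$origin_y)
}
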
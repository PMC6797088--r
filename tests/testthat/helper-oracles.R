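# Independent brute-force oracles used across the suite. These deliberately
# re-derive results by the most direct method available (exhaustive loops,
# prcomp, hand-rolled union-find) so they share no code with the package
# implementations they check.

# a small scene that keeps per-test runtime low
small_scene <- function(seed, rows = 64, cols = 64, n_whales = 3, ...) {
  scene_config(rows = rows, cols = cols, n_whales = n_whales,
               n_logs = 1, n_waves = 1, min_separation_m = 20,
               seed = seed, ...)
}

# principal-axis length of a pixel footprint via prcomp
oracle_pca_length <- function(fp, pixel_size) {
  if (nrow(fp) == 1L) return(pixel_size)
  xy <- cbind(fp[, 2], -fp[, 1]) * pixel_size
  p <- stats::prcomp(xy, center = TRUE, scale. = FALSE)
  diff(range(p$x[, 1])) + pixel_size
}

# connected components by explicit union-find over all candidate pairs
oracle_union_find <- function(px, connectivity) {
  n <- nrow(px)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    dr <- abs(px[i, 1] - px[j, 1]); dc <- abs(px[i, 2] - px[j, 2])
    adj <- if (connectivity == 4L) dr + dc == 1 else max(dr, dc) == 1
    if (adj) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  match(roots, unique(roots))
}

# buffer membership by all-pairs center distance to boundary pixels
oracle_buffer <- function(water, distance_m, pixel_size, side = "both") {
  rows <- nrow(water); cols <- ncol(water)
  w <- water; w[is.na(w)] <- FALSE
  bnd <- matrix(FALSE, rows, cols)
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    if (w[r, c]) next
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 >= 1 && r2 <= rows && c2 >= 1 && c2 <= cols && w[r2, c2])
        bnd[r, c] <- TRUE
    }
  }
  bi <- which(bnd, arr.ind = TRUE)
  buf <- matrix(FALSE, rows, cols)
  if (nrow(bi)) {
    for (r in seq_len(rows)) for (c in seq_len(cols)) {
      d2 <- (bi[, 1] - r)^2 + (bi[, 2] - c)^2
      buf[r, c] <- sqrt(min(d2)) * pixel_size <= distance_m + 1e-9
    }
  }
  if (side == "landward") buf <- buf & !w
  if (side == "seaward") buf <- buf & w
  buf[is.na(water)] <- FALSE
  buf
}

# exhaustive per-pixel SAM: same rule as sam_classify, applied one pixel at
# a time with scalar arithmetic
oracle_sam <- function(raster, signatures, params, mask = NULL) {
  d <- dim(raster$values)
  tg <- Filter(function(s) s$role == "target", signatures)
  ex <- Filter(function(s) s$role == "exclusion", signatures)
  hits <- list()
  for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
    if (!is.null(mask) && !isTRUE(mask[r, c])) next
    v <- raster$values[r, c, ]
    if (anyNA(v) || sum(v^2) == 0) next
    angs <- vapply(tg, function(s) spectral_angle(v, s$stats$mean), 0)
    b <- which.min(angs)
    if (angs[b] > params$theta_max) next
    if (length(ex)) {
      eangs <- vapply(ex, function(s) spectral_angle(v, s$stats$mean), 0)
      if (!(angs[b] < min(eangs))) next
    }
    hits[[length(hits) + 1L]] <- data.frame(
      row = r, col = c, label = tg[[b]]$label, angle_rad = angs[b])
  }
  if (!length(hits))
    return(data.frame(row = integer(), col = integer(),
                      label = character(), angle_rad = numeric()))
  do.call(rbind, hits)
}

# streaming per-band statistics (Welford) for signature checking
oracle_stream_stats <- function(spectra) {
  nb <- ncol(spectra)
  out <- data.frame(band = seq_len(nb), mean = NA_real_, min = NA_real_,
                    max = NA_real_, sd = NA_real_)
  for (b in seq_len(nb)) {
    m <- 0; s <- 0; n <- 0; lo <- Inf; hi <- -Inf
    for (x in spectra[, b]) {
      n <- n + 1
      d <- x - m
      m <- m + d / n
      s <- s + d * (x - m)
      lo <- min(lo, x); hi <- max(hi, x)
    }
    out$mean[b] <- m; out$min[b] <- lo; out$max[b] <- hi
    out$sd[b] <- if (n > 1) sqrt(s / (n - 1)) else 0
  }
  out
}
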
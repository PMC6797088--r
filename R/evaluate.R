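round1 <- function(x) round(x + 1e-9, 1)   # half-up at one decimal
round0 <- function(x) round(x + 1e-9)      # half-up to nearest integer

#' Nearest-neighbor matching between two point sets
#'
#' For every point of `a`, the planar distance to its nearest point in `b`
#' (one-to-many: several `a` points may share a nearest `b` point), the
#' "Near"-style analysis used to compare satellite detections with survey
#' GPS locations.
#'
#' @param a,b data frames with columns `id`, `easting`, `northing`; `b`
#'   must be non-empty.
#' @return Data frame with columns `a_id`, `b_id`, `distance_m`.
#' @export
nearest_match <- function(a, b) {
  if (nrow(b) == 0L) stop("'b' must contain at least one point")
  if (nrow(a) == 0L)
    return(data.frame(a_id = integer(), b_id = integer(),
                      distance_m = numeric()))
  dx <- outer(a$easting, b$easting, "-")
  dy <- outer(a$northing, b$northing, "-")
  d <- sqrt(dx^2 + dy^2)
  j <- max.col(-d, ties.method = "first")
  data.frame(a_id = a$id, b_id = b$id[j],
             distance_m = d[cbind(seq_len(nrow(a)), j)])
}

#' Cumulative counts of matches within given radii
#'
#' @param matches a [nearest_match()] result (non-empty).
#' @param radii ascending distances in meters.
#' @return Data frame with columns `radius_m`, `count`, `pct`
#'   (`100 * count / n`, rounded to the nearest integer). Counts are
#'   cumulative and monotone in the radius.
#' @export
within_distance_summary <- function(matches, radii) {
  if (nrow(matches) == 0L) stop("empty match set")
  if (is.unsorted(radii, strictly = TRUE)) stop("radii must be ascending")
  n <- nrow(matches)
  count <- vapply(radii, function(r) sum(matches$distance_m <= r), 0L)
  data.frame(radius_m = radii, count = count,
             pct = round0(100 * count / n))
}

report_stratum <- function(total, whale_pixels, identified, n_truth,
                           all_total = total) {
  commission <- total - whale_pixels
  omission <- n_truth - identified
  data.frame(
    total_pixels = total,
    total_pixels_pct = round1(100 * total / all_total),
    whale_pixels = whale_pixels,
    whale_pixels_pct = round1(if (total > 0) 100 * whale_pixels / total else 0),
    commission_pixels = commission,
    commission_pct = round1(if (total > 0) 100 * commission / total else 0),
    whales_identified = identified,
    n_truth_whales = n_truth,
    whales_identified_pct = round1(if (n_truth > 0)
      100 * identified / n_truth else NA_real_),
    omission_whales = omission,
    omission_pct = round1(if (n_truth > 0)
      100 * omission / n_truth else NA_real_)
  )
}

#' Detection-performance arithmetic from plain counts
#'
#' Builds one report row from already-tallied counts: total flagged pixels,
#' how many of them fell on true whales, and how many of the truth whales
#' were identified. All percentages are at one decimal; pixel percentages
#' are of `total` (and of `all_total` for the stratum share), whale
#' percentages of `n_truth`. Useful for reproducing published error tables.
#'
#' @param total total flagged pixels in the stratum.
#' @param whale_pixels flagged pixels associated with true whales.
#' @param identified truth whales hit by at least one flagged pixel.
#' @param n_truth number of truth whales.
#' @param all_total total flagged pixels in the unthresholded stratum
#'   (defaults to `total`).
#' @return One-row data frame with counts and percentages (columns
#'   `whale_pixels_pct`, `commission_pct`, `whales_identified_pct`,
#'   `omission_pct`, ...).
#' @export
detection_counts <- function(total, whale_pixels, identified, n_truth,
                             all_total = total) {
  stopifnot(whale_pixels <= total, identified <= n_truth)
  report_stratum(total, whale_pixels, identified, n_truth, all_total)
}

#' Detection report against ground truth
#'
#' Tabulates SAM candidates against truth whale footprints, stratified by
#' likelihood threshold. A candidate pixel is a *whale pixel* iff it lies
#' on, or within `assoc_tol_px` pixels (Chebyshev) of, a truth whale
#' footprint — the tolerance absorbs georeferencing jitter. A truth whale
#' is *identified* at a threshold iff at least one candidate pixel at that
#' threshold associates with it (a whale claimed by several pixel groups
#' still counts once). Commission pixels are flagged pixels not associated
#' with any whale; omissions are truth whales never hit.
#'
#' @param candidates a `candidate_pixels` data frame from [sam_classify()].
#' @param truth a `truth_set` on the same grid (its non-whale objects are
#'   ignored); must contain at least one whale.
#' @param thresholds ascending likelihood thresholds; each stratum keeps
#'   candidates with `likelihood >= threshold` (default 0/40/65).
#' @param assoc_tol_px association tolerance in pixels (default 1, i.e.
#'   one MS pixel).
#' @return An object of class `detection_report`: a data frame with one
#'   row per threshold (column `threshold` plus the columns of
#'   [detection_counts()]).
#' @export
detection_report <- function(candidates, truth, thresholds = c(0, 40, 65),
                             assoc_tol_px = 1L) {
  stopifnot(inherits(truth, "truth_set"))
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be ascending")
  whales <- which(truth$class == "whale")
  if (!length(whales)) stop("truth contains no whale objects")
  fps <- attr(truth, "footprints")
  g <- attr(truth, "grid")
  # whale id per grid cell after dilating footprints by the tolerance
  owner <- matrix(0L, g$rows, g$cols)
  for (w in whales) {
    fp <- fps[[w]]
    for (dr in -assoc_tol_px:assoc_tol_px) for (dc in -assoc_tol_px:assoc_tol_px) {
      r2 <- pmin(pmax(fp[, 1] + dr, 1L), g$rows)
      c2 <- pmin(pmax(fp[, 2] + dc, 1L), g$cols)
      cells <- cbind(r2, c2)
      free <- owner[cells] == 0L
      owner[cells[free, , drop = FALSE]] <- w
    }
  }
  # exact footprint wins over a neighboring whale's dilation
  for (w in whales) owner[fps[[w]]] <- w
  assoc <- owner[cbind(candidates$row, candidates$col)]
  n_truth <- length(whales)
  all_total <- nrow(candidates)
  rows <- lapply(thresholds, function(t) {
    sel <- candidates$likelihood >= t
    total <- sum(sel)
    wp <- sum(assoc[sel] > 0L)
    ident <- length(unique(assoc[sel][assoc[sel] > 0L]))
    cbind(data.frame(threshold = t),
          report_stratum(total, wp, ident, n_truth, all_total))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("detection_report", "data.frame")
  out
}

#' @export
print.detection_report <- function(x, ...) {
  cat("<detection_report>\n")
  df <- as.data.frame(x)
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    cat(sprintf("  likelihood >= %g: %d pixels (%s%% whale, %s%% commission); %d of %d whales identified (%s%%), %d omitted (%s%%)\n",
                r$threshold, r$total_pixels, r$whale_pixels_pct,
                r$commission_pct, r$whales_identified, r$n_truth_whales,
                r$whales_identified_pct, r$omission_whales, r$omission_pct))
  }
  invisible(x)
}

#' Satellite-vs-ground count comparison
#'
#' Compares a satellite object count (with per-confidence-class breakdown)
#' against a ground/aerial survey count. The excess percentage is
#' `100 * (satellite - ground) / ground`, rounded to the nearest integer;
#' it is `NA` (flagged) when the ground count is zero. If per-class counts
#' are supplied and do not sum to the satellite count, the discrepancy is
#' kept and flagged rather than resolved — published tables are not always
#' internally consistent.
#'
#' @param satellite_count total satellite objects.
#' @param ground_count ground/aerial survey count.
#' @param class_counts optional numeric vector of per-class counts
#'   (class 1, 2, 3).
#' @return An object of class `count_comparison`: list with
#'   `ground_count`, `satellite_count`, `class_counts`, `excess`,
#'   `excess_pct`, `class_sum_ok`.
#' @export
count_comparison <- function(satellite_count, ground_count,
                             class_counts = NULL) {
  stopifnot(satellite_count >= 0, ground_count >= 0)
  excess <- satellite_count - ground_count
  excess_pct <- if (ground_count > 0) round0(100 * excess / ground_count)
                else NA_real_
  class_sum_ok <- if (is.null(class_counts)) NA
                  else sum(class_counts) == satellite_count
  out <- list(ground_count = ground_count, satellite_count = satellite_count,
              class_counts = class_counts, excess = excess,
              excess_pct = excess_pct, class_sum_ok = class_sum_ok)
  class(out) <- "count_comparison"
  out
}

#' @export
print.count_comparison <- function(x, ...) {
  cat(sprintf("<count_comparison> satellite %d vs ground %d: excess %+d (%s%%)\n",
              x$satellite_count, x$ground_count, x$excess,
              ifelse(is.na(x$excess_pct), "undefined", x$excess_pct)))
  if (!is.null(x$class_counts)) {
    cat(sprintf("  classes 1/2/3: %s%s\n",
                paste(x$class_counts, collapse = "/"),
                if (isFALSE(x$class_sum_ok))
                  " [warning: class counts do not sum to the satellite count]"
                else ""))
  }
  invisible(x)
}
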
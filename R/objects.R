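#' Group candidate pixels into connected objects
#'
#' Partitions SAM candidate pixels into connected components under
#' 4-neighbor (edge) or 8-neighbor (edge + diagonal) adjacency. Every
#' candidate pixel ends up in exactly one object; an empty candidate set
#' yields an empty object list. Default connectivity is 8, so diagonally
#' oriented carcasses at coarse pixel sizes stay in one group.
#'
#' @param candidates a `candidate_pixels` data frame from [sam_classify()]
#'   (or any data frame with `row`, `col` and optionally `likelihood`).
#' @param connectivity 4 or 8.
#' @return A data frame of class `candidate_objects` with one row per
#'   object (`id`, `n_pixels`, `centroid_easting`, `centroid_northing`,
#'   `max_likelihood`, `mean_likelihood`) and attribute `members`, a list
#'   mapping each object to the row indices of its member candidates.
#' @export
group_pixels <- function(candidates, connectivity = 8L) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  n <- nrow(candidates)
  g <- attr(candidates, "grid")
  if (n == 0L) {
    out <- data.frame(id = integer(), n_pixels = integer(),
                      centroid_easting = numeric(),
                      centroid_northing = numeric(),
                      max_likelihood = numeric(), mean_likelihood = numeric())
    attr(out, "members") <- list()
    attr(out, "grid") <- g
    class(out) <- c("candidate_objects", "data.frame")
    return(out)
  }
  offs <- if (connectivity == 4L) {
    cbind(c(0L, 1L), c(1L, 0L))
  } else {
    cbind(c(0L, 1L, 1L, 1L), c(1L, -1L, 0L, 1L))
  }
  key <- function(r, c) paste(r, c)
  id_of <- seq_len(n)
  names(id_of) <- key(candidates$row, candidates$col)
  edges <- integer(0)
  for (j in seq_len(nrow(offs))) {
    nb <- id_of[key(candidates$row + offs[j, 1], candidates$col + offs[j, 2])]
    hit <- !is.na(nb)
    if (any(hit)) edges <- c(edges, rbind(which(hit), nb[hit]))
  }
  gr <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges)) gr <- igraph::add_edges(gr, edges)
  comp <- igraph::components(gr)$membership
  ids <- sort(unique(comp))
  members <- lapply(ids, function(i) which(comp == i))
  lik <- if ("likelihood" %in% names(candidates)) candidates$likelihood
         else rep(NA_real_, n)
  has_xy <- all(c("easting", "northing") %in% names(candidates))
  out <- data.frame(
    id = seq_along(ids),
    n_pixels = vapply(members, length, 0L),
    centroid_easting = vapply(members, function(m)
      if (has_xy) mean(candidates$easting[m]) else NA_real_, 0),
    centroid_northing = vapply(members, function(m)
      if (has_xy) mean(candidates$northing[m]) else NA_real_, 0),
    max_likelihood = vapply(members, function(m) max(lik[m]), 0),
    mean_likelihood = vapply(members, function(m) mean(lik[m]), 0)
  )
  attr(out, "members") <- members
  attr(out, "grid") <- g
  attr(out, "candidates") <- candidates
  class(out) <- c("candidate_objects", "data.frame")
  out
}

#' @export
print.candidate_objects <- function(x, ...) {
  cat(sprintf("<candidate_objects> %d objects, %d member pixels\n",
              nrow(x), sum(x$n_pixels)))
  if (nrow(x)) print(utils::head(as.data.frame(x), 5), row.names = FALSE)
  invisible(x)
}

#' Morphometrics of a pixel object
#'
#' Length is the extent of the pixel centers along the principal axis plus
#' one pixel (so a single pixel has length = width = the pixel size, and a
#' straight run of k pixels has length `k * pixel_size`); width is the
#' extent along the orthogonal axis plus one pixel; elongation is
#' length / width.
#'
#' @param pixels two-column matrix of (row, col) member pixels.
#' @param pixel_size_m pixel size in meters.
#' @return List with `length_m`, `width_m`, `elongation`,
#'   `orientation_deg`.
#' @export
measure_object <- function(pixels, pixel_size_m) {
  m <- measure_pixel_set(as.matrix(pixels), pixel_size_m)
  m$elongation <- m$length_m / m$width_m
  m
}

#' Morphometric confidence rules
#'
#' Codifies the three-level manual confidence grading of whale-like objects
#' into numeric bounds: class 1 (obvious whale) requires whale-like length
#' and a clearly elongated, cigar-like shape; class 2 (probable) relaxed
#' bounds; everything else is class 3 (possible). The class-1 length bounds
#' default to the 7-20 m of an adult carcass; the elongation cutoffs are
#' non-canonical defaults, since the original grading was done by eye
#' (fluke visibility, part of the manual class-1 criterion, is not
#' assessable from pixel footprints and is dropped). Class-1 bounds must be
#' nested inside class-2 bounds.
#'
#' @param class1_length length bounds (m) for class 1; default `c(7, 20)`.
#' @param class1_elongation minimum elongation for class 1; default 2.5.
#' @param class2_length relaxed length bounds for class 2; default
#'   `c(5, 25)`.
#' @param class2_elongation minimum elongation for class 2; default 1.5.
#' @return An object of class `confidence_rules`.
#' @export
confidence_rules <- function(class1_length = c(7, 20),
                             class1_elongation = 2.5,
                             class2_length = c(5, 25),
                             class2_elongation = 1.5) {
  stopifnot(length(class1_length) == 2, length(class2_length) == 2,
            class1_length[1] < class1_length[2],
            class2_length[1] < class2_length[2])
  if (class2_length[1] > class1_length[1] ||
      class2_length[2] < class1_length[2] ||
      class2_elongation > class1_elongation)
    stop("class-1 bounds must be nested inside class-2 bounds")
  r <- list(class1_length = class1_length,
            class1_elongation = class1_elongation,
            class2_length = class2_length,
            class2_elongation = class2_elongation)
  class(r) <- "confidence_rules"
  r
}

#' Assign a confidence class from morphometrics
#'
#' @param morphometrics a list with `length_m` and `elongation`, as from
#'   [measure_object()].
#' @param rules a [confidence_rules()].
#' @return Integer class: 1 (obvious), 2 (probable) or 3 (possible).
#' @export
classify_confidence <- function(morphometrics, rules = confidence_rules()) {
  L <- morphometrics$length_m
  E <- morphometrics$elongation
  if (L >= rules$class1_length[1] && L <= rules$class1_length[2] &&
      E >= rules$class1_elongation) return(1L)
  if (L >= rules$class2_length[1] && L <= rules$class2_length[2] &&
      E >= rules$class2_elongation) return(2L)
  3L
}

#' Measure and grade grouped objects
#'
#' Applies [measure_object()] and [classify_confidence()] to every object
#' of a [group_pixels()] result.
#'
#' @param objects a `candidate_objects` data frame.
#' @param rules a [confidence_rules()].
#' @param pixel_size_m pixel size; defaults to the grid recorded on
#'   `objects`.
#' @return The object data frame with added columns `length_m`, `width_m`,
#'   `elongation`, `orientation_deg`, `confidence_class`.
#' @export
grade_objects <- function(objects, rules = confidence_rules(),
                          pixel_size_m = NULL) {
  g <- attr(objects, "grid")
  if (is.null(pixel_size_m)) {
    if (is.null(g)) stop("pixel_size_m is required when objects carry no grid")
    pixel_size_m <- g$pixel_size
  }
  cand <- attr(objects, "candidates")
  members <- attr(objects, "members")
  mm <- lapply(members, function(m)
    measure_object(cbind(cand$row[m], cand$col[m]), pixel_size_m))
  objects$length_m <- vapply(mm, `[[`, 0, "length_m")
  objects$width_m <- vapply(mm, `[[`, 0, "width_m")
  objects$elongation <- vapply(mm, `[[`, 0, "elongation")
  objects$orientation_deg <- vapply(mm, `[[`, 0, "orientation_deg")
  objects$confidence_class <- vapply(mm, classify_confidence, 0L,
                                     rules = rules)
  objects
}

#' Write graded objects as CSV and GeoJSON footprint polygons
#'
#' @param objects a graded `candidate_objects` data frame.
#' @param stem output path stem; writes `<stem>.csv` and `<stem>.geojson`.
#' @return The stem, invisibly.
#' @export
write_objects <- function(objects, stem) {
  utils::write.csv(as.data.frame(objects), paste0(stem, ".csv"),
                   row.names = FALSE)
  g <- attr(objects, "grid")
  cand <- attr(objects, "candidates")
  members <- attr(objects, "members")
  feats <- lapply(seq_len(nrow(objects)), function(i) {
    m <- members[[i]]
    e <- g$origin_x + c(cand$col[m] - 1, cand$col[m],
                        cand$col[m] - 1, cand$col[m]) * g$pixel_size
    n <- g$origin_y - c(cand$row[m] - 1, cand$row[m] - 1,
                        cand$row[m], cand$row[m]) * g$pixel_size
    h <- grDevices::chull(e, n)
    ring <- cbind(e[h], n[h])
    ring <- rbind(ring, ring[1, , drop = FALSE])
    props <- as.list(as.data.frame(objects)[i, ])
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(j) ring[j, ]))),
         properties = props)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       paste0(stem, ".geojson"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}
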
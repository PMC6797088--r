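cand_df <- function(px, likelihood = NULL, pixel_size = 2) {
  n <- nrow(px)
  df <- data.frame(row = px[, 1], col = px[, 2],
                   easting = (px[, 2] - 0.5) * pixel_size,
                   northing = (100 - px[, 1] + 0.5) * pixel_size,
                   likelihood = if (is.null(likelihood)) rep(50, n)
                                else likelihood)
  attr(df, "grid") <- list(rows = 100, cols = 100, pixel_size = pixel_size,
                           origin_x = 0, origin_y = 100 * pixel_size)
  df
}

test_that("grouping follows the chosen pixel adjacency", {
  two <- cand_df(rbind(c(5, 5), c(5, 6)))
  expect_equal(nrow(group_pixels(two, 4)), 1L)
  expect_equal(nrow(group_pixels(two, 8)), 1L)
  diag2 <- cand_df(rbind(c(5, 5), c(6, 6)))
  expect_equal(nrow(group_pixels(diag2, 8)), 1L)
  expect_equal(nrow(group_pixels(diag2, 4)), 2L)
  expect_equal(nrow(group_pixels(cand_df(matrix(numeric(), 0, 2)))), 0L)
  expect_error(group_pixels(two, 6), "connectivity")
})

test_that("grouping partitions candidates identically to union-find", {
  set.seed(101)
  for (rep in 1:5) {
    n <- 200
    px <- unique(cbind(sample(1:64, n, TRUE), sample(1:64, n, TRUE)))
    df <- cand_df(px)
    for (conn in c(4L, 8L)) {
      obj <- group_pixels(df, conn)
      members <- attr(obj, "members")
      # partition: every pixel exactly once
      expect_equal(sort(unlist(members)), seq_len(nrow(px)))
      got <- integer(nrow(px))
      for (i in seq_along(members)) got[members[[i]]] <- i
      want <- oracle_union_find(px, conn)
      # same partition up to relabeling
      expect_equal(length(unique(got)), length(unique(want)))
      expect_true(all(tapply(want, got, function(v) length(unique(v))) == 1))
    }
    # 8-connectivity can only merge 4-connected components
    expect_lte(nrow(group_pixels(df, 8L)), nrow(group_pixels(df, 4L)))
  }
})

test_that("morphometrics use principal-axis extents plus one pixel", {
  expect_equal(measure_object(cbind(10, 10), 0.5)$length_m, 0.5)
  expect_equal(measure_object(cbind(10, 10), 0.5)$width_m, 0.5)
  run20 <- cbind(rep(7, 20), 1:20)
  m <- measure_object(run20, 0.5)
  expect_equal(m$length_m, 10)
  expect_equal(m$width_m, 0.5)
  expect_equal(m$elongation, 20)
  diag3 <- cbind(1:3, 1:3)
  expect_equal(measure_object(diag3, 1)$length_m, 2 * sqrt(2) + 1)
  # generated footprints re-measure to within one pixel of the truth length
  sc <- generate_scene(small_scene(seed = 103, n_whales = 5))
  fps <- attr(sc$truth, "footprints")
  px <- attr(sc$truth, "grid")$pixel_size
  for (w in which(sc$truth$class == "whale")) {
    m <- measure_object(fps[[w]], px)
    expect_lt(abs(m$length_m - sc$truth$length_m[w]), px)
  }
})

test_that("confidence classes follow the nested morphometric rules", {
  r <- confidence_rules()
  expect_equal(classify_confidence(list(length_m = 12, elongation = 4), r), 1L)
  expect_equal(classify_confidence(list(length_m = 25, elongation = 4), r), 2L)
  expect_equal(classify_confidence(list(length_m = 30, elongation = 4), r), 3L)
  expect_equal(classify_confidence(list(length_m = 12, elongation = 2), r), 2L)
  expect_equal(classify_confidence(list(length_m = 12, elongation = 1.2), r), 3L)
  # exhaustive check against an independent rule table
  set.seed(107)
  for (i in 1:1000) {
    L <- runif(1, 0, 40); E <- runif(1, 1, 8)
    got <- classify_confidence(list(length_m = L, elongation = E), r)
    want <- if (L >= 7 && L <= 20 && E >= 2.5) 1L
            else if (L >= 5 && L <= 25 && E >= 1.5) 2L
            else 3L
    expect_identical(got, want)
  }
  expect_error(confidence_rules(class1_length = c(4, 20)), "nested")
  expect_error(confidence_rules(class2_elongation = 3), "nested")
})

test_that("grade_objects attaches morphometrics and classes to groups", {
  px <- rbind(cbind(rep(10, 6), 11:16),        # 12 m x 2 m run: class 1
              cbind(20:21, rep(3, 2)))         # 2-pixel blob: class 3
  obj <- grade_objects(group_pixels(cand_df(px), 8L))
  expect_equal(nrow(obj), 2L)
  big <- which.max(obj$n_pixels)
  expect_equal(obj$length_m[big], 12)
  expect_equal(obj$confidence_class[big], 1L)
  expect_equal(obj$confidence_class[-big], 3L)
  expect_true(all(obj$length_m >= obj$width_m))
})
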
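pts <- function(e, n) data.frame(id = seq_along(e), easting = e, northing = n)

test_that("nearest matching is the exhaustive all-pairs minimum", {
  expect_equal(nearest_match(pts(0, 0), pts(0, 0))$distance_m, 0)
  expect_equal(nearest_match(pts(0, 0), pts(3, 4))$distance_m, 5)
  set.seed(111)
  a <- pts(runif(50, 0, 1000), runif(50, 0, 1000))
  b <- pts(runif(30, 0, 1000), runif(30, 0, 1000))
  m <- nearest_match(a, b)
  for (i in seq_len(nrow(a))) {
    d <- sqrt((a$easting[i] - b$easting)^2 + (a$northing[i] - b$northing)^2)
    expect_equal(m$distance_m[i], min(d))
    expect_equal(m$b_id[i], b$id[which.min(d)])
  }
  expect_error(nearest_match(a, pts(numeric(), numeric())), "at least one")
})

test_that("within-radius summaries count cumulatively and round as published", {
  # 19 of 24 within 100 m prints as 79%
  m <- data.frame(a_id = 1:24, b_id = 1,
                  distance_m = c(runif(19, 0, 99), runif(5, 150, 310)))
  s <- within_distance_summary(m, c(100, 200, 400))
  expect_equal(s$count[1], 19L)
  expect_equal(s$pct[1], 79)
  expect_true(all(diff(s$count) >= 0))
  expect_equal(s$count[3], 24L)
  z <- within_distance_summary(data.frame(a_id = 1:3, b_id = 1,
                                          distance_m = rep(0, 3)), c(1, 10))
  expect_equal(z$pct, c(100, 100))
  set.seed(113)
  d <- runif(40, 0, 500)
  s2 <- within_distance_summary(data.frame(a_id = 1:40, b_id = 1,
                                           distance_m = d), c(50, 250))
  expect_equal(s2$count, c(sum(d <= 50), sum(d <= 250)))
  expect_error(within_distance_summary(m[0, ], 100), "empty")
})

test_that("detection arithmetic reproduces published error percentages", {
  # 39 flagged pixels, 26 on whales; 14 of 21 whales found
  r <- detection_counts(39, 26, 14, 21)
  expect_equal(r$whale_pixels_pct, 66.7)
  expect_equal(r$commission_pct, 33.3)
  expect_equal(r$whales_identified_pct, 66.7)
  expect_equal(r$omission_pct, 33.3)
  expect_equal(r$whale_pixels + r$commission_pixels, r$total_pixels)
  # whole-image stratum: 109 pixels, 26 on whales, 14 of 23 whales
  w <- detection_counts(109, 26, 14, 23)
  expect_equal(w$whale_pixels_pct, 23.9)
  expect_equal(w$commission_pct, 76.1)
  expect_equal(w$whales_identified_pct, 60.9)  # 14/23, one decimal
  expect_equal(w$omission_pct, 39.1)
  # likelihood > 40 stratum of the subset analysis
  s40 <- detection_counts(16, 16, 11, 21, all_total = 39)
  expect_equal(s40$total_pixels_pct, 41.0)
  expect_equal(s40$whale_pixels_pct, 100.0)
  expect_equal(s40$commission_pct, 0.0)
  s65 <- detection_counts(10, 10, 6, 21, all_total = 39)
  expect_equal(s65$total_pixels_pct, 25.6)
  expect_equal(s65$whales_identified_pct, 28.6)
  expect_equal(s65$omission_pct, 71.4)
})

test_that("detection reports against truth conserve counts and nest", {
  sc <- generate_scene(small_scene(seed = 127))
  sigs <- signatures_from_truth(sc$ms, sc$truth)
  buf <- build_coastal_buffer(extract_water_mask(compute_ndwi(sc$ms)),
                              5, sc$ms$pixel_size)
  cand <- sam_classify(sc$ms, sigs, mask = buf)
  rep <- detection_report(cand, sc$truth)
  expect_s3_class(rep, "detection_report")
  expect_equal(rep$whale_pixels + rep$commission_pixels, rep$total_pixels)
  expect_equal(rep$whales_identified + rep$omission_whales,
               rep$n_truth_whales)
  expect_true(all(diff(rep$total_pixels) <= 0))
  expect_true(all(diff(rep$commission_pixels) <= 0))
  expect_true(all(diff(rep$omission_whales) >= 0))
  # zero candidates: full omission, no commission
  none <- cand[0, ]
  attr(none, "grid") <- attr(cand, "grid")
  r0 <- detection_report(none, sc$truth, thresholds = 0)
  expect_equal(r0$total_pixels, 0L)
  expect_equal(r0$commission_pixels, 0L)
  expect_equal(r0$omission_pct, 100)
  truth_nw <- sc$truth[sc$truth$class != "whale", , drop = FALSE]
  attr(truth_nw, "footprints") <-
    attr(sc$truth, "footprints")[sc$truth$class != "whale"]
  attr(truth_nw, "grid") <- attr(sc$truth, "grid")
  class(truth_nw) <- class(sc$truth)
  expect_error(detection_report(cand, truth_nw), "no whale")
})

test_that("count comparisons reproduce published excesses and flag bad sums", {
  c1 <- count_comparison(23, 14, class_counts = c(14, 3, 6))
  expect_equal(c1$excess, 9)
  expect_equal(c1$excess_pct, 64)
  expect_true(c1$class_sum_ok)
  expect_equal(count_comparison(20, 20)$excess_pct, 0)
  c2 <- count_comparison(22, 30, class_counts = c(11, 2, 8))
  expect_equal(c2$excess, -8)
  expect_false(c2$class_sum_ok)   # published rows are not always consistent
  expect_true(is.na(count_comparison(5, 0)$excess_pct))
})
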
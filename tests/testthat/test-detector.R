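test_that("signature statistics are exact over the chosen pixels", {
  bs <- wv2_band_set()
  vals <- array(0, c(4, 4, 8))
  vals[1, 1, ] <- 10
  vals[2, 2, ] <- 30
  r <- ms_raster(vals, bs)
  s1 <- extract_signature(r, cbind(1, 1), "one")
  expect_equal(s1$stats$mean, rep(10, 8))
  expect_equal(s1$stats$min, s1$stats$max)
  expect_equal(s1$stats$sd, rep(0, 8))
  s2 <- extract_signature(r, rbind(c(1, 1), c(2, 2)), "two")
  expect_equal(s2$stats$mean, rep(20, 8))
  expect_equal(s2$stats$min, rep(10, 8))
  expect_equal(s2$stats$max, rep(30, 8))
  # 40 random pixels vs an independent streaming-statistics oracle
  set.seed(61)
  vals <- array(runif(20 * 20 * 8, 0, 80), c(20, 20, 8))
  r <- ms_raster(vals, bs)
  px <- cbind(sample(1:20, 40, TRUE), sample(1:20, 40, TRUE))
  sig <- extract_signature(r, px, "rand")
  spectra <- t(apply(px, 1, function(p) vals[p[1], p[2], ]))
  o <- oracle_stream_stats(spectra)
  expect_equal(sig$stats$mean, o$mean)
  expect_equal(sig$stats$min, o$min)
  expect_equal(sig$stats$max, o$max)
  expect_equal(sig$stats$sd, o$sd)
  expect_true(all(sig$stats$min <= sig$stats$mean &
                  sig$stats$mean <= sig$stats$max))
  # all-nodata pixel sets are rejected
  vals[3, 3, ] <- NA
  expect_error(extract_signature(ms_raster(vals, bs), cbind(3, 3), "bad"),
               "nodata")
})

test_that("signatures round-trip through CSV", {
  sc <- generate_scene(small_scene(seed = 67))
  sigs <- signatures_from_truth(sc$ms, sc$truth)
  path <- file.path(withr::local_tempdir(), "sigs.csv")
  write_signatures(sigs, path)
  back <- read_signatures(path)
  expect_length(back, length(sigs))
  for (i in seq_along(sigs)) {
    expect_equal(back[[i]]$label, sigs[[i]]$label)
    expect_equal(back[[i]]$role, sigs[[i]]$role)
    expect_equal(back[[i]]$stats$mean, sigs[[i]]$stats$mean, tolerance = 1e-9)
    expect_equal(back[[i]]$stats$sd, sigs[[i]]$stats$sd, tolerance = 1e-9)
  }
})

test_that("the spectral angle is a scale-invariant shape distance", {
  expect_equal(spectral_angle(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(spectral_angle(c(1, 2, 3), c(2, 4, 6)), 0)
  expect_equal(spectral_angle(c(1, 0), c(1, 1)), pi / 4)
  expect_equal(spectral_angle(c(1, 0), c(0, 1)), pi / 2)
  set.seed(71)
  for (i in 1:20) {
    a <- runif(8, 1, 80); b <- runif(8, 1, 80)
    expect_equal(spectral_angle(a, b), spectral_angle(b, a))
    expect_equal(spectral_angle(a * runif(1, 0.1, 10), b),
                 spectral_angle(a, b), tolerance = 1e-8)
  }
  expect_error(spectral_angle(rep(0, 8), runif(8)), "zero-norm")
  expect_error(spectral_angle(1:3, 1:4), "same length")
})

test_that("the likelihood map is linear, clipped and monotone", {
  expect_equal(angle_to_likelihood(0, 0.1), 100)
  expect_equal(angle_to_likelihood(0.1, 0.1), 0)
  expect_equal(angle_to_likelihood(0.05, 0.1), 50)
  expect_equal(angle_to_likelihood(0.2, 0.1), 0)
  a <- seq(0, 0.1, by = 0.005)
  expect_true(all(diff(angle_to_likelihood(a, 0.1)) < 0))
})

test_that("SAM recovers exact-spectrum whales and only them", {
  lib <- spectral_library()
  cfg <- small_scene(seed = 73, n_whales = 3, within_cv = 0,
                     background_cv = 0, noise_sd = 0,
                     decay_weights = c(whale_pink = 1))
  sc <- generate_scene(cfg)
  sig <- extract_signature(sc$ms,
                           attr(sc$truth, "footprints")[[
                             which(sc$truth$class == "whale")[1]]],
                           "whale_pink")
  cand <- sam_classify(sc$ms, list(sig), sam_params(0.10))
  fps <- attr(sc$truth, "footprints")
  whale_px <- do.call(rbind, fps[sc$truth$class == "whale"])
  expect_setequal(paste(cand$row, cand$col),
                  paste(whale_px[, 1], whale_px[, 2]))
  expect_true(all(cand$likelihood == 100))
})

test_that("exclusion signatures veto pixels closer to them than to targets", {
  lib <- spectral_library()
  bs <- wv2_band_set()
  vals <- array(0, c(2, 2, 8))
  vals[1, 1, ] <- lib$whale_pink
  vals[1, 2, ] <- lib$cloud
  vals[2, 1, ] <- 0.97 * lib$cloud   # still cloud-shaped
  vals[2, 2, ] <- lib$water
  r <- ms_raster(vals, bs)
  tg <- extract_signature(r, cbind(1, 1), "whale")
  # wide angle tolerance: without the exclusion, cloud pixels sneak in
  loose <- sam_params(theta_max = pi / 2 - 0.01)
  cand0 <- sam_classify(r, list(tg), loose)
  expect_true(any(cand0$row == 1 & cand0$col == 2))
  ex <- extract_signature(r, cbind(1, 2), "cloud", role = "exclusion")
  cand1 <- sam_classify(r, list(tg, ex), loose)
  expect_false(any(cand1$row == 1 & cand1$col == 2))
  expect_false(any(cand1$row == 2 & cand1$col == 1))
  expect_true(any(cand1$row == 1 & cand1$col == 1))
})

test_that("vectorized SAM equals the per-pixel brute-force oracle", {
  for (seed in c(81, 82)) {
    cfg <- small_scene(seed = seed, rows = 40, cols = 40, n_whales = 2)
    sc <- generate_scene(cfg)
    sigs <- signatures_from_truth(sc$ms, sc$truth)
    sigs[[length(sigs) + 1L]] <-
      extract_signature(sc$ms, cbind(1:3, 1), "water", role = "exclusion")
    params <- sam_params(0.25)
    buf <- build_coastal_buffer(extract_water_mask(compute_ndwi(sc$ms)),
                                5, sc$ms$pixel_size)
    for (mask in list(NULL, buf)) {
      got <- sam_classify(sc$ms, sigs, params, mask)
      want <- oracle_sam(sc$ms, sigs, params, mask)
      ko <- order(got$row, got$col)
      kw <- order(want$row, want$col)
      expect_equal(got$row[ko], want$row[kw])
      expect_equal(got$col[ko], want$col[kw])
      expect_equal(got$label[ko], want$label[kw])
      expect_equal(got$angle_rad[ko], want$angle_rad[kw], tolerance = 1e-10)
    }
  }
})

test_that("masking never adds candidates and strata are nested", {
  sc <- generate_scene(small_scene(seed = 91))
  sigs <- signatures_from_truth(sc$ms, sc$truth)
  buf <- build_coastal_buffer(extract_water_mask(compute_ndwi(sc$ms)),
                              5, sc$ms$pixel_size)
  all_cand <- sam_classify(sc$ms, sigs)
  masked <- sam_classify(sc$ms, sigs, mask = buf)
  k_all <- paste(all_cand$row, all_cand$col)
  k_masked <- paste(masked$row, masked$col)
  expect_true(all(k_masked %in% k_all))
  k65 <- k_masked[masked$likelihood >= 65]
  k40 <- k_masked[masked$likelihood >= 40]
  expect_true(all(k65 %in% k40))
  expect_true(all(k40 %in% k_masked))
  # nodata pixels are never candidates
  ms2 <- sc$ms
  ms2$values[all_cand$row[1], all_cand$col[1], ] <- NA
  cand2 <- sam_classify(ms2, sigs)
  expect_false(any(cand2$row == all_cand$row[1] &
                   cand2$col == all_cand$col[1]))
  expect_error(sam_classify(sc$ms, list()), "target signature")
})
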
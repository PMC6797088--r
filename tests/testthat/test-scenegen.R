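test_that("an empty configuration yields a background-only scene", {
  cfg <- scene_config(rows = 32, cols = 32, n_whales = 0, n_logs = 0,
                      n_waves = 0, n_clouds = 0, seed = 3)
  sc <- generate_scene(cfg)
  expect_equal(nrow(sc$truth), 0L)
  expect_equal(dim(sc$ms$values), c(32, 32, 8))
  expect_equal(dim(sc$pan$values), c(128, 128))
  expect_true(all(is.finite(sc$ms$values)))
})

test_that("identical config and seed reproduce the scene bit for bit", {
  cfg <- small_scene(seed = 11)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$ms$values, b$ms$values)
  expect_identical(a$pan$values, b$pan$values)
  expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))
  expect_identical(attr(a$truth, "footprints"), attr(b$truth, "footprints"))
})

test_that("whale footprints re-measure to the configured length range", {
  cfg <- scene_config(rows = 200, cols = 200, n_whales = 10, n_logs = 0,
                      n_waves = 0, seed = 42)
  sc <- generate_scene(cfg)
  whales <- which(sc$truth$class == "whale")
  expect_length(whales, 10L)
  fps <- attr(sc$truth, "footprints")
  px <- attr(sc$truth, "grid")$pixel_size
  for (w in whales) {
    L <- oracle_pca_length(fps[[w]], px)
    expect_gte(L, 7)
    expect_lte(L, 20)
    expect_equal(L, sc$truth$length_m[w], tolerance = 1e-6)
  }
})

test_that("footprints are disjoint and whales sit on the coastline", {
  sc <- generate_scene(small_scene(seed = 5, n_whales = 4))
  fps <- attr(sc$truth, "footprints")
  keys <- unlist(lapply(fps, function(fp) paste(fp[, 1], fp[, 2])))
  expect_equal(anyDuplicated(keys), 0L)
  # every whale must have at least one pixel within the 5 m coastal buffer
  buf <- build_coastal_buffer(extract_water_mask(compute_ndwi(sc$ms)),
                              5, sc$ms$pixel_size)
  for (w in which(sc$truth$class == "whale"))
    expect_true(any(buf[fps[[w]]]))
})

test_that("whales outshine logs and waves in the red and NIR1 bands", {
  sc <- generate_scene(small_scene(seed = 9, n_whales = 5))
  fps <- attr(sc$truth, "footprints")
  mean_band <- function(cls, b) {
    idx <- which(sc$truth$class == cls)
    mean(unlist(lapply(idx, function(i) sc$ms$values[, , b][fps[[i]]])))
  }
  for (b in c(5L, 7L)) {   # red, NIR1
    expect_gt(mean_band("whale", b), mean_band("log", b))
    expect_gt(mean_band("whale", b), mean_band("wave", b))
  }
})

test_that("the pan raster tracks band-weighted MS brightness", {
  cfg <- small_scene(seed = 13)
  sc <- generate_scene(cfg)
  k <- 4
  down <- block_average(sc$pan$values, k)
  bright <- matrix(0, cfg$rows, cfg$cols)
  for (b in 1:8) bright <- bright + cfg$pan_weights[b] * sc$ms$values[, , b]
  expect_gt(stats::cor(as.vector(down), as.vector(bright)), 0.9)
})

test_that("an overfull scene raises a placement-failure error", {
  cfg <- scene_config(rows = 16, cols = 16, n_whales = 40, n_logs = 0,
                      n_waves = 0, seed = 1)
  expect_error(generate_scene(cfg), "placement failure|too small")
})

test_that("truth files round-trip centroids, attributes and footprints", {
  sc <- generate_scene(small_scene(seed = 21, n_whales = 5))
  stem <- file.path(withr::local_tempdir(), "truth")
  write_truth(sc$truth, stem)
  back <- read_truth(stem)
  expect_equal(back$easting, sc$truth$easting, tolerance = 1e-9)
  expect_equal(back$northing, sc$truth$northing, tolerance = 1e-9)
  expect_equal(back$class, sc$truth$class)
  expect_equal(back$length_m, sc$truth$length_m, tolerance = 1e-9)
  expect_equal(attr(back, "footprints"), attr(sc$truth, "footprints"))
  gj <- jsonlite::read_json(paste0(stem, "_points.geojson"),
                            simplifyVector = TRUE)
  expect_equal(gj$type, "FeatureCollection")
  expect_equal(nrow(gj$features), nrow(sc$truth))
  # empty truth still writes a valid (empty) collection
  sc0 <- generate_scene(scene_config(rows = 32, cols = 32, n_whales = 0,
                                     n_logs = 0, n_waves = 0, seed = 2))
  stem0 <- file.path(withr::local_tempdir(), "empty")
  write_truth(sc0$truth, stem0)
  gj0 <- jsonlite::read_json(paste0(stem0, "_points.geojson"))
  expect_equal(gj0$type, "FeatureCollection")
  expect_length(gj0$features, 0L)
  expect_equal(nrow(read_truth(stem0)), 0L)
})
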
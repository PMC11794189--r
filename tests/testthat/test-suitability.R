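test_that("the MTP threshold is the minimum training score", {
  expect_equal(mtp_threshold(c(0.2, 0.35, 0.15)), 0.15)
  expect_equal(mtp_threshold(0.3), 0.3)
  expect_error(mtp_threshold(numeric()))
})

test_that("classification uses the four half-open intervals", {
  vals <- matrix(c(0, 0.05, 0.1039, 0.399, 0.4, 0.55, 0.599, 0.6, 1, NA),
                 2, 5)
  g <- raster_grid(vals, west = 0, north = 2, dx = 1, dy = 1)
  cm <- classify_suitability(g, mtp = 0.1039)
  expect_equal(as.vector(cm$values),
               c(0, 0, 1, 1, 2, 2, 2, 3, 3, NA))
  expect_error(classify_suitability(g, mtp = 0.4), "below")
  expect_error(classify_suitability(g, mtp = 0.45), "below")
  bad <- raster_grid(matrix(1.2, 2, 2), 0, 2, 1, 1)
  expect_error(classify_suitability(bad, 0.1), "\\[0, 1\\]")
})

test_that("classification partitions the unmasked cells", {
  fx <- make_sdm_fixture(40, n_grid = 25, n_presence = 100,
                         n_background = 300)
  cm <- classify_suitability(fx$suitability, mtp = 0.2)
  counts <- table(cm$values)
  expect_equal(sum(counts), sum(!is.na(cm$values)))
  expect_true(all(names(counts) %in% as.character(0:3)))
})

test_that("every training presence is suitable at its own MTP", {
  fx <- make_sdm_fixture(41, n_grid = 25, n_presence = 150,
                         n_background = 500, linear = c(bio1 = 3))
  m <- fit_sdm(fx$presence_values, fx$background_values,
               fc_set = c("L", "Q"), rm = 1)
  scores <- predict_cloglog(m, fx$presence_values)
  mtp <- min(mtp_threshold(scores), 0.399)
  cm <- classify_suitability(
    raster_grid(matrix(scores, nrow = 1), 0, 1, 1, 1), mtp = mtp)
  expect_true(all(cm$values >= 1))
})

test_that("class areas integrate to the sphere on a global one-degree grid", {
  g <- raster_grid(matrix(0.7, 180, 360), west = -180, north = 90,
                   dx = 1, dy = 1)
  cm <- classify_suitability(g, mtp = 0.1)  # everything class 3
  at <- class_areas(cm)
  sphere <- 4 * pi * 6371.0088^2 / 1e4
  expect_equal(at$area_1e4_km2[at$label == "high"], sphere,
               tolerance = 1e-3)
  expect_equal(at$area_1e4_km2[at$label == "low"], 0)
  expect_equal(at$area_1e4_km2[at$label == "total"],
               at$area_1e4_km2[at$label == "high"])
})

test_that("areas are additive under a north/south split", {
  set.seed(42)
  vals <- matrix(runif(40 * 20), 40, 20)
  g <- raster_grid(vals, west = 10, north = 50, dx = 0.5, dy = 0.5)
  cm <- classify_suitability(g, mtp = 0.2)
  whole <- class_areas(cm)$area_1e4_km2
  gn <- raster_grid(vals[1:20, ], west = 10, north = 50, dx = 0.5, dy = 0.5)
  gs <- raster_grid(vals[21:40, ], west = 10, north = 40, dx = 0.5, dy = 0.5)
  north <- class_areas(classify_suitability(gn, 0.2))$area_1e4_km2
  south <- class_areas(classify_suitability(gs, 0.2))$area_1e4_km2
  expect_equal(north + south, whole, tolerance = 1e-12)
})

test_that("permuting class codes in place permutes their areas exactly", {
  set.seed(7)
  g <- raster_grid(matrix(runif(100), 10, 10), west = 0, north = 10,
                   dx = 1, dy = 1)
  cm <- classify_suitability(g, 0.3)
  a1 <- class_areas(cm)
  cm2 <- cm
  cm2$values[] <- 3 - cm$values  # 0<->3, 1<->2 in the same cells
  a2 <- class_areas(cm2)
  expect_equal(a1$area_1e4_km2[a1$label == "high"],
               a2$area_1e4_km2[a2$label == "unsuitable"])
  expect_equal(a1$area_1e4_km2[a1$label == "low"],
               a2$area_1e4_km2[a2$label == "moderate"])
})

test_that("projected-looking rasters are rejected for area computation", {
  g <- raster_grid(matrix(1, 5, 5), west = 0, north = 5e5, dx = 1000,
                   dy = 1000)
  cm <- classify_suitability(
    raster_grid(matrix(0.7, 5, 5), west = 0, north = 5e5, dx = 1000,
                dy = 1000), 0.1)
  expect_error(class_areas(cm), "geographic")
})

test_that("crop overlay restricts areas and reports the suitable share", {
  vals <- matrix(runif(400, 0, 1), 20, 20)
  g <- raster_grid(vals, west = 0, north = 20, dx = 1, dy = 1)
  cm <- classify_suitability(g, 0.2)
  ones <- raster_grid(matrix(1, 20, 20), 0, 20, 1, 1)
  ov <- overlay_crop(cm, ones)
  expect_equal(ov$areas$area_1e4_km2, class_areas(cm)$area_1e4_km2)
  zeros <- raster_grid(matrix(0, 20, 20), 0, 20, 1, 1)
  ov0 <- overlay_crop(cm, zeros)
  expect_true(ov0$empty_crop)
  expect_equal(ov0$proportion_suitable, 0)
  expect_true(all(ov0$areas$area_1e4_km2 == 0))
  # mask exactly on the high-suitability cells -> proportion 1
  high <- raster_grid((cm$values == 3) * 1, 0, 20, 1, 1)
  ovh <- overlay_crop(cm, high)
  expect_equal(ovh$proportion_suitable, 1, tolerance = 1e-12)
  # fractional mode weights areas by the crop fraction
  half <- raster_grid(matrix(0.5, 20, 20), 0, 20, 1, 1)
  ovf <- overlay_crop(cm, half, mode = "fractional")
  expect_equal(ovf$areas$area_1e4_km2,
               class_areas(cm)$area_1e4_km2 / 2, tolerance = 1e-12)
  # geometry mismatches are errors
  off <- raster_grid(matrix(1, 20, 20), 1, 20, 1, 1)
  expect_error(overlay_crop(cm, off), "co-registered")
})

test_that("scenario comparison reproduces the reference arithmetic", {
  ref <- tibble::tibble(label = "total", area_1e4_km2 = 1068.40)
  f1 <- tibble::tibble(label = "total", area_1e4_km2 = 1119.54)
  f2 <- tibble::tibble(label = "total", area_1e4_km2 = 1018.85)
  cmp <- compare_scenarios(ref, `2030s` = f1, `2050s` = f2)
  tb <- tidy(cmp)
  expect_equal(tb$pct_change[tb$scenario == "2030s"], 4.79)
  avg <- tb[tb$scenario == "average", ]
  expect_equal(round_half_up(avg$area_1e4_km2, 2), 1069.20)
  expect_equal(avg$pct_change, 0.07)
})

test_that("comparing a map with itself gives zero change and a stable map", {
  vals <- matrix(runif(100), 10, 10)
  cm <- classify_suitability(raster_grid(vals, 0, 10, 1, 1), 0.2)
  cmp <- compare_scenarios(cm, future = cm)
  tb <- tidy(cmp)
  expect_true(all(tb$pct_change[tb$scenario == "future" &
                                  tb$area_1e4_km2 > 0] == 0))
  ch <- cmp$change_maps$future$values
  expect_true(all(ch %in% c(0, 3)))  # stable-unsuitable / stable-suitable
  # an undefined change (0 reference, positive future) is NA
  ref0 <- tibble::tibble(label = "total", area_1e4_km2 = 0)
  fut <- tibble::tibble(label = "total", area_1e4_km2 = 5)
  expect_true(is.na(tidy(compare_scenarios(ref0, f = fut))$pct_change[2]))
})

test_that("gain and loss cells are coded from the suitable/unsuitable split", {
  ref <- classify_suitability(
    raster_grid(matrix(c(0.05, 0.5, 0.05, 0.5), 2, 2), 0, 2, 1, 1), 0.2)
  fut <- classify_suitability(
    raster_grid(matrix(c(0.5, 0.05, 0.05, 0.5), 2, 2), 0, 2, 1, 1), 0.2)
  ch <- compare_scenarios(ref, f = fut)$change_maps$f$values
  expect_equal(as.vector(ch), c(1, 2, 0, 3))  # gain, loss, stable x2
})
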
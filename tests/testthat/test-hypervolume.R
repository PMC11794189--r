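std_cloud <- function(n = 400, seed = 1, shift = c(0, 0)) {
  set.seed(seed)
  tibble::tibble(x = rnorm(n) + shift[1], y = rnorm(n) + shift[2])
}

test_that("pooled z-standardization makes axes commensurable", {
  one <- dplyr::mutate(std_cloud(300, 1), group = "a")
  std <- standardize_niche(one)
  expect_equal(mean(std$data$x), 0, tolerance = 1e-12)
  expect_equal(sd(std$data$x), 1, tolerance = 1e-12)
  # two identical groups standardize identically
  two <- dplyr::bind_rows(one, dplyr::mutate(one, group = "b"))
  std2 <- standardize_niche(two)
  a <- dplyr::filter(std2$data, group == "a")
  b <- dplyr::filter(std2$data, group == "b")
  expect_equal(a$x, b$x)
  # shifting one group by +pooled-sd moves its centroid by about 1
  pooled_sd <- sd(two$x)
  three <- dplyr::bind_rows(one,
    dplyr::mutate(one, x = x + pooled_sd, group = "b"))
  std3 <- standardize_niche(three)
  d <- mean(dplyr::filter(std3$data, group == "b")$x) -
    mean(dplyr::filter(std3$data, group == "a")$x)
  expect_equal(d, pooled_sd / sd(three$x), tolerance = 1e-10)
  expect_lt(abs(d - 1), 0.2)
  flat <- dplyr::mutate(one, y = 1)
  expect_error(standardize_niche(flat), "zero-variance")
})

test_that("cross-validation bandwidths track the Silverman rule for Gaussian data", {
  pts <- std_cloud(500, 2)
  h_cv <- estimate_bandwidth(pts, method = "cross-validation")
  h_s <- estimate_bandwidth(pts, method = "silverman")
  expect_true(all(h_cv / h_s < 2 & h_cv / h_s > 0.5))
  # duplicating the data cannot increase the bandwidth
  dup <- dplyr::bind_rows(pts, pts)
  expect_true(all(estimate_bandwidth(dup) <= h_cv + 1e-12))
  # Silverman is scale-equivariant
  wide <- dplyr::mutate(pts, x = 2 * x)
  h_w <- estimate_bandwidth(wide, method = "silverman")
  expect_equal(h_w[["x"]], 2 * h_s[["x"]], tolerance = 1e-12)
  expect_warning(estimate_bandwidth(pts[1:5, ]), "Silverman")
})

test_that("hypervolume volume matches the dense-grid oracle", {
  pts <- std_cloud(300, 3)
  bw <- estimate_bandwidth(pts, method = "silverman")
  hv <- build_hypervolume(pts, bandwidths = bw, mass = 0.95,
                          n_support = 20000, seed = 4)
  oracle <- oracle_kde_2d(as.matrix(pts), bw, mass = 0.95)
  expect_lt(abs(hv$volume - oracle$volume) / oracle$volume, 0.1)
  expect_true(all(c("x", "y") == hv$axes))
})

test_that("support mass is nested and translation-invariant", {
  pts <- std_cloud(250, 5)
  bw <- estimate_bandwidth(pts, method = "silverman")
  v <- vapply(c(0.90, 0.95, 0.99), function(m)
    build_hypervolume(pts, bw, mass = m, n_support = 5000, seed = 6)$volume,
    numeric(1))
  expect_true(all(diff(v) > 0))
  # the 0.90 support points all clear the 0.99 threshold
  hv90 <- build_hypervolume(pts, bw, mass = 0.90, n_support = 5000, seed = 6)
  hv99 <- build_hypervolume(pts, bw, mass = 0.99, n_support = 5000, seed = 6)
  dens <- pestrisk:::kde_density(as.matrix(hv90$support_points),
                                 as.matrix(pts), bw)
  expect_true(all(dens >= hv99$threshold))
  # translation: same seed, shifted cloud -> same volume, shifted support
  sh <- dplyr::mutate(pts, x = x + 7)
  hv <- build_hypervolume(pts, bw, mass = 0.95, n_support = 5000, seed = 7)
  hv_sh <- build_hypervolume(sh, bw, mass = 0.95, n_support = 5000, seed = 7)
  expect_equal(hv_sh$volume, hv$volume, tolerance = 1e-12)
  expect_equal(hv_sh$centroid[["x"]] - hv$centroid[["x"]], 7,
               tolerance = 1e-9)
  expect_error(build_hypervolume(dplyr::mutate(pts, x = 1, y = 2)[1:20, ],
                                 bw), "degenerate")
})

test_that("volume scales as c^d when all axes are scaled by c", {
  pts <- std_cloud(250, 8)
  bw <- estimate_bandwidth(pts, method = "silverman")
  hv <- build_hypervolume(pts, bw, n_support = 8000, seed = 9)
  scaled <- dplyr::mutate(pts, x = 2 * x, y = 2 * y)
  hv2 <- build_hypervolume(scaled, 2 * bw, n_support = 8000, seed = 9)
  expect_equal(hv2$volume / hv$volume, 4, tolerance = 0.05)
})

test_that("Sorensen overlap behaves at its anchors and matches the oracle", {
  a <- std_cloud(300, 10)
  b <- std_cloud(300, 11)
  bw_a <- estimate_bandwidth(a, method = "silverman")
  bw_b <- estimate_bandwidth(b, method = "silverman")
  hv_a <- build_hypervolume(a, bw_a, n_support = 8000, seed = 12)
  hv_b <- build_hypervolume(b, bw_b, n_support = 8000, seed = 13)
  # two draws of the same distribution: near-total overlap
  expect_gt(overlap_sorensen(hv_a, hv_b), 0.8)
  expect_equal(overlap_sorensen(hv_a, hv_a), 1, tolerance = 0.05)
  # symmetry is exact
  expect_identical(overlap_sorensen(hv_a, hv_b),
                   overlap_sorensen(hv_b, hv_a))
  # clouds ten pooled sds apart do not overlap
  far <- std_cloud(300, 14, shift = c(10, 0))
  hv_far <- build_hypervolume(far, estimate_bandwidth(far, method = "silverman"),
                              n_support = 8000, seed = 15)
  expect_lt(overlap_sorensen(hv_a, hv_far), 0.01)
  # half-sd separation agrees with the grid-integration oracle
  near <- std_cloud(300, 16, shift = c(0.5, 0))
  bw_n <- estimate_bandwidth(near, method = "silverman")
  hv_near <- build_hypervolume(near, bw_n, n_support = 20000, seed = 17)
  hv_a2 <- build_hypervolume(a, bw_a, n_support = 20000, seed = 18)
  s_pkg <- overlap_sorensen(hv_a2, hv_near)
  s_oracle <- oracle_sorensen_2d(as.matrix(a), as.matrix(near), bw_a, bw_n)
  expect_lt(abs(s_pkg - s_oracle), 0.05)
})

test_that("centroid distances recover known shifts symmetrically", {
  a <- std_cloud(300, 20)
  sh <- dplyr::mutate(a, x = x + 2)
  bw <- estimate_bandwidth(a, method = "silverman")
  hv_a <- build_hypervolume(a, bw, n_support = 10000, seed = 21)
  hv_b <- build_hypervolume(sh, bw, n_support = 10000, seed = 22)
  d <- centroid_distance(hv_a, hv_b)
  expect_lt(abs(d - 2), 0.1)
  expect_identical(d, centroid_distance(hv_b, hv_a))
  hv_a2 <- build_hypervolume(a, bw, n_support = 10000, seed = 23)
  expect_lt(centroid_distance(hv_a, hv_a2), 0.05)
  # observation centroids are available as an alternative
  expect_lt(abs(centroid_distance(hv_a, hv_b, use = "observations") - 2),
            0.01)
  expect_equal(centroid_distance(hv_a, hv_a), 0)
})

test_that("pairwise comparison fills the triangular layout and round-trips", {
  cl <- generate_niche_clouds(list(
    niche_cloud_spec("A", c(x = 0, y = 0), diag(2), 200),
    niche_cloud_spec("B", c(x = 0, y = 0), diag(2), 200),
    niche_cloud_spec("C", c(x = 30, y = 30), diag(2), 200)), seed = 24)
  nc <- pairwise_compare(cl, n_support = 4000, seed = 25,
                         bandwidth_method = "silverman")
  expect_gt(nc$sorensen["A", "B"], 0.7)   # identical distributions
  expect_lt(nc$sorensen["A", "C"], 0.01)  # far-away group
  expect_lt(nc$sorensen["B", "C"], 0.01)
  expect_lt(nc$distance["A", "B"], 0.2)
  # layout: Sorensen above the diagonal, distance below
  expect_equal(nc$matrix["A", "B"], nc$sorensen["A", "B"])
  expect_equal(nc$matrix["B", "A"], nc$distance["A", "B"])
  expect_true(all(is.na(diag(nc$matrix))))
  # reproducible given the seed
  nc2 <- pairwise_compare(cl, n_support = 4000, seed = 25,
                          bandwidth_method = "silverman")
  expect_equal(nc$matrix, nc2$matrix)
  # CSV round trip of the triangular matrix
  p <- tempfile(fileext = ".csv")
  write_comparison_matrix(nc, p)
  m2 <- read_comparison_matrix(p)
  expect_equal(unname(m2), unname(nc$matrix), tolerance = 1e-12)
  td <- tidy(nc)
  expect_equal(nrow(td), 3)
  expect_true(all(td$sorensen >= 0 & td$sorensen <= 1))
  expect_true(all(td$distance >= 0))
})
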
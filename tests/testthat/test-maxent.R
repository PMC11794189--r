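test_that("feature expansion produces the documented counts and bounds", {
  set.seed(1)
  vals <- tibble::as_tibble(matrix(runif(50 * 4), 50,
                                   dimnames = list(NULL, paste0("v", 1:4))))
  f1 <- build_features(vals["v1"], fc_set = "L")
  expect_equal(ncol(f1$X), 1)
  f2 <- build_features(vals, fc_set = c("L", "Q", "P"))
  expect_equal(ncol(f2$X), 4 + 4 + choose(4, 2))
  fh <- build_features(vals, fc_set = c("L", "H"), n_knots = 5)
  expect_true(all(fh$X >= 0 & fh$X <= 1))
  expect_equal(sum(fh$spec$features$class == "H"), 4 * 5 * 2)
  # presence expansion reuses the background scalings exactly
  again <- build_features(vals[1:10, ], spec = f2$spec)
  expect_identical(again$X, f2$X[1:10, ])
  expect_warning(build_features(tibble::tibble(a = rnorm(20), b = rep(1, 20)),
                                fc_set = "L"), "zero-variance")
})

test_that("a forward hinge with its knot at the variable minimum is the linear feature", {
  set.seed(2)
  x <- tibble::tibble(v = runif(30, 2, 5))
  base <- build_features(x, fc_set = "L")
  spec <- base$spec
  spec$features <- tibble::tibble(name = "H:v", class = "H", parent1 = "v",
                                  parent2 = NA_character_,
                                  knot = min(x$v), direction = "fwd")
  hinge <- build_features(x, spec = spec)
  expect_equal(unname(hinge$X[, 1]), unname(base$X[, 1]), tolerance = 1e-12)
})

test_that("uniform presences give a near-null model with zero gain", {
  set.seed(3)
  bg <- tibble::tibble(v1 = runif(600), v2 = runif(600))
  pres <- bg[sample.int(600, 300), ]
  m <- fit_sdm(pres, bg, fc_set = c("L", "Q"), rm = 1)
  expect_lt(max(abs(m$beta)), 0.25)
  expect_lt(m$training_gain, 0.02)
  raw <- predict_raw(m, bg)
  expect_equal(sum(raw), 1, tolerance = 1e-6)
  expect_lt(max(abs(raw - 1 / 600)), 0.25 / 600)
})

test_that("an overwhelming penalty forces every coefficient to zero", {
  fx <- make_sdm_fixture(4, n_grid = 20, n_presence = 80, n_background = 300)
  m <- fit_sdm(fx$presence_values, fx$background_values,
               fc_set = c("L", "Q"), rm = 1e6)
  expect_true(all(m$beta == 0))
  expect_equal(m$training_gain, 0)
})

test_that("raw predictions normalize over background after every fit", {
  for (s in 1:3) {
    fx <- make_sdm_fixture(s, n_grid = 20, n_presence = 60,
                           n_background = 250)
    m <- fit_sdm(fx$presence_values, fx$background_values,
                 fc_set = c("L", "Q"), rm = 0.5 + s)
    expect_equal(sum(predict_raw(m, fx$background_values)), 1,
                 tolerance = 1e-6)
  }
})

test_that("the single-feature fit matches a brute-force grid search", {
  set.seed(5)
  xb <- runif(300)
  xp <- pmin(1, rbeta(80, 4, 2))  # presences shifted high
  Xp <- matrix(xp, dimnames = list(NULL, "L:v"))
  Xb <- matrix(xb, dimnames = list(NULL, "L:v"))
  m <- fit_maxent(Xp, Xb, rm = 1, tolerance = 1e-10)
  expect_equal(unname(m$beta), oracle_beta_1d(xp, xb, m$lambda),
               tolerance = 2e-3)
})

test_that("the penalized objective is non-decreasing across cycles", {
  fx <- make_sdm_fixture(6, n_grid = 20, n_presence = 80, n_background = 300)
  m <- fit_sdm(fx$presence_values, fx$background_values,
               fc_set = c("L", "Q", "H"), n_knots = 4, rm = 0.5)
  expect_true(all(diff(m$obj_trace) >= -1e-12))
})

test_that("stronger regularization prunes coefficients (soft property)", {
  fails <- 0
  for (s in 1:10) {
    fx <- make_sdm_fixture(s + 20, n_grid = 20, n_presence = 60,
                           n_background = 250)
    k <- vapply(c(0.5, 4), function(rm) {
      m <- fit_sdm(fx$presence_values, fx$background_values,
                   fc_set = c("L", "Q"), rm = rm)
      sum(abs(m$beta) > 1e-8)
    }, numeric(1))
    if (k[1] < k[2]) fails <- fails + 1
  }
  expect_lte(fails, 1)
})

test_that("cloglog is the entropy-scaled monotone transform of raw", {
  set.seed(7)
  bg <- tibble::tibble(v = runif(200))
  pres <- bg[sample.int(200, 50), ]
  m <- fit_sdm(pres, bg, fc_set = "L", rm = 1e6)  # uniform model
  cl <- predict_cloglog(m, bg)
  expect_equal(unname(cl), rep(1 - exp(-1), 200), tolerance = 1e-9)
  # monotonicity in raw for a non-trivial model
  fx <- make_sdm_fixture(8, n_grid = 20, n_presence = 80, n_background = 300)
  m2 <- fit_sdm(fx$presence_values, fx$background_values,
                fc_set = c("L", "Q"))
  raw <- predict_raw(m2, fx$background_values)
  cl2 <- predict_cloglog(m2, fx$background_values)
  ord <- order(raw)
  expect_true(all(diff(cl2[ord]) >= 0))
  expect_equal(1 - exp(-exp(m2$H_raw) * 0), 0)  # raw = 0 maps to 0
  expect_error(predict_raw(m2, matrix(0, 2, 3)), "mismatch")
})

test_that("AUC follows the pairwise-comparison definition", {
  expect_equal(evaluate_auc(c(5, 6), c(1, 2)), 1)
  expect_equal(evaluate_auc(c(0.9, 0.8), c(0.7, 0.85)), 0.75)
  set.seed(9)
  x <- rnorm(500); y <- rnorm(500)
  expect_lt(abs(evaluate_auc(x, y) - 0.5), 0.06)
  # invariant under strictly monotone transforms
  p <- runif(40); b <- runif(60)
  expect_equal(evaluate_auc(p, b), evaluate_auc(exp(3 * p), exp(3 * b)))
  # ties contribute half
  expect_equal(evaluate_auc(c(1, 1), c(1, 0)), 0.75)
})

test_that("AICc follows the small-sample formula and selection rules", {
  # K = 2, logLik = -100, n = 50 -> 204 + 12/47
  K <- 2; ll <- -100; n <- 50
  expect_equal(2 * K - 2 * ll + 2 * K * (K + 1) / (n - K - 1),
               204 + 12 / 47)
  fx <- make_sdm_fixture(10, n_grid = 20, n_presence = 80,
                         n_background = 300)
  tn <- tune_sdm(fx$presence_values, fx$background_values,
                 rm_grid = c(1, 2), fc_grid = list(L = "L", LQ = c("L", "Q")),
                 n_knots = 4)
  cand <- tidy(tn)
  expect_equal(nrow(cand), 4)
  expect_equal(min(cand$dAICc, na.rm = TRUE), 0)
  expect_true(cand$dAICc[cand$selected] == 0)
  # AICc recomputes from K and logLik on every row
  with(cand[cand$valid, ], expect_equal(
    AICc, 2 * K - 2 * log_lik + 2 * K * (K + 1) / (tn$n_presence - K - 1)))
  # single-candidate grid selects itself
  tn1 <- tune_sdm(fx$presence_values, fx$background_values,
                  rm_grid = 1, fc_grid = list(L = "L"))
  expect_equal(tidy(tn1)$dAICc, 0)
  expect_true(tidy(tn1)$selected)
})
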
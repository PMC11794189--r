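# Shared fixture builders and independent oracles. Everything is
# generated in code; no binary data.

fixture_bounds <- c(west = 100, east = 120, south = 20, north = 40)

make_stack <- function(seed = 1, n = 40, layers = c("bio1", "bio2", "bio3")) {
  generate_env_stack(seed, n, n, fixture_bounds,
                     lapply(layers, layer_spec))
}

# A stack + known truth + sampled presences/background, shared by the
# recovery, tuning and mapping tests.
make_sdm_fixture <- function(seed = 1, n_grid = 40, n_presence = 300,
                             n_background = 1500,
                             linear = c(bio1 = 2), quadratic = c(bio2 = -1)) {
  st <- make_stack(seed, n_grid)
  suit <- generate_true_suitability(st, 0, linear = linear,
                                    quadratic = quadratic)
  occ <- sample_presences(suit, n_presence, seed = seed + 1)
  bg <- sample_background(st, n_background, seed = seed + 2)
  cells <- as_tibble(st)
  z <- function(v) (cells[[v]] - mean(cells[[v]])) /
    (stats::sd(cells[[v]]) * sqrt((nrow(cells) - 1) / nrow(cells)))
  zl <- lapply(names(st), z)
  names(zl) <- names(st)
  true_eta <- function(values) {
    # population-standardized truth evaluated at arbitrary cell values
    out <- rep(0, nrow(values))
    for (nm in names(linear)) {
      mu <- mean(cells[[nm]])
      sd0 <- stats::sd(cells[[nm]]) * sqrt((nrow(cells) - 1) / nrow(cells))
      out <- out + linear[[nm]] * (values[[nm]] - mu) / sd0
    }
    for (nm in names(quadratic)) {
      mu <- mean(cells[[nm]])
      sd0 <- stats::sd(cells[[nm]]) * sqrt((nrow(cells) - 1) / nrow(cells))
      out <- out + quadratic[[nm]] * ((values[[nm]] - mu) / sd0)^2
    }
    out
  }
  list(stack = st, suitability = suit, occ = occ, bg = bg,
       presence_values = extract_values(st, occ),
       background_values = extract_values(st, bg),
       true_eta = true_eta)
}

# Brute-force 1-D maximizer of the penalized maxent objective; the
# independent oracle for the single-feature coordinate-descent check.
oracle_beta_1d <- function(xp, xb, lambda, step = 1e-3, range = c(-10, 10)) {
  betas <- seq(range[1], range[2], by = step)
  obj <- vapply(betas, function(b) {
    eta_b <- b * xb
    mean(b * xp) - (max(eta_b) + log(sum(exp(eta_b - max(eta_b))))) -
      lambda * abs(b)
  }, numeric(1))
  betas[which.max(obj)]
}

# Dense-grid integration oracle for 2-D product-Gaussian KDE supports:
# evaluates the mixture density on a regular grid, finds the density
# level enclosing `mass` of the probability, and integrates cellwise.
oracle_kde_2d <- function(X, bandwidths, mass = 0.95, res = 400, pad = 3) {
  lo <- apply(X, 2, min) - pad * bandwidths
  hi <- apply(X, 2, max) + pad * bandwidths
  gx <- seq(lo[1], hi[1], length.out = res)
  gy <- seq(lo[2], hi[2], length.out = res)
  dens_x <- sapply(X[, 1], function(m) dnorm(gx, m, bandwidths[1]))
  dens_y <- sapply(X[, 2], function(m) dnorm(gy, m, bandwidths[2]))
  dens <- (dens_x %*% t(dens_y)) / nrow(X)  # sum_i fx_i(x) fy_i(y) / n
  cell <- diff(gx)[1] * diff(gy)[1]
  ord <- order(dens, decreasing = TRUE)
  cum <- cumsum(dens[ord]) * cell
  k <- which(cum >= mass * sum(dens) * cell)[1]
  threshold <- dens[ord[k]]
  list(volume = sum(dens >= threshold) * cell, threshold = threshold,
       grid_x = gx, grid_y = gy, density = dens, cell = cell)
}

# Oracle Sorensen of two 2-D KDE supports by joint-grid integration.
oracle_sorensen_2d <- function(Xa, Xb, bw_a, bw_b, mass = 0.95, res = 400) {
  lo <- pmin(apply(Xa, 2, min) - 3 * bw_a, apply(Xb, 2, min) - 3 * bw_b)
  hi <- pmax(apply(Xa, 2, max) + 3 * bw_a, apply(Xb, 2, max) + 3 * bw_b)
  gx <- seq(lo[1], hi[1], length.out = res)
  gy <- seq(lo[2], hi[2], length.out = res)
  dens_of <- function(X, bw) {
    dx <- sapply(X[, 1], function(m) dnorm(gx, m, bw[1]))
    dy <- sapply(X[, 2], function(m) dnorm(gy, m, bw[2]))
    (dx %*% t(dy)) / nrow(X)
  }
  cell <- diff(gx)[1] * diff(gy)[1]
  level <- function(dens) {
    ord <- order(dens, decreasing = TRUE)
    cum <- cumsum(dens[ord]) * cell
    dens[ord[which(cum >= mass * sum(dens) * cell)[1]]]
  }
  da <- dens_of(Xa, bw_a); db <- dens_of(Xb, bw_b)
  ia <- da >= level(da); ib <- db >= level(db)
  va <- sum(ia) * cell; vb <- sum(ib) * cell
  vint <- sum(ia & ib) * cell
  2 * vint / (va + vb)
}
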
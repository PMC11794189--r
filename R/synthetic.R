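#' Synthetic environmental raster stacks
#'
#' Generates co-registered environmental layers with controllable
#' spatial structure for pipeline testing: latitudinal or longitudinal
#' gradients, or spatially smoothed Gaussian noise, with optional target
#' Pearson correlations between layers achieved by linear mixing of a
#' shared standardized latent field.
#'
#' @param seed integer seed; the call is a pure function of
#'   `(seed, arguments)`.
#' @param n_rows,n_cols grid dimensions (>= 2).
#' @param bounds named numeric vector `c(west, east, south, north)` in
#'   degrees, within `[-180, 180] x [-90, 90]`.
#' @param specs list of layer specifications from [layer_spec()].
#' @return A [raster_stack()] with one layer per spec.
#' @examples
#' st <- generate_env_stack(1, 40, 40, c(west = 0, east = 10, south = 0,
#'   north = 10), list(layer_spec("temp"), layer_spec("prec",
#'   correlation_with = c("temp", 0.5))))
#' @export
generate_env_stack <- function(seed, n_rows, n_cols, bounds, specs) {
  stopifnot(n_rows >= 2, n_cols >= 2, length(specs) >= 1)
  bounds <- bounds[c("west", "east", "south", "north")]
  stopifnot(!anyNA(bounds),
            bounds["west"] >= -180, bounds["east"] <= 180,
            bounds["south"] >= -90, bounds["north"] <= 90,
            bounds["east"] > bounds["west"],
            bounds["north"] > bounds["south"])
  nms <- vapply(specs, function(s) s$name, character(1))
  if (anyDuplicated(nms))
    stop("duplicate layer names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  for (s in specs) {
    cw <- s$correlation_with
    if (!is.null(cw) && !(cw$layer %in% nms))
      stop("correlation target references unknown layer '", cw$layer, "'",
           call. = FALSE)
  }
  dx <- (bounds["east"] - bounds["west"]) / n_cols
  dy <- (bounds["north"] - bounds["south"]) / n_rows
  lat <- matrix(rep(bounds["north"] - (seq_len(n_rows) - 0.5) * dy, n_cols),
                nrow = n_rows)
  lon <- matrix(rep(bounds["west"] + (seq_len(n_cols) - 0.5) * dx,
                    each = n_rows), nrow = n_rows)
  set.seed(as.integer(seed))
  fields <- list()
  for (s in specs) {
    base <- switch(s$base,
      "latitudinal-gradient" = lat,
      "longitudinal-gradient" = lon,
      "smoothed-noise" = smooth_noise(n_rows, n_cols, s$smoothing_radius),
      stop("unknown base '", s$base, "'", call. = FALSE))
    cw <- s$correlation_with
    if (!is.null(cw)) {
      r <- cw$r
      z_ref <- standardize_field(fields[[cw$layer]])
      z_own <- standardize_field(base)
      base <- r * z_ref + sqrt(1 - r^2) * z_own
    }
    fields[[s$name]] <- base
  }
  layers <- lapply(fields, raster_grid, west = bounds[["west"]],
                   north = bounds[["north"]], dx = dx, dy = dy)
  raster_stack(layers)
}

#' @rdname generate_env_stack
#' @param name layer name, unique within one request.
#' @param base one of `"smoothed-noise"`, `"latitudinal-gradient"`,
#'   `"longitudinal-gradient"`.
#' @param smoothing_radius box-kernel radius in cells (>= 0) for
#'   smoothed noise.
#' @param correlation_with optional length-2 vector `c(layer_name, r)`
#'   with target Pearson correlation `r` in `[-1, 1]` to an earlier layer.
#' @export
layer_spec <- function(name, base = "smoothed-noise", smoothing_radius = 3,
                       correlation_with = NULL) {
  stopifnot(is.character(name), nchar(name) > 0, smoothing_radius >= 0)
  cw <- NULL
  if (!is.null(correlation_with)) {
    r <- as.numeric(correlation_with[[2]])
    if (is.na(r) || abs(r) > 1)
      stop("target correlation must be in [-1, 1]", call. = FALSE)
    cw <- list(layer = as.character(correlation_with[[1]]), r = r)
  }
  list(name = name, base = base, smoothing_radius = smoothing_radius,
       correlation_with = cw)
}

# i.i.d. standard normal noise convolved with a (2r+1)^2 uniform kernel,
# edges handled by local renormalization.
smooth_noise <- function(n_rows, n_cols, radius) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  if (radius == 0) return(z)
  box_blur(z, radius)
}

box_blur <- function(m, radius) {
  k <- as.integer(radius)
  sum_1d <- function(x) {
    n <- length(x)
    cs <- cumsum(c(0, x))
    hi <- pmin(seq_len(n) + k, n)
    lo <- pmax(seq_len(n) - k, 1)
    cs[hi + 1] - cs[lo]
  }
  cnt <- matrix(1, nrow(m), ncol(m))
  num <- apply(m, 2, sum_1d)
  num <- t(apply(num, 1, sum_1d))
  den <- apply(cnt, 2, sum_1d)
  den <- t(apply(den, 1, sum_1d))
  num / den
}

standardize_field <- function(m) {
  mu <- mean(m, na.rm = TRUE)
  sd0 <- stats::sd(as.vector(m), na.rm = TRUE)
  if (sd0 == 0) sd0 <- 1
  (m - mu) / sd0
}

#' True suitability surface from a known log-linear model
#'
#' Computes `sigma(eta)` with `eta = intercept + sum(linear * z(layer))
#' + sum(quadratic * z(layer)^2)`, where `z()` standardizes a layer over
#' its unmasked cells and `sigma` is the logistic function. The result
#' is the ground-truth suitability used in parameter-recovery tests.
#'
#' @param stack a [raster_stack()].
#' @param intercept real intercept.
#' @param linear,quadratic named numeric vectors of coefficients; names
#'   must be layers in `stack`.
#' @return A [raster_grid()] with values in (0, 1).
#' @export
generate_true_suitability <- function(stack, intercept = 0,
                                      linear = numeric(), quadratic = numeric()) {
  stopifnot(inherits(stack, "raster_stack"))
  used <- union(names(linear), names(quadratic))
  unknown <- setdiff(used, names(stack))
  if (length(unknown))
    stop("unknown layer(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  tpl <- stack_template(stack)
  eta <- matrix(intercept, nrow(tpl$values), ncol(tpl$values))
  for (nm in names(linear))
    eta <- eta + linear[[nm]] * standardize_field(stack$layers[[nm]]$values)
  for (nm in names(quadratic))
    eta <- eta + quadratic[[nm]] * standardize_field(stack$layers[[nm]]$values)^2
  suit <- 1 / (1 + exp(-eta))
  suit[is.na(tpl$values)] <- NA_real_
  raster_grid(suit, west = tpl$geotransform[["west"]],
              north = tpl$geotransform[["north"]],
              dx = tpl$geotransform[["dx"]], dy = tpl$geotransform[["dy"]])
}

#' Sample presence points proportional to a suitability surface
#'
#' Draws `n` occurrence points at cell centers, with replacement, with
#' per-cell probability proportional to suitability. Masked or
#' zero-suitability cells are never drawn.
#'
#' @param suitability a [raster_grid()] with nonnegative values.
#' @param n number of points (>= 1).
#' @param seed integer seed.
#' @return A tibble with columns `lon`, `lat` (an occurrence table).
#' @export
sample_presences <- function(suitability, n, seed) {
  stopifnot(inherits(suitability, "raster_grid"), n >= 1)
  cc <- cell_centers(suitability)
  cc <- cc[!is.na(cc$value) & cc$value > 0, ]
  if (nrow(cc) == 0)
    stop("suitability has no unmasked cell with positive value", call. = FALSE)
  set.seed(as.integer(seed))
  idx <- sample.int(nrow(cc), n, replace = TRUE, prob = cc$value)
  tibble::tibble(lon = cc$lon[idx], lat = cc$lat[idx])
}

#' Random binary crop mask
#'
#' Marks a given fraction of the template's unmasked cells as crop
#' (value 1), the rest 0; masked cells stay masked.
#'
#' @param template a [raster_grid()] providing geometry and mask.
#' @param fraction share of unmasked cells set to 1, in `[0, 1]`.
#' @param seed integer seed.
#' @return A binary [raster_grid()] co-registered with `template`.
#' @export
generate_crop_mask <- function(template, fraction, seed) {
  stopifnot(inherits(template, "raster_grid"), fraction >= 0, fraction <= 1)
  ok <- which(!is.na(template$values))
  k <- round(fraction * length(ok))
  m <- matrix(NA_real_, nrow(template$values), ncol(template$values))
  m[ok] <- 0
  set.seed(as.integer(seed))
  if (k > 0) m[sample(ok, k)] <- 1
  gt <- template$geotransform
  raster_grid(m, west = gt[["west"]], north = gt[["north"]],
              dx = gt[["dx"]], dy = gt[["dy"]])
}

#' Multivariate-normal niche clouds
#'
#' Generates group-labelled points in niche (climate) space, one
#' multivariate normal cloud per group, emulating per-region occurrence
#' climates for hypervolume comparisons.
#'
#' @param specs list of specs from [niche_cloud_spec()]; all groups must
#'   share the same axis names.
#' @param seed integer seed.
#' @return A tibble with a `group` column plus one column per axis.
#' @export
generate_niche_clouds <- function(specs, seed) {
  stopifnot(length(specs) >= 1)
  axes <- names(specs[[1]]$mean)
  stopifnot(length(axes) >= 2)
  for (s in specs)
    if (!identical(names(s$mean), axes))
      stop("all groups must share the same axes", call. = FALSE)
  set.seed(as.integer(seed))
  purrr::map_dfr(specs, function(s) {
    pts <- MASS::mvrnorm(s$n_points, mu = s$mean, Sigma = s$covariance)
    out <- tibble::as_tibble(as.data.frame(pts))
    names(out) <- axes
    dplyr::bind_cols(tibble::tibble(group = s$group), out)
  })
}

#' @rdname generate_niche_clouds
#' @param group group label.
#' @param mean named numeric vector of axis means (length >= 2).
#' @param covariance symmetric positive-semidefinite covariance matrix.
#' @param n_points points to draw (> number of axes).
#' @export
niche_cloud_spec <- function(group, mean, covariance, n_points) {
  d <- length(mean)
  stopifnot(d >= 2, n_points > d)
  if (is.null(names(mean))) names(mean) <- paste0("axis", seq_len(d))
  covariance <- as.matrix(covariance)
  stopifnot(nrow(covariance) == d, ncol(covariance) == d)
  if (max(abs(covariance - t(covariance))) > 1e-8)
    stop("covariance must be symmetric", call. = FALSE)
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop("covariance must be positive semi-definite", call. = FALSE)
  list(group = group, mean = mean, covariance = covariance,
       n_points = as.integer(n_points))
}
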
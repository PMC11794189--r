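#' Pooled z-score standardization of grouped niche tables
#'
#' Standardizes each niche axis with the mean and standard deviation
#' pooled over ALL groups, so axes are commensurable across groups and
#' Euclidean distances are comparable between pairs.
#'
#' @param groups tibble with a `group` column and one numeric column
#'   per niche axis.
#' @return A list: `data` (standardized tibble, same shape), `center`
#'   and `scale` (named per-axis pooled statistics).
#' @export
standardize_niche <- function(groups) {
  stopifnot(is.data.frame(groups), "group" %in% names(groups))
  axes <- setdiff(names(dplyr::select(tibble::as_tibble(groups),
                                      dplyr::where(is.numeric))), "group")
  stopifnot(length(axes) >= 2)
  center <- purrr::map_dbl(groups[axes], mean)
  scale <- purrr::map_dbl(groups[axes], stats::sd)
  if (any(scale == 0))
    stop("zero-variance axis: ", paste(axes[scale == 0], collapse = ", "),
         call. = FALSE)
  out <- groups
  for (a in axes) out[[a]] <- (out[[a]] - center[[a]]) / scale[[a]]
  list(data = tibble::as_tibble(out), center = center, scale = scale)
}

#' Per-axis kernel bandwidth estimation
#'
#' Cross-validation bandwidths maximize the leave-one-out mean log
#' kernel density of the 1-D Gaussian KDE on each axis over a
#' log-spaced candidate grid; the Silverman rule
#' `1.06 * sd * n^(-1/(d+4))` is the fallback (and is forced, with a
#' warning, below 10 points).
#'
#' @param points data frame of standardized axis values (non-numeric
#'   and `group` columns ignored).
#' @param method `"cross-validation"` (default) or `"silverman"`.
#' @param n_candidates size of the log-spaced candidate grid.
#' @return Named numeric vector of per-axis bandwidths.
#' @export
estimate_bandwidth <- function(points, method = c("cross-validation", "silverman"),
                               n_candidates = 25) {
  method <- match.arg(method)
  pts <- dplyr::select(tibble::as_tibble(points), dplyr::where(is.numeric))
  pts <- pts[setdiff(names(pts), "group")]
  d <- ncol(pts); n <- nrow(pts)
  stopifnot(d >= 1, n >= 2)
  silver <- purrr::map_dbl(pts, function(x)
    1.06 * stats::sd(x) * n^(-1 / (d + 4)))
  if (method == "silverman") return(silver)
  if (n < 10) {
    warning("fewer than 10 points; falling back to Silverman bandwidths",
            call. = FALSE)
    return(silver)
  }
  purrr::imap_dbl(pts, function(x, nm) {
    h0 <- silver[[nm]]
    cand <- exp(seq(log(h0 / 8), log(h0 * 8), length.out = n_candidates))
    dist2 <- as.matrix(stats::dist(x))^2
    score <- purrr::map_dbl(cand, function(h) {
      K <- exp(-dist2 / (2 * h^2)) / (sqrt(2 * pi) * h)
      diag(K) <- 0
      loo <- rowSums(K) / (n - 1)
      mean(log(pmax(loo, 1e-300)))
    })
    cand[which.max(score)]
  })
}

# Product-Gaussian KDE density of `query` (matrix q x d) given data
# points (n x d) and per-axis bandwidths.
kde_density <- function(query, data, bandwidths) {
  n <- nrow(data); d <- ncol(data)
  logdens <- matrix(0, nrow(query), n)
  for (j in seq_len(d)) {
    diff <- outer(query[, j], data[, j], "-") / bandwidths[j]
    logdens <- logdens - diff^2 / 2
  }
  const <- -d / 2 * log(2 * pi) - sum(log(bandwidths))
  rowMeans(exp(logdens)) * exp(const)
}

#' Build a kernel-density niche hypervolume
#'
#' Estimates the high-density support of a product-Gaussian KDE on
#' standardized niche axes. Uniform points are drawn over the data's
#' bounding box expanded by three bandwidths per axis; the density
#' threshold is set so the fraction of total KDE probability mass
#' above it equals `mass`, support points are the uniform draws at or
#' above the threshold, and the volume is the box volume times the
#' acceptance fraction. Deterministic given the seed.
#'
#' @param points data frame of standardized axis values for ONE group.
#' @param bandwidths per-axis bandwidths (default: cross-validation via
#'   [estimate_bandwidth()]).
#' @param mass probability mass enclosed by the support (default 0.95).
#' @param n_support number of uniform Monte-Carlo draws (>= 100).
#' @param seed integer seed.
#' @return An object of class `hypervolume_kde`: `axes`, `bandwidths`,
#'   `threshold`, `support_points` (tibble of retained draws),
#'   `volume` (standardized units^d), `centroid`, `data`, `mass`,
#'   `seed`.
#' @export
build_hypervolume <- function(points, bandwidths = NULL, mass = 0.95,
                              n_support = 10000, seed = 1) {
  pts <- dplyr::select(tibble::as_tibble(points), dplyr::where(is.numeric))
  pts <- pts[setdiff(names(pts), "group")]
  stopifnot(ncol(pts) >= 2, mass > 0, mass < 1, n_support >= 100)
  X <- as.matrix(pts)
  if (nrow(unique(pts)) < 2)
    stop("degenerate cloud: all points identical", call. = FALSE)
  axes <- colnames(X)
  if (is.null(bandwidths)) bandwidths <- estimate_bandwidth(pts)
  bandwidths <- bandwidths[axes]
  stopifnot(all(bandwidths > 0))
  lo <- apply(X, 2, min) - 3 * bandwidths
  hi <- apply(X, 2, max) + 3 * bandwidths
  box_vol <- prod(hi - lo)
  set.seed(as.integer(seed))
  U <- matrix(stats::runif(n_support * ncol(X)), n_support)
  Q <- sweep(sweep(U, 2, hi - lo, "*"), 2, lo, "+")
  colnames(Q) <- axes
  dens <- kde_density(Q, X, bandwidths)
  # Mass above threshold t: integral over {f >= t} estimated by the
  # uniform sample; pick the largest t enclosing `mass` of the total.
  ord <- order(dens, decreasing = TRUE)
  cum_mass <- cumsum(dens[ord]) * box_vol / n_support
  total <- cum_mass[n_support]
  k <- which(cum_mass >= mass * total)[1]
  threshold <- dens[ord[k]]
  keep <- dens >= threshold
  structure(list(
    axes = axes, bandwidths = bandwidths, threshold = threshold,
    support_points = tibble::as_tibble(as.data.frame(Q[keep, , drop = FALSE])),
    volume = box_vol * mean(keep),
    centroid = colMeans(Q[keep, , drop = FALSE]),
    data = pts, mass = mass, n_support = n_support, seed = seed),
    class = "hypervolume_kde")
}

#' @export
print.hypervolume_kde <- function(x, ...) {
  cat(sprintf("<hypervolume_kde> %d axes (%s), volume %.4g at mass %.2f\n",
              length(x$axes), paste(x$axes, collapse = ", "), x$volume,
              x$mass))
  cat(sprintf("  %d support points, seed %d\n", nrow(x$support_points),
              x$seed))
  invisible(x)
}

#' Sorensen overlap between two hypervolumes
#'
#' Estimates the intersection volume by mutual inclusion — the average
#' of (fraction of a's support points whose density under b's KDE
#' reaches b's threshold) times a's volume, and the converse — and
#' returns `2 V_int / (V_a + V_b)` in `[0, 1]`.
#'
#' @param a,b `hypervolume_kde` objects on the same axes.
#' @return Sorensen similarity in `[0, 1]`.
#' @export
overlap_sorensen <- function(a, b) {
  check_same_axes(a, b)
  in_other <- function(hv, other) {
    q <- as.matrix(hv$support_points)
    if (nrow(q) == 0) return(0)
    mean(kde_density(q, as.matrix(other$data), other$bandwidths) >=
           other$threshold)
  }
  v_int <- (in_other(a, b) * a$volume + in_other(b, a) * b$volume) / 2
  min(1, max(0, 2 * v_int / (a$volume + b$volume)))
}

#' Centroid distance between two hypervolumes
#'
#' Euclidean distance between the support-point centroids (or the raw
#' observation centroids with `use = "observations"`), in pooled
#' standard-deviation units.
#'
#' @param a,b `hypervolume_kde` objects on the same axes.
#' @param use `"support"` (default) or `"observations"`.
#' @return Nonnegative distance; exactly symmetric in its arguments.
#' @export
centroid_distance <- function(a, b, use = c("support", "observations")) {
  use <- match.arg(use)
  check_same_axes(a, b)
  ca <- if (use == "support") a$centroid else colMeans(a$data)
  cb <- if (use == "support") b$centroid else colMeans(b$data)
  sqrt(sum((ca - cb)^2))
}

check_same_axes <- function(a, b) {
  stopifnot(inherits(a, "hypervolume_kde"), inherits(b, "hypervolume_kde"))
  if (!identical(a$axes, b$axes))
    stop("hypervolumes are built on different axes", call. = FALSE)
  invisible(TRUE)
}

#' Pairwise niche comparison across groups
#'
#' Standardizes all groups with pooled z-scores, builds one hypervolume
#' per group, and fills the conventional comparison matrix: Sorensen
#' index above the diagonal, centroid Euclidean distance below.
#'
#' @param groups tibble with `group` plus numeric axis columns.
#' @param mass,n_support,seed passed to [build_hypervolume()]; each
#'   group's hypervolume gets a seed derived from `seed`.
#' @param bandwidth_method passed to [estimate_bandwidth()].
#' @return An object of class `niche_comparison`: `matrix` (Sorensen
#'   above / distance below the diagonal), `sorensen` and `distance`
#'   (full symmetric matrices), `hypervolumes` (named list), `tidy`
#'   (long tibble with `group1`, `group2`, `sorensen`, `distance`).
#' @export
pairwise_compare <- function(groups, mass = 0.95, n_support = 10000,
                             seed = 1,
                             bandwidth_method = "cross-validation") {
  std <- standardize_niche(groups)
  gs <- sort(unique(std$data$group))
  stopifnot(length(gs) >= 2)
  set.seed(as.integer(seed))
  hv_seeds <- sample.int(.Machine$integer.max, length(gs))
  hvs <- purrr::map2(gs, hv_seeds, function(g, s) {
    pts <- dplyr::filter(std$data, .data$group == g)
    bw <- estimate_bandwidth(pts, method = bandwidth_method)
    build_hypervolume(pts, bandwidths = bw, mass = mass,
                      n_support = n_support, seed = s)
  })
  names(hvs) <- gs
  k <- length(gs)
  sor <- dist <- matrix(NA_real_, k, k, dimnames = list(gs, gs))
  diag(sor) <- 1; diag(dist) <- 0
  long <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    s <- overlap_sorensen(hvs[[i]], hvs[[j]])
    d <- centroid_distance(hvs[[i]], hvs[[j]])
    sor[i, j] <- sor[j, i] <- s
    dist[i, j] <- dist[j, i] <- d
    long[[length(long) + 1]] <- tibble::tibble(
      group1 = gs[i], group2 = gs[j], sorensen = s, distance = d)
  }
  display <- sor
  display[lower.tri(display)] <- dist[lower.tri(dist)]
  diag(display) <- NA_real_
  structure(list(matrix = display, sorensen = sor, distance = dist,
                 hypervolumes = hvs, tidy = dplyr::bind_rows(long),
                 standardization = std[c("center", "scale")],
                 mass = mass, n_support = n_support, seed = seed),
            class = "niche_comparison")
}

#' @export
print.niche_comparison <- function(x, ...) {
  cat("<niche_comparison> Sorensen above diagonal, centroid distance below\n")
  print(round(x$matrix, 4))
  invisible(x)
}
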
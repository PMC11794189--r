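#' Fit a maximum-entropy SDM from raw value tables
#'
#' Convenience wrapper around [build_features()] + [fit_maxent()]:
#' feature scalings are frozen on the background table, presences are
#' expanded with the same scalings, and background variable means are
#' stored on the model so [response_curve()] can hold covariates at
#' their background averages.
#'
#' @param presence_values,background_values data frames of raw
#'   covariate values (coordinate columns `lon`/`lat`/`row`/`col` are
#'   ignored).
#' @param fc_set feature classes, subset of `c("L", "Q", "H", "P")`.
#' @param rm regularization multiplier.
#' @param n_knots hinge knots per direction per variable.
#' @param ... passed on to [fit_maxent()].
#' @return A `maxent_model` (see [fit_maxent()]) carrying the feature
#'   spec and background covariate means.
#' @export
fit_sdm <- function(presence_values, background_values,
                    fc_set = c("L", "Q"), rm = 1, n_knots = 20, ...) {
  bg <- build_features(background_values, fc_set = fc_set, n_knots = n_knots)
  pr <- build_features(presence_values, spec = bg$spec)
  model <- fit_maxent(pr, bg, rm = rm, ...)
  vars <- names(bg$spec$ranges)
  bv <- dplyr::select(tibble::as_tibble(background_values),
                      dplyr::all_of(vars))
  model$background_means <- colMeans(bv)
  model
}

default_fc_grid <- function() {
  list(L = "L", LQ = c("L", "Q"), H = "H", LQH = c("L", "Q", "H"),
       LQHP = c("L", "Q", "H", "P"))
}

#' Tune regularization multiplier and feature classes by AICc
#'
#' Fits one model per (feature-class set, regularization multiplier)
#' candidate on all presences and scores each with the small-sample
#' Akaike criterion `AICc = 2K - 2 logLik + 2K(K+1)/(n - K - 1)`,
#' where `K` counts nonzero coefficients (`|beta| > 1e-8`), `logLik`
#' is the presence log-likelihood of the background-normalized raw
#' density, and `n` is the presence count. Candidates with
#' `n <= K + 1` are marked invalid and excluded from selection. The
#' selected model has `dAICc = 0`; ties break toward smaller `K`, then
#' lower `rm`, then feature-class order. The default grids (12
#' multipliers x 5 class sets) enumerate 60 candidates.
#'
#' @param presence_values,background_values raw covariate tables.
#' @param rm_grid regularization multipliers (default 0.5 to 6 by 0.5).
#' @param fc_grid named list of feature-class sets (default L, LQ, H,
#'   LQH, LQHP).
#' @param n_knots,max_iterations,tolerance passed to [fit_sdm()].
#' @return An object of class `maxent_tuning`: `candidates` tibble
#'   (`fc`, `rm`, `K`, `log_lik`, `AICc`, `dAICc`, `valid`,
#'   `selected`), the `selected` index and the refitted `best_model`.
#' @export
tune_sdm <- function(presence_values, background_values,
                     rm_grid = seq(0.5, 6, by = 0.5),
                     fc_grid = default_fc_grid(),
                     n_knots = 20, max_iterations = 500, tolerance = 1e-5) {
  stopifnot(length(rm_grid) >= 1, length(fc_grid) >= 1)
  if (is.null(names(fc_grid)))
    names(fc_grid) <- vapply(fc_grid, paste, character(1), collapse = "")
  grid <- tidyr::expand_grid(fc = names(fc_grid), rm = rm_grid)
  n <- nrow(tibble::as_tibble(presence_values))
  fits <- purrr::pmap(grid, function(fc, rm) {
    fit_sdm(presence_values, background_values, fc_set = fc_grid[[fc]],
            rm = rm, n_knots = n_knots, max_iterations = max_iterations,
            tolerance = tolerance)
  })
  cand <- dplyr::mutate(grid,
    K = vapply(fits, function(m) sum(abs(m$beta) > 1e-8), integer(1)),
    log_lik = vapply(fits, function(m) m$log_lik, numeric(1)),
    valid = n > .data$K + 1,
    AICc = ifelse(.data$valid,
                  2 * .data$K - 2 * .data$log_lik +
                    2 * .data$K * (.data$K + 1) / (n - .data$K - 1),
                  NA_real_))
  if (!any(cand$valid))
    stop("all tuning candidates are invalid (n <= K + 1)", call. = FALSE)
  cand$dAICc <- cand$AICc - min(cand$AICc, na.rm = TRUE)
  ord <- order(!cand$valid, cand$dAICc, cand$K, cand$rm,
               match(cand$fc, names(fc_grid)))
  sel <- ord[1]
  cand$selected <- seq_len(nrow(cand)) == sel
  structure(list(candidates = cand, selected = sel,
                 best_model = fits[[sel]], n_presence = n,
                 fc_grid = fc_grid, rm_grid = rm_grid),
            class = "maxent_tuning")
}

#' @export
print.maxent_tuning <- function(x, ...) {
  b <- x$candidates[x$selected, ]
  cat(sprintf("<maxent_tuning> %d candidate(s); selected fc = %s, rm = %.2g (K = %d, AICc = %.2f)\n",
              nrow(x$candidates), b$fc[1], b$rm[1], b$K[1], b$AICc[1]))
  invisible(x)
}

#' Bootstrap replicate fits
#'
#' Each replicate resamples the presences with replacement, splits the
#' resample 75/25 into train/test, fits on the train portion and scores
#' the held-out test presences against the background (AUC). When a
#' projection stack is supplied, the replicate cloglog maps are
#' averaged into a final suitability surface.
#'
#' @param presence_values,background_values raw covariate tables.
#' @param n_reps number of bootstrap replicates (default 10).
#' @param seed integer seed.
#' @param stack optional [raster_stack()] to project each replicate onto.
#' @param train_fraction train share within each resample.
#' @param ... passed to [fit_sdm()] (e.g. `fc_set`, `rm`).
#' @return A list of class `sdm_bootstrap`: `auc` (per-replicate test
#'   AUC), `mean_map` (averaged cloglog [raster_grid()] or `NULL`),
#'   `models` (per-replicate fits).
#' @export
bootstrap_replicates <- function(presence_values, background_values,
                                 n_reps = 10, seed = 1, stack = NULL,
                                 train_fraction = 0.75, ...) {
  stopifnot(n_reps >= 1)
  pv <- tibble::as_tibble(presence_values)
  n <- nrow(pv)
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)
  proj_tbl <- if (!is.null(stack)) as_tibble.raster_stack(stack)
  acc <- NULL
  auc <- numeric(n_reps)
  models <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    res <- pv[sample.int(n, n, replace = TRUE), , drop = FALSE]
    n_train <- max(1L, min(n - 1L, round(n * train_fraction)))
    idx <- sample.int(n, n_train)
    model <- fit_sdm(res[idx, , drop = FALSE], background_values, ...)
    test <- res[-idx, , drop = FALSE]
    bg_scores <- predict_cloglog(model, background_values)
    auc[r] <- evaluate_auc(predict_cloglog(model, test), bg_scores)
    models[[r]] <- model
    if (!is.null(proj_tbl)) {
      p <- predict_cloglog(model, proj_tbl)
      acc <- if (is.null(acc)) p else acc + p
    }
  }
  mean_map <- NULL
  if (!is.null(proj_tbl)) {
    tpl <- stack_template(stack)
    m <- matrix(NA_real_, nrow(tpl$values), ncol(tpl$values))
    m[cbind(proj_tbl$row, proj_tbl$col)] <- acc / n_reps
    gt <- tpl$geotransform
    mean_map <- raster_grid(m, west = gt[["west"]], north = gt[["north"]],
                            dx = gt[["dx"]], dy = gt[["dy"]])
  }
  structure(list(auc = auc, mean_map = mean_map, models = models,
                 n_reps = n_reps, seed = seed),
            class = "sdm_bootstrap")
}

#' @export
print.sdm_bootstrap <- function(x, ...) {
  cat(sprintf("<sdm_bootstrap> %d replicate(s), mean test AUC = %.3f (sd %.3f)\n",
              x$n_reps, mean(x$auc), stats::sd(x$auc)))
  invisible(x)
}

#' Percent contribution of each variable
#'
#' Attributes the positive penalized-objective increments recorded
#' during coordinate updates to the updated feature's parent
#' variable(s) — product features split 50/50 — and normalizes to
#' percentages summing to 100.
#'
#' @param model a `maxent_model` fitted through [fit_sdm()] (so the
#'   feature spec is available).
#' @return A tibble with `variable` and `contribution` (percent),
#'   sorted decreasing.
#' @export
variable_contributions <- function(model) {
  stopifnot(inherits(model, "maxent_model"))
  if (is.null(model$spec))
    stop("model carries no feature spec", call. = FALSE)
  parents <- feature_parents(model$spec)
  inc <- model$gain_increments
  vars <- names(model$spec$ranges)
  contrib <- stats::setNames(numeric(length(vars)), vars)
  for (j in seq_along(inc)) {
    p <- parents[[j]]
    contrib[p] <- contrib[p] + inc[j] / length(p)
  }
  if (sum(contrib) <= 0) {
    warning("zero total gain; attributing uniformly", call. = FALSE)
    contrib[] <- 1
  }
  dplyr::arrange(
    tibble::tibble(variable = names(contrib),
                   contribution = unname(100 * contrib / sum(contrib))),
    dplyr::desc(.data$contribution))
}

#' Jackknife gain analysis
#'
#' Refits the model with each variable alone and with each variable
#' excluded, reporting training gains — the standard "with only" /
#' "without" importance diagnostic.
#'
#' @param presence_values,background_values raw covariate tables.
#' @param variables variables to jackknife (default: all shared numeric
#'   columns).
#' @param ... passed to [fit_sdm()].
#' @return A tibble with `variable`, `gain_with_only`, `gain_without`,
#'   plus attribute `"full_gain"` (training gain of the full model).
#' @export
jackknife_gain <- function(presence_values, background_values,
                           variables = NULL, ...) {
  bv <- dplyr::select(tibble::as_tibble(background_values),
                      dplyr::where(is.numeric),
                      -dplyr::any_of(c("row", "col", "lon", "lat")))
  variables <- variables %||% names(bv)
  stopifnot(length(variables) >= 2)
  pv <- tibble::as_tibble(presence_values)
  gain <- function(vars) {
    fit_sdm(dplyr::select(pv, dplyr::all_of(vars)),
            dplyr::select(bv, dplyr::all_of(vars)), ...)$training_gain
  }
  out <- purrr::map_dfr(variables, function(v) tibble::tibble(
    variable = v,
    gain_with_only = gain(v),
    gain_without = gain(setdiff(variables, v))))
  attr(out, "full_gain") <- gain(variables)
  out
}

#' Response curve of one variable
#'
#' Sweeps a variable across its background range at `n_points` equally
#' spaced values with all other variables held at their background
#' means, and reports the model's cloglog output.
#'
#' @param model a `maxent_model` from [fit_sdm()].
#' @param variable variable name.
#' @param n_points number of sweep points.
#' @return A tibble with `value` and `cloglog`.
#' @export
response_curve <- function(model, variable, n_points = 100) {
  stopifnot(inherits(model, "maxent_model"))
  if (is.null(model$spec) || is.null(model$background_means))
    stop("model must be fitted through fit_sdm()", call. = FALSE)
  vars <- names(model$spec$ranges)
  if (!variable %in% vars)
    stop("unknown variable '", variable, "'", call. = FALSE)
  r <- model$spec$ranges[[variable]]
  sweep_vals <- seq(r[1], r[2], length.out = n_points)
  tbl <- tibble::as_tibble(purrr::map(model$background_means[vars],
                                      rep, times = n_points))
  tbl[[variable]] <- sweep_vals
  tibble::tibble(value = sweep_vals, cloglog = predict_cloglog(model, tbl))
}
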
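#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted maximum-entropy model
#'
#' @param x a `maxent_model`.
#' @param ... unused.
#' @return One row per feature: `feature`, `class`, `parent1`,
#'   `parent2`, `knot`, `estimate`, `penalty`.
#' @export
tidy.maxent_model <- function(x, ...) {
  base <- if (!is.null(x$spec)) x$spec$features
  else tibble::tibble(name = names(x$beta) %||%
                        paste0("f", seq_along(x$beta)),
                      class = x$classes, parent1 = NA_character_,
                      parent2 = NA_character_, knot = NA_real_,
                      direction = NA_character_)
  dplyr::mutate(dplyr::rename(base, feature = "name"),
                estimate = unname(x$beta), penalty = unname(x$lambda))
}

#' @rdname tidy.maxent_model
#' @export
glance.maxent_model <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$beta), n_nonzero = sum(abs(x$beta) > 1e-8),
    rm = x$rm, n_presence = x$n_presence, n_background = x$n_background,
    training_gain = x$training_gain, log_lik = x$log_lik,
    entropy = x$H_raw, converged = x$converged, iterations = x$iterations)
}

#' Tidy a tuning-grid result
#'
#' @param x a `maxent_tuning` from [tune_sdm()].
#' @param ... unused.
#' @return The candidate table (`fc`, `rm`, `K`, `log_lik`, `AICc`,
#'   `dAICc`, `valid`, `selected`).
#' @export
tidy.maxent_tuning <- function(x, ...) x$candidates

#' @rdname tidy.maxent_tuning
#' @export
glance.maxent_tuning <- function(x, ...) {
  b <- x$candidates[x$selected, ]
  tibble::tibble(n_candidates = nrow(x$candidates),
                 n_valid = sum(x$candidates$valid),
                 fc = b$fc, rm = b$rm, K = b$K, AICc = b$AICc,
                 n_presence = x$n_presence)
}

#' Tidy bootstrap replicates
#'
#' @param x an `sdm_bootstrap`.
#' @param ... unused.
#' @return One row per replicate with its test AUC.
#' @export
tidy.sdm_bootstrap <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$auc), auc = x$auc)
}

#' @rdname tidy.sdm_bootstrap
#' @export
glance.sdm_bootstrap <- function(x, ...) {
  tibble::tibble(n_reps = x$n_reps, mean_auc = mean(x$auc),
                 sd_auc = stats::sd(x$auc), seed = x$seed)
}

#' Tidy a niche comparison
#'
#' @param x a `niche_comparison` from [pairwise_compare()].
#' @param ... unused.
#' @return Long tibble with `group1`, `group2`, `sorensen`, `distance`.
#' @export
tidy.niche_comparison <- function(x, ...) x$tidy

#' @rdname tidy.niche_comparison
#' @export
glance.niche_comparison <- function(x, ...) {
  tibble::tibble(n_groups = length(x$hypervolumes), mass = x$mass,
                 n_support = x$n_support, seed = x$seed)
}

#' Tidy a risk simulation result
#'
#' @param x a `risk_result` from [run_scenario()].
#' @param ... unused.
#' @return The per-quantity summary table (see [summarize_risk()]).
#' @export
tidy.risk_result <- function(x, ...) x$summary

#' @rdname tidy.risk_result
#' @export
glance.risk_result <- function(x, ...) {
  tibble::tibble(n_iterations = x$config$n_iterations,
                 seed = x$config$seed, D = x$config$D)
}

#' Tidy a scenario comparison
#'
#' @param x a `scenario_comparison` from [compare_scenarios()].
#' @param ... unused.
#' @return Long tibble with `scenario`, `label`, `area_1e4_km2`,
#'   `pct_change`.
#' @export
tidy.scenario_comparison <- function(x, ...) x$table

#' Write the triangular comparison matrix as CSV
#'
#' Writes (and reads back) the conventional layout with Sorensen above
#' the diagonal and centroid distance below it.
#'
#' @param x a `niche_comparison` or the `matrix` element of one.
#' @param path output CSV path.
#' @return `path`, invisibly; `read_comparison_matrix()` returns the
#'   numeric matrix with group dimnames.
#' @export
write_comparison_matrix <- function(x, path) {
  m <- if (inherits(x, "niche_comparison")) x$matrix else as.matrix(x)
  df <- data.frame(group = rownames(m), m, check.names = FALSE)
  readr::write_csv(df, path, na = "")
  invisible(path)
}

#' @rdname write_comparison_matrix
#' @export
read_comparison_matrix <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$group
  m
}
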
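#' Feature expansion for maximum-entropy models
#'
#' Expands raw covariates into the bounded feature classes used by
#' presence-background maximum-entropy models:
#' \describe{
#'   \item{L}{the variable min-max scaled to `[0, 1]` over the
#'     background range;}
#'   \item{Q}{the square of the scaled variable;}
#'   \item{P}{pairwise products of scaled variables;}
#'   \item{H}{forward hinges `max(0, (x - k) / (x_max - k))` and reverse
#'     hinges `max(0, (k - x) / (k - x_min))` with knots `k` at equally
#'     spaced quantiles of the background values.}
#' }
#' All features are bounded in `[0, 1]`. Scalings (background min/max,
#' knots) are frozen into the returned spec so presence and projection
#' data are expanded identically.
#'
#' @param values data frame of raw covariate values (the background
#'   table when `spec = NULL`).
#' @param fc_set feature classes, a subset of `c("L", "Q", "H", "P")`.
#' @param n_knots hinge knots per direction per variable (>= 2).
#' @param spec a `feature_spec` from a previous call; when supplied,
#'   `values` is expanded with the frozen scalings instead of new ones.
#' @return A list with `X` (numeric feature matrix) and `spec` (a
#'   `feature_spec`: per-feature parent variable(s), class, scaling,
#'   knot).
#' @export
build_features <- function(values, fc_set = c("L", "Q"), n_knots = 20,
                           spec = NULL) {
  values <- dplyr::select(tibble::as_tibble(values), dplyr::where(is.numeric),
                          -dplyr::any_of(c("row", "col", "lon", "lat")))
  if (!is.null(spec)) return(expand_with_spec(values, spec))
  stopifnot(nrow(values) >= 2, length(fc_set) >= 1,
            all(fc_set %in% c("L", "Q", "H", "P")))
  if ("H" %in% fc_set) stopifnot(n_knots >= 2)
  vars <- names(values)
  rng <- purrr::map(values, range)
  const <- vapply(rng, function(r) diff(r) == 0, logical(1))
  if (any(const)) {
    warning("zero-variance variable(s) omitted from features: ",
            paste(vars[const], collapse = ", "), call. = FALSE)
    vars <- vars[!const]
  }
  feats <- list()
  add <- function(parents, class, knot = NA_real_, direction = NA_character_) {
    feats[[length(feats) + 1]] <<- tibble::tibble(
      name = paste0(class, ":", paste(parents, collapse = "*"),
                    if (!is.na(knot)) sprintf(":%s:%.6g", direction, knot) else ""),
      class = class, parent1 = parents[1],
      parent2 = if (length(parents) > 1) parents[2] else NA_character_,
      knot = knot, direction = direction)
  }
  for (v in vars) if ("L" %in% fc_set) add(v, "L")
  for (v in vars) if ("Q" %in% fc_set) add(v, "Q")
  if ("H" %in% fc_set) {
    for (v in vars) {
      qs <- stats::quantile(values[[v]], probs = seq(0, 1, length.out = n_knots + 2),
                            names = FALSE)
      knots <- unique(qs[-c(1, length(qs))])
      knots <- knots[knots > rng[[v]][1] & knots < rng[[v]][2]]
      for (k in knots) {
        add(v, "H", knot = k, direction = "fwd")
        add(v, "H", knot = k, direction = "rev")
      }
    }
  }
  if ("P" %in% fc_set && length(vars) >= 2) {
    cmb <- utils::combn(vars, 2)
    for (j in seq_len(ncol(cmb))) add(cmb[, j], "P")
  }
  spec <- structure(list(features = dplyr::bind_rows(feats),
                         ranges = rng[vars], fc_set = fc_set),
                    class = "feature_spec")
  expand_with_spec(values, spec)
}

expand_with_spec <- function(values, spec) {
  ft <- spec$features
  scale_l <- function(v) {
    r <- spec$ranges[[v]]
    (values[[v]] - r[1]) / (r[2] - r[1])
  }
  cols <- purrr::pmap(ft, function(name, class, parent1, parent2, knot,
                                   direction) {
    switch(class,
      L = scale_l(parent1),
      Q = scale_l(parent1)^2,
      P = scale_l(parent1) * scale_l(parent2),
      H = {
        r <- spec$ranges[[parent1]]
        x <- values[[parent1]]
        if (direction == "fwd") pmax(0, (x - knot) / (r[2] - knot))
        else pmax(0, (knot - x) / (knot - r[1]))
      })
  })
  X <- do.call(cbind, cols)
  colnames(X) <- ft$name
  list(X = X, spec = spec)
}

#' @export
print.feature_spec <- function(x, ...) {
  cat(sprintf("<feature_spec> %d features (%s) over %d variable(s)\n",
              nrow(x$features), paste(x$fc_set, collapse = ""),
              length(x$ranges)))
  invisible(x)
}

# Parent variables of each feature, for contribution bookkeeping.
feature_parents <- function(spec) {
  ft <- spec$features
  purrr::map2(ft$parent1, ft$parent2,
              function(a, b) if (is.na(b)) a else c(a, b))
}
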
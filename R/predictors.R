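#' Extract raster values at occurrence points
#'
#' Looks up each layer of the stack at each point. Points outside the
#' stack extent or on masked cells are dropped (never returned as
#' `NA` rows) and counted in the attached report.
#'
#' @param stack a [raster_stack()].
#' @param points tibble with `lon`, `lat` columns; extra columns (e.g.
#'   `group`) are carried through.
#' @return A tibble with the input columns of retained points followed
#'   by one column per layer; attribute `"report"` counts `n_in`,
#'   `n_kept`, `n_outside`, `n_masked`.
#' @export
extract_values <- function(stack, points) {
  stopifnot(inherits(stack, "raster_stack"), is.data.frame(points),
            all(c("lon", "lat") %in% names(points)))
  tpl <- stack_template(stack)
  loc <- locate_cells(tpl, points$lon, points$lat)
  outside <- is.na(loc$row)
  masked <- !outside & is.na(tpl$values[cbind(loc$row, loc$col)])
  keep <- !outside & !masked
  if (!any(keep))
    stop("no points fall on unmasked cells of the stack", call. = FALSE)
  ij <- cbind(loc$row[keep], loc$col[keep])
  vals <- purrr::map(stack$layers, function(g) g$values[ij])
  out <- dplyr::bind_cols(tibble::as_tibble(points[keep, , drop = FALSE]),
                          tibble::as_tibble(vals))
  attr(out, "report") <- list(n_in = nrow(points), n_kept = sum(keep),
                              n_outside = sum(outside), n_masked = sum(masked))
  out
}

#' Pairwise-correlation variable screen
#'
#' Greedy collinearity filter: while any retained pair has
#' `|Pearson r| >= threshold`, drop one member of the worst pair — the
#' variable with the larger mean absolute correlation to all other
#' retained variables, unless a `keep_priority` ordering dictates
#' otherwise. Zero-variance variables are dropped first. Deterministic:
#' ties break by variable name order.
#'
#' @param values data frame of candidate variables (columns) over
#'   observations (rows) — typically all unmasked stack cells via
#'   [as_tibble.raster_stack()], or values at occurrence points.
#' @param threshold retained pairs must satisfy `|r| <` this (default
#'   0.8, the conventional collinearity cutoff).
#' @param keep_priority optional character vector; earlier names win
#'   conflicts.
#' @return A list of class `screen_report`: `retained` (names),
#'   `dropped` (tibble with `name`, `reason`, `partner`, `abs_r`) and
#'   `threshold`.
#' @export
correlation_screen <- function(values, threshold = 0.8, keep_priority = NULL) {
  values <- dplyr::select(tibble::as_tibble(values),
                          dplyr::where(is.numeric), -dplyr::any_of(
                            c("row", "col", "lon", "lat")))
  stopifnot(ncol(values) >= 2, nrow(values) >= 3, threshold > 0)
  vars <- names(values)
  dropped <- tibble::tibble(name = character(), reason = character(),
                            partner = character(), abs_r = numeric())
  sds <- vapply(values, stats::sd, numeric(1))
  for (v in sort(vars[sds == 0])) {
    dropped <- dplyr::add_row(dropped, name = v, reason = "zero variance",
                              partner = NA_character_, abs_r = NA_real_)
  }
  retained <- setdiff(vars, dropped$name)
  cm <- abs(stats::cor(values[retained]))
  diag(cm) <- 0
  prio <- function(v) {
    p <- match(v, keep_priority)
    ifelse(is.na(p), Inf, p)
  }
  while (length(retained) > 1 && max(cm) >= threshold) {
    worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    a <- retained[worst[1]]; b <- retained[worst[2]]
    pa <- prio(a); pb <- prio(b)
    if (pa != pb) {
      drop <- if (pa > pb) a else b
    } else {
      ma <- mean(cm[a, ]); mb <- mean(cm[b, ])
      drop <- if (ma > mb) a else if (mb > ma) b else sort(c(a, b))[2]
    }
    partner <- setdiff(c(a, b), drop)
    dropped <- dplyr::add_row(dropped, name = drop,
                              reason = "high correlation",
                              partner = partner, abs_r = max(cm))
    retained <- setdiff(retained, drop)
    cm <- cm[retained, retained, drop = FALSE]
  }
  structure(list(retained = retained, dropped = dropped,
                 threshold = threshold),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("<screen_report> %d retained, %d dropped (|r| < %.2f)\n",
              length(x$retained), nrow(x$dropped), x$threshold))
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  if (nrow(x$dropped)) {
    cat("  dropped:\n")
    for (i in seq_len(nrow(x$dropped)))
      cat(sprintf("    %s (%s%s)\n", x$dropped$name[i], x$dropped$reason[i],
                  if (!is.na(x$dropped$abs_r[i]))
                    sprintf(", |r|=%.3f with %s", x$dropped$abs_r[i],
                            x$dropped$partner[i]) else ""))
  }
  invisible(x)
}

#' @export
tidy.screen_report <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(name = x$retained, status = "retained",
                   reason = NA_character_, partner = NA_character_,
                   abs_r = NA_real_),
    dplyr::mutate(x$dropped, status = "dropped", .after = "name"))
}
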
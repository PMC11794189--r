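#' Round half away from zero
#'
#' Decimal rounding as printed tables round it: halves go away from
#' zero (base `round()` rounds halves to even).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Minimum training presence threshold
#'
#' The lowest predicted (cloglog) suitability among training presences.
#' By construction every training presence scores at or above it, so
#' thresholding at the MTP classifies all training presences as
#' suitable.
#'
#' @param training_presence_scores numeric scores of training presences.
#' @return The minimum score.
#' @export
mtp_threshold <- function(training_presence_scores) {
  stopifnot(length(training_presence_scores) >= 1,
            !anyNA(training_presence_scores))
  min(training_presence_scores)
}

#' Classify a suitability surface into four classes
#'
#' Reclassifies cloglog suitability into integer codes with half-open
#' intervals (top class closed): `[0, mtp) -> 0` unsuitable,
#' `[mtp, 0.4) -> 1` low, `[0.4, 0.6) -> 2` moderate, `[0.6, 1] -> 3`
#' high. Masked cells stay masked.
#'
#' @param suitability a [raster_grid()] with values in `[0, 1]`.
#' @param mtp threshold in (0, 0.4) separating unsuitable from low.
#' @param mid,high upper bounds of the low and moderate classes.
#' @return An object of class `classified_map` (a [raster_grid()] of
#'   codes with a `thresholds` attribute).
#' @export
classify_suitability <- function(suitability, mtp, mid = 0.4, high = 0.6) {
  stopifnot(inherits(suitability, "raster_grid"), mtp > 0)
  if (mtp >= mid)
    stop("mtp must be below the low/moderate bound (", mid, ")",
         call. = FALSE)
  v <- suitability$values
  ok <- !is.na(v)
  if (any(v[ok] < 0 | v[ok] > 1))
    stop("suitability values must lie in [0, 1]", call. = FALSE)
  cls <- matrix(NA_real_, nrow(v), ncol(v))
  cls[ok] <- findInterval(v[ok], c(mtp, mid, high))
  gt <- suitability$geotransform
  out <- raster_grid(cls, west = gt[["west"]], north = gt[["north"]],
                     dx = gt[["dx"]], dy = gt[["dy"]])
  attr(out, "thresholds") <- c(mtp = mtp, mid = mid, high = high)
  class(out) <- c("classified_map", class(out))
  out
}

class_labels <- c(`0` = "unsuitable", `1` = "low", `2` = "moderate",
                  `3` = "high")

#' Latitude-weighted class areas
#'
#' Sums spherical cell areas (see [cell_area_km2()]) per suitability
#' class and reports them in 10^4 km^2, the conventional reporting
#' unit, together with the total suitable area (classes 1-3).
#'
#' @param classified a `classified_map` from [classify_suitability()].
#' @param weights optional co-registered [raster_grid()] of cell
#'   weights in `[0, 1]` (used by [overlay_crop()]).
#' @return A tibble with `class` (code), `label` and `area_1e4_km2`,
#'   plus a `total` row (classes >= 1).
#' @export
class_areas <- function(classified, weights = NULL) {
  stopifnot(inherits(classified, "classified_map"))
  area <- cell_area_km2(classified)
  if (!is.null(weights)) {
    stopifnot(inherits(weights, "raster_grid"))
    if (!same_geometry(classified, weights))
      stop("weights raster is not co-registered", call. = FALSE)
    area <- area * ifelse(is.na(weights$values), 0, weights$values)
  }
  v <- classified$values
  per <- purrr::map_dbl(0:3, function(k)
    sum(area[!is.na(v) & v == k]) / 1e4)
  tibble::tibble(
    class = c(0:3, NA_integer_),
    label = c(unname(class_labels), "total"),
    area_1e4_km2 = c(per, sum(per[2:4])))
}

#' Restrict class areas to a crop mask
#'
#' Recomputes class areas over crop cells only: binary mode counts
#' cells where the mask is `>= 0.5`; fractional mode weights each
#' cell's area by its crop fraction. Also reports the proportion of
#' the crop area that is suitable (classes >= 1).
#'
#' @param classified a `classified_map`.
#' @param crop_mask a co-registered [raster_grid()] with values in
#'   `[0, 1]`.
#' @param mode `"binary"` (default) or `"fractional"`.
#' @return A list of class `crop_overlay`: `areas` (as [class_areas()]),
#'   `crop_area_1e4_km2`, `proportion_suitable` and
#'   `empty_crop` flag (`TRUE` when the mask selects no area, in which
#'   case the proportion is reported as 0).
#' @export
overlay_crop <- function(classified, crop_mask, mode = c("binary", "fractional")) {
  mode <- match.arg(mode)
  stopifnot(inherits(classified, "classified_map"),
            inherits(crop_mask, "raster_grid"))
  if (!same_geometry(classified, crop_mask))
    stop("crop mask is not co-registered with the classified map",
         call. = FALSE)
  w <- crop_mask$values
  w[is.na(w)] <- 0
  if (mode == "binary") w[] <- as.numeric(w >= 0.5)
  gt <- crop_mask$geotransform
  wgrid <- raster_grid(w, west = gt[["west"]], north = gt[["north"]],
                       dx = gt[["dx"]], dy = gt[["dy"]])
  areas <- class_areas(classified, weights = wgrid)
  area_all <- cell_area_km2(classified)
  crop_total <- sum(area_all[!is.na(classified$values)] *
                      w[!is.na(classified$values)]) / 1e4
  suitable <- areas$area_1e4_km2[areas$label == "total"]
  empty <- crop_total <= 0
  structure(list(
    areas = areas,
    crop_area_1e4_km2 = crop_total,
    proportion_suitable = if (empty) 0 else suitable / crop_total,
    empty_crop = empty, mode = mode),
    class = "crop_overlay")
}

#' @export
print.crop_overlay <- function(x, ...) {
  cat(sprintf("<crop_overlay> crop area %.2f x10^4 km^2; %.1f%% suitable%s\n",
              x$crop_area_1e4_km2, 100 * x$proportion_suitable,
              if (x$empty_crop) " [empty crop mask]" else ""))
  invisible(x)
}

area_vector <- function(x) {
  if (inherits(x, "classified_map")) x <- class_areas(x)
  stopifnot(is.data.frame(x), all(c("label", "area_1e4_km2") %in% names(x)))
  stats::setNames(x$area_1e4_km2, x$label)
}

#' Compare suitability scenarios
#'
#' Builds the change table between a reference (current) and one or
#' more future area tables or classified maps: per-class percent change
#' `100 * (future - reference) / reference` rounded to two decimals,
#' the arithmetic period-average table across the supplied futures with
#' its own percent change, and (for map inputs) a change map coding
#' cells as stable-unsuitable / gain / loss / stable-suitable with
#' suitable meaning class >= 1.
#'
#' @param reference a `classified_map` or [class_areas()] table.
#' @param ... future scenarios of the same type, optionally named.
#' @return A list of class `scenario_comparison`: `table` (long tibble
#'   with `scenario`, `label`, `area_1e4_km2`, `pct_change`; the
#'   average appears as scenario `"average"` when more than one future
#'   is given), and `change_maps` (named list of change-code
#'   [raster_grid()]s, codes 0 stable-unsuitable, 1 gain, 2 loss,
#'   3 stable-suitable) when maps were supplied. Undefined percent
#'   changes (reference 0, future nonzero) are `NA`.
#' @export
compare_scenarios <- function(reference, ...) {
  futures <- list(...)
  stopifnot(length(futures) >= 1)
  if (is.null(names(futures)) || any(names(futures) == ""))
    names(futures) <- paste0("future", seq_along(futures))
  ref_v <- area_vector(reference)
  fut_v <- purrr::map(futures, area_vector)
  pct <- function(fut) {
    out <- round_half_up(100 * (fut - ref_v) / ref_v, 2)
    out[ref_v == 0 & fut != 0] <- NA_real_
    out[ref_v == 0 & fut == 0] <- 0
    out
  }
  rows <- list(tibble::tibble(scenario = "reference", label = names(ref_v),
                              area_1e4_km2 = unname(ref_v),
                              pct_change = NA_real_))
  for (nm in names(fut_v))
    rows[[length(rows) + 1]] <- tibble::tibble(
      scenario = nm, label = names(ref_v),
      area_1e4_km2 = unname(fut_v[[nm]]),
      pct_change = unname(pct(fut_v[[nm]])))
  if (length(fut_v) > 1) {
    avg <- Reduce(`+`, fut_v) / length(fut_v)
    rows[[length(rows) + 1]] <- tibble::tibble(
      scenario = "average", label = names(ref_v),
      area_1e4_km2 = unname(avg), pct_change = unname(pct(avg)))
  }
  change_maps <- NULL
  if (inherits(reference, "classified_map") &&
      all(purrr::map_lgl(futures, inherits, "classified_map"))) {
    change_maps <- purrr::map(futures, function(f) {
      if (!same_geometry(reference, f))
        stop("maps are not co-registered", call. = FALSE)
      rs <- reference$values >= 1
      fs <- f$values >= 1
      code <- matrix(NA_real_, nrow(reference$values), ncol(reference$values))
      ok <- !is.na(rs) & !is.na(fs)
      code[ok] <- ifelse(!rs[ok] & !fs[ok], 0,
                   ifelse(!rs[ok] & fs[ok], 1,
                     ifelse(rs[ok] & !fs[ok], 2, 3)))
      gt <- reference$geotransform
      raster_grid(code, west = gt[["west"]], north = gt[["north"]],
                  dx = gt[["dx"]], dy = gt[["dy"]])
    })
  }
  structure(list(table = dplyr::bind_rows(rows), change_maps = change_maps),
            class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    dplyr::mutate(x$table, cell = ifelse(is.na(.data$pct_change),
      sprintf("%.2f", .data$area_1e4_km2),
      sprintf("%.2f (%.2f)", .data$area_1e4_km2, .data$pct_change))),
    id_cols = "label", names_from = "scenario", values_from = "cell")
  cat("<scenario_comparison> areas x10^4 km^2 (% change vs reference)\n")
  print(as.data.frame(wide), row.names = FALSE)
  invisible(x)
}
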
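#' Read occurrence records from a delimited file
#'
#' Reads point records, validates coordinates (longitude in
#' `[-180, 180]`, latitude in `[-90, 90]`, no missing values) and drops
#' invalid rows, counting them in an attached report.
#'
#' @param source path to a CSV/TSV file.
#' @param lon,lat,group column names in the file holding longitude,
#'   latitude and the optional group label.
#' @return A tibble with columns `lon`, `lat` and (if mapped) `group`,
#'   with attribute `"report"` — a list with `n_read`, `n_kept`,
#'   `n_dropped` and `dropped_reasons` counts.
#' @export
read_occurrences <- function(source, lon = "lon", lat = "lat", group = NULL) {
  stopifnot(file.exists(source))
  raw <- readr::read_csv(source, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  need <- c(lon, lat, group)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("mapped column(s) not in file: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  x <- suppressWarnings(as.numeric(raw[[lon]]))
  y <- suppressWarnings(as.numeric(raw[[lat]]))
  bad_parse <- is.na(x) | is.na(y)
  bad_range <- !bad_parse & (x < -180 | x > 180 | y < -90 | y > 90)
  keep <- !bad_parse & !bad_range
  out <- tibble::tibble(lon = x[keep], lat = y[keep])
  if (!is.null(group)) out$group <- raw[[group]][keep]
  if (nrow(out) == 0)
    stop("no valid occurrence records in ", source, call. = FALSE)
  attr(out, "report") <- list(
    n_read = nrow(raw), n_kept = nrow(out), n_dropped = sum(!keep),
    dropped_reasons = c(unparseable = sum(bad_parse),
                        out_of_range = sum(bad_range)))
  out
}

#' Spatially thin occurrences to one record per raster cell
#'
#' Retains at most one record per cell of the template grid — the first
#' record in input order. Records outside the template extent or on
#' masked (nodata) cells are dropped and counted.
#'
#' @param occ occurrence tibble with `lon`, `lat` columns.
#' @param template a [raster_grid()] defining the thinning cells.
#' @return The thinned tibble, with attribute `"report"` counting
#'   `n_in`, `n_kept`, `n_outside`, `n_masked`, `n_duplicate`.
#' @export
thin_to_grid <- function(occ, template) {
  stopifnot(is.data.frame(occ), all(c("lon", "lat") %in% names(occ)),
            inherits(template, "raster_grid"))
  loc <- locate_cells(template, occ$lon, occ$lat)
  outside <- is.na(loc$row)
  masked <- !outside & is.na(template$values[cbind(loc$row, loc$col)])
  cell_id <- ifelse(outside | masked, NA_integer_,
                    (loc$row - 1L) * ncol(template$values) + loc$col)
  keep <- !outside & !masked & !duplicated(cell_id, incomparables = NA)
  out <- occ[keep, , drop = FALSE]
  attr(out, "report") <- list(
    n_in = nrow(occ), n_kept = nrow(out),
    n_outside = sum(outside), n_masked = sum(masked),
    n_duplicate = sum(!outside & !masked) - nrow(out))
  out
}

#' Split occurrences into training and testing sets
#'
#' Random partition with `round(n * train_fraction)` training records;
#' deterministic given the seed.
#'
#' @param occ occurrence tibble (>= 2 rows).
#' @param train_fraction fraction in (0, 1); 0.75 gives the standard
#'   75/25 split.
#' @param seed integer seed.
#' @return A list with tibbles `train` and `test` (disjoint, exhaustive).
#' @export
split_train_test <- function(occ, train_fraction = 0.75, seed = 1) {
  stopifnot(is.data.frame(occ), nrow(occ) >= 2,
            train_fraction > 0, train_fraction < 1)
  n <- nrow(occ)
  n_train <- round(n * train_fraction)
  n_train <- max(1L, min(n - 1L, n_train))
  set.seed(as.integer(seed))
  idx <- sample.int(n, n_train)
  list(train = occ[sort(idx), , drop = FALSE],
       test = occ[-sort(idx), , drop = FALSE])
}
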
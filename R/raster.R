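#' Gridded raster layers in geographic coordinates
#'
#' A `raster_grid` is a minimal in-memory raster: a numeric matrix in
#' row-major map order (row 1 = northernmost row), a geotransform
#' `(west, north, dx, dy)` in decimal degrees with `dx, dy > 0`, and an
#' implicit nodata mask carried as `NA` cells. A `raster_stack` is an
#' ordered, named collection of co-registered `raster_grid` layers
#' sharing geotransform, shape and mask.
#'
#' Cells are half-open intervals `[west, east) x [south, north)` so that
#' every point inside the extent belongs to exactly one cell.
#'
#' @param values numeric matrix; `NA` marks nodata.
#' @param west,north coordinates of the grid's top-left corner (degrees).
#' @param dx,dy positive cell width and height (degrees).
#' @return `raster_grid()` returns an object of class `raster_grid`.
#' @export
raster_grid <- function(values, west, north, dx, dy) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values) || is.logical(values),
            nrow(values) >= 1, ncol(values) >= 1,
            is.numeric(dx), dx > 0, is.numeric(dy), dy > 0)
  storage.mode(values) <- "double"
  structure(
    list(values = values,
         geotransform = c(west = unname(west), north = unname(north),
                          dx = unname(dx), dy = unname(dy))),
    class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  gt <- x$geotransform
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<raster_grid> %d x %d cells, %.4g x %.4g deg\n",
              nrow(x$values), ncol(x$values), gt["dx"], gt["dy"]))
  cat(sprintf("  extent: lon [%.4f, %.4f], lat [%.4f, %.4f]\n",
              gt["west"], gt["west"] + ncol(x$values) * gt["dx"],
              gt["north"] - nrow(x$values) * gt["dy"], gt["north"]))
  cat(sprintf("  values: [%.4g, %.4g], %d nodata cells\n",
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA,
              sum(is.na(x$values))))
  invisible(x)
}

grid_extent <- function(g) {
  gt <- g$geotransform
  c(west = unname(gt["west"]),
    east = unname(gt["west"] + ncol(g$values) * gt["dx"]),
    south = unname(gt["north"] - nrow(g$values) * gt["dy"]),
    north = unname(gt["north"]))
}

same_geometry <- function(a, b, tol = 1e-9) {
  all(dim(a$values) == dim(b$values)) &&
    all(abs(a$geotransform - b$geotransform) < tol)
}

#' Cell centers of a raster grid
#'
#' @param g a `raster_grid`.
#' @return A tibble with one row per cell in matrix order: `row`, `col`,
#'   `lon`, `lat`, `value`. Nodata cells are included with `value = NA`.
#' @export
cell_centers <- function(g) {
  stopifnot(inherits(g, "raster_grid"))
  gt <- g$geotransform
  nr <- nrow(g$values); nc <- ncol(g$values)
  idx <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  tibble::tibble(
    row = idx$row, col = idx$col,
    lon = gt["west"] + (idx$col - 0.5) * gt["dx"],
    lat = gt["north"] - (idx$row - 0.5) * gt["dy"],
    value = g$values[cbind(idx$row, idx$col)])
}

# Row/col of points under the half-open cell convention; NA for points
# outside the extent.
locate_cells <- function(g, lon, lat) {
  gt <- g$geotransform
  ext <- grid_extent(g)
  j <- floor((lon - gt["west"]) / gt["dx"]) + 1L
  i <- nrow(g$values) - floor((lat - ext["south"]) / gt["dy"])
  inside <- lon >= ext["west"] & lon < ext["east"] &
    lat >= ext["south"] & lat < ext["north"]
  i[!inside] <- NA_integer_; j[!inside] <- NA_integer_
  tibble::tibble(row = as.integer(i), col = as.integer(j))
}

#' Stack of co-registered raster layers
#'
#' @param layers named list of `raster_grid` objects with identical
#'   geometry. Masks are harmonized: a cell that is nodata in any layer
#'   becomes nodata in all.
#' @return An object of class `raster_stack`.
#' @export
raster_stack <- function(layers) {
  stopifnot(is.list(layers), length(layers) >= 1)
  nms <- names(layers)
  if (is.null(nms) || any(nms == "") || anyDuplicated(nms))
    stop("layers must have unique non-empty names", call. = FALSE)
  ok <- vapply(layers, inherits, logical(1), "raster_grid")
  if (!all(ok)) stop("all layers must be raster_grid objects", call. = FALSE)
  for (k in seq_along(layers)[-1]) {
    if (!same_geometry(layers[[1]], layers[[k]]))
      stop("layer '", nms[k], "' is not co-registered with '", nms[1], "'",
           call. = FALSE)
  }
  na_any <- Reduce(`|`, lapply(layers, function(g) is.na(g$values)))
  layers <- lapply(layers, function(g) {
    g$values[na_any] <- NA_real_
    g
  })
  structure(list(layers = layers), class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  g <- x$layers[[1]]
  cat(sprintf("<raster_stack> %d layer(s), %d x %d cells\n",
              length(x$layers), nrow(g$values), ncol(g$values)))
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' @export
names.raster_stack <- function(x) names(x$layers)

stack_template <- function(s) s$layers[[1]]

#' Stack cells as a tibble
#'
#' One row per unmasked cell with the cell center coordinates and one
#' column per layer.
#'
#' @param x a `raster_stack`.
#' @param ... unused.
#' @return A tibble with columns `row`, `col`, `lon`, `lat` and the
#'   layer values.
#' @export
as_tibble.raster_stack <- function(x, ...) {
  cc <- cell_centers(stack_template(x))
  vals <- purrr::map(x$layers, function(g) g$values[cbind(cc$row, cc$col)])
  out <- dplyr::bind_cols(cc[c("row", "col", "lon", "lat")],
                          tibble::as_tibble(vals))
  tidyr::drop_na(out, dplyr::all_of(names(x$layers)))
}

#' @export
as_tibble.raster_grid <- function(x, ...) {
  tidyr::drop_na(cell_centers(x), "value")
}

#' Read and write ESRI ASCII grids
#'
#' Plain-text raster exchange format (`ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value` header followed by rows north to south).
#' Cells must be square.
#'
#' @param path file path.
#' @return `read_ascii_grid()` returns a `raster_grid`.
#' @export
read_ascii_grid <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  hdr <- list(); i <- 0
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && grepl("^[A-Za-z_]+$", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2]); i <- i + 1
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("missing ESRI ASCII header fields: ",
         paste(setdiff(need, names(hdr)), collapse = ", "), call. = FALSE)
  nodata <- hdr[["nodata_value"]] %||% -9999
  body <- scan(text = paste(lines[-seq_len(i)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(body) != nr * nc)
    stop("grid body has ", length(body), " values, expected ", nr * nc,
         call. = FALSE)
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  raster_grid(m, west = hdr$xllcorner,
              north = hdr$yllcorner + nr * hdr$cellsize,
              dx = hdr$cellsize, dy = hdr$cellsize)
}

#' @rdname read_ascii_grid
#' @param g a `raster_grid` with square cells.
#' @param nodata value written for masked cells.
#' @export
write_ascii_grid <- function(g, path, nodata = -9999) {
  stopifnot(inherits(g, "raster_grid"))
  gt <- g$geotransform
  if (abs(gt["dx"] - gt["dy"]) > 1e-12)
    stop("ESRI ASCII grids require square cells", call. = FALSE)
  ext <- grid_extent(g)
  m <- g$values
  m[is.na(m)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(m)),
           sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %.10g", ext["west"]),
           sprintf("yllcorner %.10g", ext["south"]),
           sprintf("cellsize %.10g", gt["dx"]),
           sprintf("NODATA_value %.10g", nodata))
  rows <- apply(m, 1, function(r) paste(format(r, trim = TRUE), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Spherical cell areas of a geographic grid
#'
#' Cell area on the authalic sphere: `R^2 * dlon * (sin(lat_top) -
#' sin(lat_bottom))` with `R = 6371.0088` km, so area depends on the
#' cell's latitude band only.
#'
#' @param g a `raster_grid` in geographic coordinates.
#' @return Numeric matrix of per-cell areas in km^2 (same shape as the
#'   grid; masked cells still get an area — callers subset).
#' @export
cell_area_km2 <- function(g) {
  stopifnot(inherits(g, "raster_grid"))
  gt <- g$geotransform
  ext <- grid_extent(g)
  if (ext["south"] < -90 - 1e-9 || ext["north"] > 90 + 1e-9 ||
      ext["west"] < -360 - 1e-9 || ext["east"] > 360 + 1e-9)
    stop("grid does not look geographic (degrees); projected rasters are not supported",
         call. = FALSE)
  R <- 6371.0088
  nr <- nrow(g$values)
  lat_top <- gt["north"] - (seq_len(nr) - 1) * gt["dy"]
  lat_bot <- lat_top - gt["dy"]
  band <- R^2 * (gt["dx"] * pi / 180) *
    (sin(pmin(lat_top, 90) * pi / 180) - sin(pmax(lat_bot, -90) * pi / 180))
  matrix(band, nrow = nr, ncol = ncol(g$values))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
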
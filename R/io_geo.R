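#' Grid specification for an aligned raster stack
#'
#' A `grid_spec` records the geometry of an ESRI ASCII grid: the number of
#' columns and rows, the lower-left corner, the (uniform) cell size and the
#' nodata sentinel. Two specs are *aligned* when all six fields agree to
#' within 1e-9; every layer entering an [env_stack()] must be aligned.
#'
#' @param ncols,nrows Positive integer grid dimensions.
#' @param xllcorner,yllcorner Coordinates of the lower-left corner of the
#'   lower-left cell, in degrees or map units.
#' @param cellsize Cell edge length in grid units; must be positive.
#' @param nodata_value Sentinel written for masked cells (default -9999).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(ncols, nrows, xllcorner, yllcorner, cellsize,
                      nodata_value = -9999) {
  stopifnot(ncols >= 1, nrows >= 1, cellsize > 0)
  structure(
    list(ncols = as.integer(ncols), nrows = as.integer(nrows),
         xllcorner = as.numeric(xllcorner), yllcorner = as.numeric(yllcorner),
         cellsize = as.numeric(cellsize),
         nodata_value = as.numeric(nodata_value)),
    class = "grid_spec")
}

#' Test whether two grid specs describe the same grid
#'
#' @param a,b `grid_spec` objects.
#' @param tol Numeric tolerance (default 1e-9).
#' @return `TRUE` iff all six fields agree within `tol`.
#' @export
specs_aligned <- function(a, b, tol = 1e-9) {
  stopifnot(inherits(a, "grid_spec"), inherits(b, "grid_spec"))
  all(abs(unlist(a) - unlist(b)) <= tol)
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d cols x %d rows, cellsize %g, ll (%g, %g), nodata %g\n",
              x$ncols, x$nrows, x$cellsize, x$xllcorner, x$yllcorner,
              x$nodata_value))
  invisible(x)
}

#' Construct a raster layer
#'
#' A `raster_layer` is a named matrix of values on a [grid_spec()] grid.
#' Row 1 of the matrix is the northernmost row (ESRI ASCII convention).
#' Masked cells are stored as `NA`; the nodata sentinel appears only on
#' disk. Categorical layers must hold integer codes.
#'
#' @param name Layer identifier.
#' @param spec A `grid_spec`.
#' @param values `nrows x ncols` numeric matrix; `NA` marks masked cells.
#' @param kind `"continuous"` or `"categorical"`.
#' @return An object of class `raster_layer`.
#' @export
raster_layer <- function(name, spec, values, kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  stopifnot(inherits(spec, "grid_spec"), is.matrix(values))
  if (nrow(values) != spec$nrows || ncol(values) != spec$ncols)
    stop("values matrix is ", nrow(values), "x", ncol(values),
         " but spec declares ", spec$nrows, "x", spec$ncols)
  if (kind == "categorical") {
    v <- values[is.finite(values)]
    if (length(v) && any(v != round(v)))
      stop("categorical layer '", name, "' contains non-integer codes")
  }
  structure(list(name = as.character(name), spec = spec,
                 values = values, kind = kind),
            class = "raster_layer")
}

#' @export
print.raster_layer <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<raster_layer> '%s' (%s), %d x %d, %d valid cells, range [%g, %g]\n",
              x$name, x$kind, x$spec$nrows, x$spec$ncols, length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Bundle aligned raster layers into an environmental stack
#'
#' @param layers List of [raster_layer()] objects sharing one grid; names
#'   must be unique.
#' @return An object of class `env_stack` with elements `layers` (named
#'   list) and `spec`.
#' @export
env_stack <- function(layers) {
  stopifnot(length(layers) >= 1,
            all(vapply(layers, inherits, logical(1), "raster_layer")))
  nms <- vapply(layers, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate layer names: ",
                               paste(unique(nms[duplicated(nms)]), collapse = ", "))
  spec <- layers[[1]]$spec
  ok <- vapply(layers, function(l) specs_aligned(l$spec, spec), logical(1))
  if (!all(ok)) stop("layers not aligned to a common grid: ",
                     paste(nms[!ok], collapse = ", "))
  names(layers) <- nms
  structure(list(layers = layers, spec = spec), class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack> %d layers on a %d x %d grid: %s\n",
              length(x$layers), x$spec$nrows, x$spec$ncols,
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' Shared validity mask of an environmental stack
#'
#' @param stack An `env_stack`.
#' @return Logical matrix, `TRUE` where every layer is valid (finite).
#' @export
valid_mask <- function(stack) {
  stopifnot(inherits(stack, "env_stack"))
  Reduce(`&`, lapply(stack$layers, function(l) is.finite(l$values)))
}

#' Read an ESRI ASCII grid
#'
#' Parses the six-key header (`ncols`, `nrows`, `xllcorner`/`xllcenter`,
#' `yllcorner`/`yllcenter`, `cellsize`, `NODATA_value`; case-insensitive;
#' the nodata key is optional, defaulting to -9999) followed by
#' `nrows * ncols` whitespace-separated values, row 1 = northernmost.
#' Cells equal to the nodata sentinel become `NA`.
#'
#' @param path Path to a `.asc` file.
#' @param name Layer name; default the file name without extension.
#' @param kind `"continuous"` (default) or `"categorical"`.
#' @return A [raster_layer()].
#' @export
read_ascii_grid <- function(path, name = NULL,
                            kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  i <- 1L
  repeat {
    if (i > length(lines)) stop("ASCII grid '", path, "': no data rows found")
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "xllcenter",
                   "yllcorner", "yllcenter", "cellsize", "nodata_value")) {
      if (length(parts) != 2 || is.na(suppressWarnings(as.numeric(parts[2]))))
        stop("ASCII grid '", path, "': malformed header line ", i, ": '",
             lines[i], "'")
      hdr[[key]] <- as.numeric(parts[2])
      i <- i + 1L
    } else break
  }
  for (k in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[k]]))
      stop("ASCII grid '", path, "': header missing required key '", k, "'")
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  cs <- hdr$cellsize
  # centre-registered headers shift to the corner convention
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner
         else if (!is.null(hdr$xllcenter)) hdr$xllcenter - cs / 2
         else stop("ASCII grid '", path, "': header missing xllcorner/xllcenter")
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner
         else if (!is.null(hdr$yllcenter)) hdr$yllcenter - cs / 2
         else stop("ASCII grid '", path, "': header missing yllcorner/yllcenter")
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  rows <- lines[i:length(lines)]
  if (length(rows) != nr)
    stop("ASCII grid '", path, "': header declares ", nr, " rows but ",
         length(rows), " data lines found (line ", i, " onward)")
  vals <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(rows[r]), "\\s+")[[1]]))
    if (length(v) != nc || anyNA(v))
      stop("ASCII grid '", path, "': data line ", i + r - 1L,
           " has ", length(v), " values, expected ", nc)
    vals[r, ] <- v
  }
  vals[vals == nodata] <- NA_real_
  raster_layer(name, grid_spec(nc, nr, xll, yll, cs, nodata), vals, kind)
}

#' Write a raster layer as an ESRI ASCII grid
#'
#' Masked (`NA`) cells are written as the spec's nodata value. Non-finite
#' non-NA values (Inf, NaN) are a contract violation and raise an error:
#' mask them first.
#'
#' @param layer A [raster_layer()].
#' @param path Output path.
#' @param digits Significant digits for formatting (default 10, round-trips
#'   doubles well within 1e-6).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(layer, path, digits = 10) {
  stopifnot(inherits(layer, "raster_layer"))
  v <- layer$values
  if (any(!is.finite(v) & !is.na(v)))
    stop("layer '", layer$name, "' contains non-finite values; mask them before writing")
  s <- layer$spec
  v[is.na(v)] <- s$nodata_value
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", s$ncols), paste("nrows", s$nrows),
    paste("xllcorner", format(s$xllcorner, digits = 15)),
    paste("yllcorner", format(s$yllcorner, digits = 15)),
    paste("cellsize", format(s$cellsize, digits = 15)),
    paste("NODATA_value", format(s$nodata_value, digits = 15))), con)
  writeLines(apply(v, 1, function(r)
    paste(format(r, digits = digits, trim = TRUE, scientific = FALSE),
          collapse = " ")), con)
  invisible(path)
}

#' Read an occurrence CSV (species, longitude, latitude)
#'
#' Rows with unparseable or out-of-range coordinates (|lon| > 180,
#' |lat| > 90) are rejected with a warning naming the offending rows.
#'
#' @param path CSV path with header columns `species`, `longitude`,
#'   `latitude` (in that order by convention; matched by name).
#' @return A tibble with columns `species`, `longitude`, `latitude`.
#' @export
read_occurrence_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "longitude", "latitude")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("occurrence CSV '", path, "' missing column(s): ",
         paste(miss, collapse = ", "))
  lon <- suppressWarnings(as.numeric(df$longitude))
  lat <- suppressWarnings(as.numeric(df$latitude))
  bad <- is.na(lon) | is.na(lat) | lon < -180 | lon > 180 | lat < -90 | lat > 90
  if (any(bad))
    warning("rejected ", sum(bad), " occurrence row(s) with invalid coordinates: rows ",
            paste(which(bad), collapse = ", "))
  tibble::tibble(species = as.character(df$species)[!bad],
                 longitude = lon[!bad], latitude = lat[!bad])
}

#' Map points to raster cell indices
#'
#' Cells are half-open in both axes (`[edge, edge + cellsize)`), so a point
#' exactly on an edge belongs to the cell with the larger index. Row 1 is
#' the northernmost row.
#'
#' @param spec A `grid_spec`.
#' @param lon,lat Coordinate vectors.
#' @return Tibble with `row`, `col` (NA when outside the grid extent) and
#'   `cell` (single linear index, column-major).
#' @export
cell_index <- function(spec, lon, lat) {
  col <- floor((lon - spec$xllcorner) / spec$cellsize) + 1
  row_from_bottom <- floor((lat - spec$yllcorner) / spec$cellsize) + 1
  row <- spec$nrows - row_from_bottom + 1
  out <- col < 1 | col > spec$ncols | row < 1 | row > spec$nrows
  col[out] <- NA_integer_; row[out] <- NA_integer_
  tibble::tibble(row = as.integer(row), col = as.integer(col),
                 cell = as.integer(row + (col - 1L) * spec$nrows))
}

#' Spatially thin occurrences to one point per grid cell
#'
#' Retains the first point (input order) in each occupied cell of `spec`;
#' duplicates and points sharing a cell are dropped. Idempotent.
#'
#' @param occ Occurrence tibble (`species`, `longitude`, `latitude`).
#' @param spec A `grid_spec` defining the thinning grid.
#' @return The thinned occurrence tibble.
#' @export
thin_occurrences <- function(occ, spec) {
  stopifnot(inherits(spec, "grid_spec"))
  if (nrow(occ) == 0) return(occ)
  idx <- cell_index(spec, occ$longitude, occ$latitude)
  keep <- !duplicated(idx$cell) & !is.na(idx$cell)
  occ[keep, , drop = FALSE]
}

#' Extract layer values at occurrence points
#'
#' Nearest-cell lookup (no interpolation). Points outside the grid extent
#' or on cells masked in any layer are flagged `valid = FALSE`, excluded
#' from downstream fits, and reported with a warning.
#'
#' @param stack An [env_stack()].
#' @param points Tibble with `longitude`, `latitude` columns.
#' @return Tibble: `longitude`, `latitude`, `valid`, then one column per
#'   layer.
#' @export
extract_values <- function(stack, points) {
  stopifnot(inherits(stack, "env_stack"))
  idx <- cell_index(stack$spec, points$longitude, points$latitude)
  n <- nrow(points)
  vals <- lapply(stack$layers, function(l) {
    v <- rep(NA_real_, n)
    ok <- !is.na(idx$row)
    v[ok] <- l$values[cbind(idx$row[ok], idx$col[ok])]
    v
  })
  out <- tibble::tibble(longitude = points$longitude,
                        latitude = points$latitude)
  valid <- !is.na(idx$row)
  for (nm in names(vals)) valid <- valid & is.finite(vals[[nm]])
  out$valid <- valid
  for (nm in names(vals)) out[[nm]] <- vals[[nm]]
  if (any(!valid))
    warning(sum(!valid), " point(s) outside the grid or on masked cells; flagged valid = FALSE")
  out
}

#' Per-cell areas in square kilometres
#'
#' For grids in decimal degrees the area of a cell centred at latitude phi
#' is (cellsize * 111.32 km)^2 * cos(phi); for metre grids it is cellsize^2
#' / 1e6 (flat).
#'
#' @param spec A `grid_spec`.
#' @param units `"degrees"` (default) or `"metres"`.
#' @return Numeric vector of length `nrows`: area of one cell in each row,
#'   north to south.
#' @export
cell_area_km2 <- function(spec, units = c("degrees", "metres")) {
  units <- match.arg(units)
  if (units == "metres") return(rep((spec$cellsize / 1000)^2, spec$nrows))
  # centre latitude of each matrix row, row 1 northernmost
  lat_top <- spec$yllcorner + spec$nrows * spec$cellsize
  lat_centres <- lat_top - (seq_len(spec$nrows) - 0.5) * spec$cellsize
  (spec$cellsize * 111.32)^2 * cos(lat_centres * pi / 180)
}

#' Convert a raster layer to a long tibble
#'
#' @param x A `raster_layer`.
#' @param ... Unused.
#' @return Tibble with `row`, `col`, `longitude`, `latitude` (cell
#'   centres), `value`; masked cells carry `NA` values.
#' @method as_tibble raster_layer
#' @export
as_tibble.raster_layer <- function(x, ...) {
  s <- x$spec
  rows <- rep(seq_len(s$nrows), times = s$ncols)
  cols <- rep(seq_len(s$ncols), each = s$nrows)
  lat_top <- s$yllcorner + s$nrows * s$cellsize
  tibble::tibble(
    row = rows, col = cols,
    longitude = s$xllcorner + (cols - 0.5) * s$cellsize,
    latitude = lat_top - (rows - 0.5) * s$cellsize,
    value = as.vector(x$values))
}

#' Convert an environmental stack to a wide tibble of cell values
#'
#' @param x An `env_stack`.
#' @param ... Unused.
#' @return Tibble with `row`, `col`, `longitude`, `latitude` and one
#'   column per layer.
#' @method as_tibble env_stack
#' @export
as_tibble.env_stack <- function(x, ...) {
  out <- as_tibble.raster_layer(x$layers[[1]])
  names(out)[names(out) == "value"] <- x$layers[[1]]$name
  for (l in x$layers[-1]) out[[l$name]] <- as.vector(l$values)
  out
}

#' Plot a raster layer with ggplot2
#'
#' @param object A `raster_layer`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot raster_layer
#' @export
autoplot.raster_layer <- function(object, ...) {
  df <- as_tibble.raster_layer(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$longitude, y = .data$latitude,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = object$name, fill = object$kind)
}
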
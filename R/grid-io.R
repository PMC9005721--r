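#' Construct a raster grid
#'
#' An \code{env_grid} is a single-band raster on a regular lon/lat grid in the
#' ESRI ASCII layout: row 1 of \code{values} is the northernmost row, NODATA
#' cells are stored as \code{NA}.
#'
#' @param values Numeric matrix, \code{nrows x ncols}, row 1 = north.
#'   \code{NA} marks NODATA cells.
#' @param xllcorner,yllcorner Longitude/latitude of the lower-left corner of
#'   the lower-left cell, WGS84 decimal degrees.
#' @param cellsize Cell edge length in degrees (> 0).
#' @param nodata_value Sentinel written for \code{NA} cells on output.
#' @return An object of class \code{env_grid}.
#' @export
env_grid <- function(values, xllcorner, yllcorner, cellsize,
                     nodata_value = -9999) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("grid values must be numeric")
  if (nrow(values) < 1L || ncol(values) < 1L) stop("grid must be at least 1x1")
  if (!is.finite(cellsize) || cellsize <= 0) stop("cellsize must be > 0")
  if (!is.finite(xllcorner) || !is.finite(yllcorner))
    stop("corner coordinates must be finite")
  if (any(!is.finite(values) & !is.na(values)))
    stop("grid values must be finite or NA")
  structure(
    list(values = values, ncols = ncol(values), nrows = nrow(values),
         xllcorner = xllcorner, yllcorner = yllcorner, cellsize = cellsize,
         nodata_value = nodata_value),
    class = "env_grid")
}

#' @export
print.env_grid <- function(x, ...) {
  cat(sprintf("env_grid: %d rows x %d cols, cellsize %g deg\n",
              x$nrows, x$ncols, x$cellsize))
  cat(sprintf("  extent: lon [%g, %g], lat [%g, %g]; %d NODATA cells\n",
              x$xllcorner, x$xllcorner + x$ncols * x$cellsize,
              x$yllcorner, x$yllcorner + x$nrows * x$cellsize,
              sum(is.na(x$values))))
  invisible(x)
}

grid_header <- function(g) {
  g[c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")]
}

#' Test whether two grids share the same geometry
#'
#' Headers must agree exactly (after parse) in all five geometry fields for
#' grids to be stacked; no resampling is performed.
#'
#' @param a,b \code{env_grid} objects.
#' @return Logical scalar.
#' @export
same_geometry <- function(a, b) {
  identical(a$ncols, b$ncols) && identical(a$nrows, b$nrows) &&
    identical(a$xllcorner, b$xllcorner) &&
    identical(a$yllcorner, b$yllcorner) &&
    identical(a$cellsize, b$cellsize)
}

#' Read an ESRI ASCII grid
#'
#' Parses the whitespace-separated ESRI ASCII (.asc) dialect: a header of
#' \code{ncols}, \code{nrows}, \code{xllcorner}, \code{yllcorner},
#' \code{cellsize} and (optionally) \code{NODATA_value} lines, keys matched
#' case-insensitively, followed by \code{nrows} rows of \code{ncols} values,
#' northernmost row first. Cells equal to the NODATA sentinel (exact equality
#' after parse) become \code{NA}.
#'
#' @param path Path to the .asc file.
#' @return An \code{env_grid}.
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  body_start <- NA_integer_
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (grepl("^[A-Za-z]", ln)) {
      parts <- strsplit(ln, "\\s+")[[1]]
      if (length(parts) != 2L)
        stop("malformed header line ", i, ": '", lines[i], "'")
      key <- tolower(parts[1])
      val <- suppressWarnings(as.numeric(parts[2]))
      if (is.na(val))
        stop("malformed header line ", i, ": '", lines[i], "'")
      hdr[[key]] <- val
    } else {
      body_start <- i
      break
    }
  }
  needed <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  missing <- setdiff(needed, names(hdr))
  if (length(missing))
    stop("header missing field(s): ", paste(missing, collapse = ", "))
  if (is.na(body_start)) stop("file has no data body")
  nodata <- if ("nodata_value" %in% names(hdr)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[body_start:length(lines)], collapse = "\n"),
               what = numeric(), quiet = TRUE)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  if (length(vals) != nc * nr)
    stop(sprintf("dimension mismatch: header says %d x %d = %d cells, body has %d",
                 nr, nc, nr * nc, length(vals)))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  env_grid(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize, nodata)
}

#' Write an ESRI ASCII grid
#'
#' Emits the standard 6-line header then \code{nrows} lines of \code{ncols}
#' numbers (north first); \code{NA} cells are written as the grid's NODATA
#' sentinel. Values are formatted with 8 significant digits, enough for a
#' lossless round trip at 1e-6 relative tolerance.
#'
#' @param grid An \code{env_grid}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_ascii_grid <- function(grid, path) {
  stopifnot(inherits(grid, "env_grid"))
  v <- grid$values
  v[is.na(v)] <- grid$nodata_value
  hdr <- c(
    sprintf("ncols %d", grid$ncols),
    sprintf("nrows %d", grid$nrows),
    sprintf("xllcorner %.10g", grid$xllcorner),
    sprintf("yllcorner %.10g", grid$yllcorner),
    sprintf("cellsize %.10g", grid$cellsize),
    sprintf("NODATA_value %.10g", grid$nodata_value))
  rows <- apply(v, 1, function(r) paste(sprintf("%.8g", r), collapse = " "))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(hdr, rows), con)
  invisible(path)
}

#' Assemble aligned grids into an environmental stack
#'
#' @param grids Named list of \code{env_grid} objects on an identical
#'   geometry. Names are the variable names (e.g. \code{BIO1}, \code{SOC}).
#' @return An object of class \code{env_stack}: the named list of grids with
#'   a shared geometry.
#' @export
env_stack <- function(grids) {
  if (length(grids) == 0L) stop("empty stack")
  nm <- names(grids)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop("grids must have unique non-empty names")
  for (g in grids) stopifnot(inherits(g, "env_grid"))
  ref <- grids[[1]]
  ok <- vapply(grids, same_geometry, logical(1), b = ref)
  if (!all(ok))
    stop("grids not aligned: ", paste(nm[!ok], collapse = ", "),
         " differ from ", nm[1], " in header geometry")
  structure(grids, class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  g <- x[[1]]
  cat(sprintf("env_stack: %d variables on a %d x %d grid (cellsize %g deg)\n",
              length(x), g$nrows, g$ncols, g$cellsize))
  cat("  ", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

#' Union NODATA mask of a stack
#'
#' A cell is masked if it is NODATA in any member grid: validity is a single
#' shared decision across variables.
#'
#' @param stack An \code{env_stack}.
#' @return Logical matrix, \code{TRUE} where masked.
#' @export
stack_mask <- function(stack) {
  stopifnot(inherits(stack, "env_stack"))
  Reduce(`|`, lapply(stack, function(g) is.na(g$values)))
}

#' Longitude/latitude of every cell centre
#'
#' @param grid An \code{env_grid} (or the first grid of a stack).
#' @return Data frame with columns \code{lon}, \code{lat}, \code{row},
#'   \code{col}, in row-major (north-first) cell order.
#' @export
cell_centers <- function(grid) {
  stopifnot(inherits(grid, "env_grid"))
  cs <- grid$cellsize
  ytop <- grid$yllcorner + grid$nrows * cs
  rows <- rep(seq_len(grid$nrows), each = grid$ncols)
  cols <- rep(seq_len(grid$ncols), times = grid$nrows)
  data.frame(lon = grid$xllcorner + (cols - 0.5) * cs,
             lat = ytop - (rows - 0.5) * cs,
             row = rows, col = cols)
}

#' Map points to grid cells
#'
#' Cell \code{(r, c)} (1-based, row 1 = north) covers the half-open interval
#' closed on its west and north edges. Returns 1-based row/col indices, or
#' \code{NA} for points outside the extent.
#' @noRd
point_cell <- function(grid, lon, lat) {
  cs <- grid$cellsize
  ytop <- grid$yllcorner + grid$nrows * cs
  col <- floor((lon - grid$xllcorner) / cs) + 1
  row <- floor((ytop - lat) / cs) + 1
  # north edge of the grid is closed: lat == ytop belongs to row 1
  row[lat == ytop] <- 1
  inside <- col >= 1 & col <= grid$ncols & row >= 1 & row <= grid$nrows &
    is.finite(lon) & is.finite(lat)
  col[!inside] <- NA_integer_
  row[!inside] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Extract covariate values at points
#'
#' Maps each lon/lat point to its containing cell and reads every stack
#' variable there. Points outside the extent, or falling on a cell that is
#' NODATA in \emph{any} variable (union mask), are flagged invalid; their
#' feature rows are \code{NA}.
#'
#' @param stack An \code{env_stack}.
#' @param points Data frame with columns \code{lon}, \code{lat} (WGS84
#'   decimal degrees).
#' @return List with \code{features} (data frame, one column per variable),
#'   \code{valid} (logical vector), and \code{cell} (row/col indices).
#' @export
extract_values <- function(stack, points) {
  if (!inherits(stack, "env_stack") || length(stack) == 0L)
    stop("extract_values needs a non-empty env_stack")
  stopifnot(all(c("lon", "lat") %in% names(points)))
  g <- stack[[1]]
  cell <- point_cell(g, points$lon, points$lat)
  n <- nrow(cell)
  mask <- stack_mask(stack)
  valid <- !is.na(cell$row)
  idx <- cbind(cell$row[valid], cell$col[valid])
  if (nrow(idx)) valid[valid] <- !mask[idx]
  idx <- cbind(cell$row, cell$col)
  feat <- lapply(stack, function(gr) {
    out <- rep(NA_real_, n)
    out[valid] <- gr$values[idx[valid, , drop = FALSE]]
    out
  })
  feat <- as.data.frame(feat, optional = TRUE)
  names(feat) <- names(stack)
  list(features = feat, valid = valid, cell = cell)
}
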
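#' Categorical raster
#'
#' A minimal in-memory container for class-coded land-cover grids in planar
#' metre coordinates. Values are stored as an integer matrix whose first row
#' is the northern (top) edge of the grid, matching on-disk row order of
#' ESRI ASCII grids. Cell (i, j) has its centre at
#' `x = x0 + (j - 0.5) * cell_size`, `y = y0 + (nrow - i + 0.5) * cell_size`,
#' with `(x0, y0)` the lower-left corner of the grid.
#'
#' @param values integer matrix of class codes (top row = north).
#' @param cell_size cell edge length in metres (> 0).
#' @param origin numeric length-2, x/y of the lower-left corner (metres).
#' @param nodata integer code marking cells outside the analysis area.
#' @param legend optional named integer vector mapping class names to codes.
#' @return an object of class `cat_raster`.
#' @export
cat_raster <- function(values, cell_size = 30, origin = c(0, 0),
                       nodata = -9999L, legend = NULL) {
  if (!is.matrix(values)) abort("`values` must be a matrix")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    abort("`cell_size` must be a single positive number")
  storage.mode(values) <- "integer"
  if (!is.null(legend)) {
    if (is.null(names(legend)) || anyDuplicated(legend))
      abort("`legend` must be a named vector of distinct codes")
    legend <- vapply(legend, as.integer, integer(1))
  }
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), nodata = as.integer(nodata),
         legend = legend),
    class = "cat_raster"
  )
}

#' @export
print.cat_raster <- function(x, ...) {
  cat(sprintf("cat_raster: %d x %d cells, %.0f m resolution\n",
              nrow(x$values), ncol(x$values), x$cell_size))
  tab <- table(x$values[x$values != x$nodata])
  if (!is.null(x$legend)) {
    nm <- names(x$legend)[match(as.integer(names(tab)), x$legend)]
    names(tab)[!is.na(nm)] <- nm[!is.na(nm)]
  }
  cat("classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.cat_raster <- function(x) dim(x$values)

# class code for a class given by name or code
class_code <- function(r, cls) {
  if (is.character(cls)) {
    if (is.null(r$legend) || !cls %in% names(r$legend))
      abort(sprintf("class '%s' not in raster legend", cls))
    r$legend[[cls]]
  } else as.integer(cls)
}

# x/y coordinates of all cell centres, as nrow x ncol matrices
cell_centers <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values); cs <- r$cell_size
  list(
    x = matrix(rep(r$origin[1] + (seq_len(nc) - 0.5) * cs, each = nr), nr, nc),
    y = matrix(rep(r$origin[2] + (nr - seq_len(nr) + 0.5) * cs, times = nc),
               nr, nc)
  )
}

# row/col of the cell containing planar point (x, y); NA outside extent
cell_at_point <- function(r, x, y) {
  nr <- nrow(r$values); nc <- ncol(r$values); cs <- r$cell_size
  j <- ceiling((x - r$origin[1]) / cs)
  i <- nr - ceiling((y - r$origin[2]) / cs) + 1L
  if (is.na(i) || is.na(j) || i < 1 || i > nr || j < 1 || j > nc)
    return(c(NA_integer_, NA_integer_))
  c(as.integer(i), as.integer(j))
}

#' Read an ESRI ASCII grid
#'
#' @param path file path to a `.asc` grid.
#' @param legend optional named class legend to attach.
#' @return a [cat_raster()].
#' @export
read_ascii_grid <- function(path, legend = NULL) {
  lines <- readLines(path, n = 6L)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2L && is.na(suppressWarnings(as.numeric(parts[1])))) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1L
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    abort("missing ESRI ASCII grid header fields: ",
          paste(setdiff(need, names(hdr)), collapse = ", "))
  nodata <- as.integer(hdr[["nodata_value"]] %||% -9999)
  vals <- scan(path, what = integer(), skip = n_hdr, quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) abort("grid body does not match header dims")
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  cat_raster(m, cell_size = hdr$cellsize,
             origin = c(hdr$xllcorner, hdr$yllcorner),
             nodata = nodata, legend = legend)
}

#' Write an ESRI ASCII grid
#'
#' @param r a [cat_raster()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(r, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(r$values)),
    sprintf("nrows %d", nrow(r$values)),
    sprintf("xllcorner %.6g", r$origin[1]),
    sprintf("yllcorner %.6g", r$origin[2]),
    sprintf("cellsize %.6g", r$cell_size),
    sprintf("NODATA_value %d", r$nodata)
  ), con)
  utils::write.table(r$values, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
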
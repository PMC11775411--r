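#' Land-cover composition within buffers around points
#'
#' For each point and radius, the proportion of each reported class among the
#' non-nodata cells whose centres fall inside the circle. Proportions over
#' the reported classes need not sum to 1 (other classes exist). Buffers
#' reaching beyond the raster extent use the available cells, with a
#' truncation warning.
#'
#' @param r a [cat_raster()] with a legend.
#' @param points data frame with columns `id`, `x`, `y`.
#' @param radii buffer radii in metres (defaults are typical carnivore
#'   home-range scales: 1000/1500/2000/3500/4500).
#' @param classes class names to report.
#' @return long data frame: `id`, `radius`, `class`, `proportion`, `n_cells`
#'   (non-nodata cells in the buffer).
#' @export
buffer_composition <- function(r, points,
                               radii = c(1000, 1500, 2000, 3500, 4500),
                               classes = c("forest", "agriculture",
                                           "built_up")) {
  stopifnot(inherits(r, "cat_raster"))
  if (any(radii <= 0)) abort("radii must be > 0")
  codes <- vapply(classes, function(cl) class_code(r, cl), integer(1))
  cc <- cell_centers(r)
  xmin <- r$origin[1]; ymin <- r$origin[2]
  xmax <- xmin + ncol(r$values) * r$cell_size
  ymax <- ymin + nrow(r$values) * r$cell_size
  ok <- r$values != r$nodata
  out <- list()
  truncated <- FALSE
  for (k in seq_len(nrow(points))) {
    px <- points$x[k]; py <- points$y[k]
    d2 <- (cc$x - px)^2 + (cc$y - py)^2
    for (rad in radii) {
      if (px - rad < xmin || px + rad > xmax ||
          py - rad < ymin || py + rad > ymax) truncated <- TRUE
      inside <- d2 <= rad^2 & ok
      n <- sum(inside)
      prop <- if (n == 0) rep(NA_real_, length(codes)) else
        vapply(codes, function(cd) sum(r$values[inside] == cd) / n,
               numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        id = points$id[k], radius = rad, class = classes,
        proportion = prop, n_cells = n, row.names = NULL)
    }
  }
  if (truncated)
    warning("some buffers extend beyond the raster; truncated to available cells")
  do.call(rbind, out)
}

#' Signed distance from a point to the nearest forest edge
#'
#' The forest edge is the set of cell faces between a forest cell and a cell
#' of any other (non-nodata) land-cover class. Returns the Euclidean distance
#' from the point to the nearest such face, positive when the point lies in
#' forest and negative otherwise; 0 exactly on a face.
#'
#' @param r a [cat_raster()] with a legend.
#' @param x,y point coordinates (planar metres), inside the raster.
#' @param forest class name or code of forest (default `"forest"`).
#' @return signed distance in metres; NA with a warning when the raster has
#'   no forest/non-forest boundary.
#' @export
distance_to_forest_edge <- function(r, x, y, forest = "forest") {
  stopifnot(inherits(r, "cat_raster"))
  code <- class_code(r, forest)
  v <- r$values
  nr <- nrow(v); nc <- ncol(v); cs <- r$cell_size
  x0 <- r$origin[1]; y0 <- r$origin[2]
  isf <- v == code & v != r$nodata
  isl <- v != code & v != r$nodata     # other land-use

  segs <- list()
  # vertical faces between horizontally adjacent cells (i,j)|(i,j+1)
  hz <- which((isf[, -nc] & isl[, -1]) | (isl[, -nc] & isf[, -1]))
  if (length(hz)) {
    i <- (hz - 1L) %% nr + 1L; j <- (hz - 1L) %/% nr + 1L
    segs[[1]] <- data.frame(ax = x0 + j * cs, ay = y0 + (nr - i) * cs,
                            bx = x0 + j * cs, by = y0 + (nr - i + 1) * cs)
  }
  # horizontal faces between vertically adjacent cells (i,j)/(i+1,j)
  vt <- which((isf[-nr, ] & isl[-1, ]) | (isl[-nr, ] & isf[-1, ]))
  if (length(vt)) {
    i <- (vt - 1L) %% (nr - 1L) + 1L; j <- (vt - 1L) %/% (nr - 1L) + 1L
    segs[[2]] <- data.frame(ax = x0 + (j - 1) * cs, ay = y0 + (nr - i) * cs,
                            bx = x0 + j * cs, by = y0 + (nr - i) * cs)
  }
  segs <- do.call(rbind, segs)
  if (is.null(segs) || nrow(segs) == 0L) {
    warning("raster has no forest/other-class boundary; distance undefined")
    return(NA_real_)
  }
  # point-to-segment distances
  vx <- segs$bx - segs$ax; vy <- segs$by - segs$ay
  t <- pmin(1, pmax(0, ((x - segs$ax) * vx + (y - segs$ay) * vy) /
                         (vx^2 + vy^2)))
  d <- sqrt((segs$ax + t * vx - x)^2 + (segs$ay + t * vy - y)^2)
  dist <- min(d)
  ij <- cell_at_point(r, x, y)
  if (anyNA(ij)) abort("point lies outside the raster extent")
  if (isf[ij[1], ij[2]]) dist else -dist
}

#' Wildland-urban interface rasters
#'
#' Builds focal-presence layers for forest, agriculture and built-up (a cell
#' is flagged when the class occurs at any cell centre within the circular
#' neighbourhood of the given radius) and intersects them cellwise:
#' FA = forest x agriculture, FB = forest x built-up, FAB = FA x FB. Reports
#' the area and percent of the (non-nodata) landscape of each interface.
#'
#' @param r a [cat_raster()] with a legend.
#' @param radius neighbourhood radius in metres (>= cell size; default 150).
#' @param focal `"presence"` (focal maximum of the binary layer, default) or
#'   `"mean"` with `mean_threshold`: focal mean > threshold.
#' @param mean_threshold cutoff for `focal = "mean"`.
#' @return object of class `interface_raster`: list with logical matrices
#'   `fa`, `fb`, `fab`, plus `area_ha` and `percent` (named length-3), and
#'   the focal layers in `focal_layers`.
#' @export
interface_rasters <- function(r, radius = 150,
                              focal = c("presence", "mean"),
                              mean_threshold = 0.5) {
  stopifnot(inherits(r, "cat_raster"))
  focal <- match.arg(focal)
  if (radius < r$cell_size) abort("radius must be at least one cell size")
  nr <- nrow(r$values); nc <- ncol(r$values); cs <- r$cell_size
  rmax <- floor(radius / cs)
  offs <- expand.grid(di = -rmax:rmax, dj = -rmax:rmax)
  offs <- offs[sqrt(offs$di^2 + offs$dj^2) * cs <= radius, ]

  shift_acc <- function(bin) {
    acc <- matrix(0, nr, nc)
    for (k in seq_len(nrow(offs))) {
      di <- offs$di[k]; dj <- offs$dj[k]
      si <- max(1, 1 + di):min(nr, nr + di)
      sj <- max(1, 1 + dj):min(nc, nc + dj)
      acc[si - di, sj - dj] <- acc[si - di, sj - dj] + bin[si, sj]
    }
    acc
  }
  foc <- lapply(c(forest = "forest", agriculture = "agriculture",
                  built_up = "built_up"), function(cl) {
    bin <- (r$values == class_code(r, cl) & r$values != r$nodata) * 1
    acc <- shift_acc(bin)
    if (focal == "presence") acc > 0 else acc / nrow(offs) > mean_threshold
  })
  ok <- r$values != r$nodata
  fa <- foc$forest & foc$agriculture & ok
  fb <- foc$forest & foc$built_up & ok
  fab <- fa & fb
  n_land <- sum(ok)
  area_ha <- c(fa = sum(fa), fb = sum(fb), fab = sum(fab)) * cs^2 / 1e4
  percent <- c(fa = sum(fa), fb = sum(fb), fab = sum(fab)) / n_land * 100
  structure(list(fa = fa, fb = fb, fab = fab, area_ha = area_ha,
                 percent = percent, radius = radius, focal_layers = foc),
            class = "interface_raster")
}

#' @export
print.interface_raster <- function(x, ...) {
  cat(sprintf("interface_raster (radius %.0f m):\n", x$radius))
  for (nm in c("fa", "fb", "fab"))
    cat(sprintf("  %-4s %.1f ha (%.1f%% of landscape)\n", toupper(nm),
                x$area_ha[[nm]], x$percent[[nm]]))
  invisible(x)
}

#' Habitat context of cattle-positive vs cattle-negative scats
#'
#' Compares the percent cover of forest, agriculture and built-up within a
#' buffer around scats that contained cattle against those that did not,
#' using Welch's two-sample t test per class. With fewer than 2 scats in
#' either group, or zero variance, the output is descriptive only (NA
#' p-values).
#'
#' @param r a [cat_raster()] with a legend.
#' @param points data frame with `id`, `x`, `y`, `contains_cattle` (logical).
#' @param radius buffer radius in metres (default 1000).
#' @param classes class names to compare.
#' @return data frame per class: group means (percent), `difference`,
#'   `p_value`, group sizes.
#' @export
cattle_context_comparison <- function(r, points, radius = 1000,
                                      classes = c("forest", "agriculture",
                                                  "built_up")) {
  if (!all(c("contains_cattle") %in% names(points)))
    abort("points need a logical `contains_cattle` column")
  if (!any(points$contains_cattle) || all(points$contains_cattle))
    abort("both cattle and non-cattle groups must be nonempty")
  comp <- buffer_composition(r, points, radii = radius, classes = classes)
  comp$pct <- comp$proportion * 100
  with_c <- points$id[points$contains_cattle]
  rows <- lapply(classes, function(cl) {
    x <- comp$pct[comp$class == cl & comp$id %in% with_c]
    y <- comp$pct[comp$class == cl & !comp$id %in% with_c]
    p <- if (length(x) >= 2 && length(y) >= 2)
      tryCatch(stats::t.test(x, y)$p.value, error = function(e) NA_real_)
    else NA_real_
    data.frame(class = cl, mean_with_cattle = mean(x),
               mean_without_cattle = mean(y),
               difference = mean(x) - mean(y), p_value = p,
               n_with = length(x), n_without = length(y))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
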
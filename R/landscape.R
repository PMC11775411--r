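# --- connected-component labeling (8-neighbourhood), two-pass union-find ---

# label TRUE cells of a logical matrix; returns integer matrix, 0 elsewhere
label_components <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  n <- nr * nc
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  idx <- which(m)
  for (v in idx) {
    i <- (v - 1L) %% nr + 1L; j <- (v - 1L) %/% nr + 1L
    # neighbours already visited in column-major order
    for (d in list(c(-1L, 0L), c(-1L, -1L), c(0L, -1L), c(1L, -1L))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (ii < 1 || ii > nr || jj < 1) next
      w <- ii + (jj - 1L) * nr
      if (m[w]) {
        rv <- find(v); rw <- find(w)
        if (rv != rw) parent[rw] <- rv
      }
    }
  }
  lab <- matrix(0L, nr, nc)
  roots <- vapply(idx, find, integer(1))
  lab[idx] <- match(roots, unique(roots))
  lab
}

# per-cell count of exposed 4-neighbour faces (different class, nodata or
# raster boundary all count as edge)
exposed_faces <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  f <- matrix(0L, nr, nc)
  up    <- rbind(matrix(FALSE, 1, nc), m[-nr, , drop = FALSE])
  down  <- rbind(m[-1, , drop = FALSE], matrix(FALSE, 1, nc))
  left  <- cbind(matrix(FALSE, nr, 1), m[, -nc, drop = FALSE])
  right <- cbind(m[, -1, drop = FALSE], matrix(FALSE, nr, 1))
  f[m] <- ((!up) + (!down) + (!left) + (!right))[m]
  f
}

#' Delineate patches of one land-cover class
#'
#' Patches are maximal 8-connected components of the class's cells (two
#' squares touching only at a corner form one patch). Patch perimeter is the
#' total length of cell faces adjacent to a different class, nodata, or the
#' raster boundary.
#'
#' @param r a [cat_raster()].
#' @param cls class name (if the raster has a legend) or integer code.
#' @return object of class `patch_set`: list with `labels` (integer matrix,
#'   0 = not this class), `patches` (data frame: `patch`, `n_cells`,
#'   `area_m2`, `perimeter_m`), `cell_size`, `class`. A class absent from
#'   the raster yields an empty patch set.
#' @export
delineate_patches <- function(r, cls) {
  stopifnot(inherits(r, "cat_raster"))
  code <- class_code(r, cls)
  m <- r$values == code & r$values != r$nodata
  lab <- label_components(m)
  cs <- r$cell_size
  np <- max(lab)
  if (np == 0L) {
    patches <- data.frame(patch = integer(), n_cells = integer(),
                          area_m2 = numeric(), perimeter_m = numeric())
  } else {
    faces <- exposed_faces(m)
    n_cells <- tabulate(lab[m], nbins = np)
    perim <- as.numeric(tapply(faces[m], lab[m], sum)) * cs
    patches <- data.frame(patch = seq_len(np), n_cells = n_cells,
                          area_m2 = n_cells * cs^2, perimeter_m = perim)
  }
  structure(list(labels = lab, patches = patches, cell_size = cs,
                 class = cls),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("patch_set (%s): %d patch(es), %.2f ha total\n",
              as.character(x$class), nrow(x$patches),
              sum(x$patches$area_m2) / 1e4))
  invisible(x)
}

# core cells: centre > edge_depth from every cell centre outside the patch.
# Window form: every in-raster offset cell with ||o|| * cs <= edge_depth must
# belong to the same patch. Offsets falling off the raster impose no
# constraint: only existing cell centres can be "outside the patch".
core_cells <- function(labels, cell_size, edge_depth) {
  nr <- nrow(labels); nc <- ncol(labels)
  rmax <- floor(edge_depth / cell_size)
  core <- labels > 0L
  if (rmax < 1 || !any(core)) return(core)
  for (di in -rmax:rmax) for (dj in -rmax:rmax) {
    if (di == 0 && dj == 0) next
    if (sqrt(di^2 + dj^2) * cell_size > edge_depth) next
    sh <- labels                             # off-raster: no constraint
    si <- max(1, 1 + di):min(nr, nr + di)    # rows of source
    sj <- max(1, 1 + dj):min(nc, nc + dj)
    sh[si - di, sj - dj] <- labels[si, sj]
    core <- core & (sh == labels)
  }
  core
}

# boundary cells of each patch: any 4-neighbour outside the class mask
boundary_mask <- function(labels) {
  m <- labels > 0L
  exposed_faces(m) > 0L & m
}

#' Class-level fragmentation metrics
#'
#' The six class metrics for one analysis unit:
#' \itemize{
#' \item PD, patch density: patches per 100 ha of landscape;
#' \item ED, edge density: total patch perimeter (m) per ha;
#' \item MPA, mean patch area (ha);
#' \item MSI, mean shape index: mean of `0.25 * perimeter / sqrt(area)` over
#'   patches (1 for a square, > 1 otherwise);
#' \item MCA, mean core area (ha) at `edge_depth`: a core cell's centre lies
#'   more than `edge_depth` from every cell centre outside its patch;
#' \item ENN, mean Euclidean nearest-neighbour distance (m): mean over
#'   patches of the minimum centre-to-centre distance between own boundary
#'   cells and boundary cells of the nearest other patch of the same class
#'   (NA with fewer than 2 patches).
#' }
#'
#' @param ps a [delineate_patches()] result.
#' @param landscape_area_ha area of the analysis unit in hectares (> 0).
#' @param edge_depth edge depth in metres for the core-area rule
#'   (default 100; 0 makes MCA equal MPA).
#' @return one-row data frame: `n_patches`, `pd`, `ed`, `mpa`, `msi`, `mca`,
#'   `enn` (all NA for an empty patch set).
#' @export
class_metrics <- function(ps, landscape_area_ha, edge_depth = 100) {
  stopifnot(inherits(ps, "patch_set"))
  if (landscape_area_ha <= 0) abort("landscape_area_ha must be > 0")
  np <- nrow(ps$patches)
  if (np == 0L)
    return(data.frame(n_patches = 0L, pd = NA_real_, ed = NA_real_,
                      mpa = NA_real_, msi = NA_real_, mca = NA_real_,
                      enn = NA_real_))
  p <- ps$patches
  cs <- ps$cell_size
  pd <- np / landscape_area_ha * 100
  ed <- sum(p$perimeter_m) / landscape_area_ha
  mpa <- mean(p$area_m2) / 1e4
  msi <- mean(0.25 * p$perimeter_m / sqrt(p$area_m2))
  core <- core_cells(ps$labels, cs, edge_depth)
  core_cells_per <- tabulate(ps$labels[core], nbins = np)
  mca <- mean(core_cells_per * cs^2) / 1e4
  enn <- NA_real_
  if (np >= 2L) {
    b <- boundary_mask(ps$labels)
    bi <- which(b)
    nr <- nrow(ps$labels)
    ii <- (bi - 1L) %% nr + 1L; jj <- (bi - 1L) %/% nr + 1L
    blab <- ps$labels[bi]
    d <- numeric(np)
    for (k in seq_len(np)) {
      own <- blab == k
      dx <- outer(jj[own], jj[!own], `-`)
      dy <- outer(ii[own], ii[!own], `-`)
      d[k] <- min(sqrt(dx^2 + dy^2)) * cs
    }
    enn <- mean(d)
  }
  data.frame(n_patches = np, pd = pd, ed = ed, mpa = mpa, msi = msi,
             mca = mca, enn = enn)
}

# circular mask of cells whose centres lie within `radius` of (x, y)
circle_mask <- function(r, x, y, radius) {
  cc <- cell_centers(r)
  (cc$x - x)^2 + (cc$y - y)^2 <= radius^2
}

#' Fragmentation metrics at analysis scales
#'
#' Computes [class_metrics()] for one class over the whole raster, over named
#' masks (e.g. the major forest patches), or over circular buffers around
#' points. The raster is clipped to each unit (cells outside become nodata)
#' and the landscape area is the unit's non-nodata area.
#'
#' @param r a [cat_raster()].
#' @param cls class name or code.
#' @param units `"whole"`, a named list of logical matrices (unit masks), or
#'   a data frame of points with columns `id`, `x`, `y`.
#' @param buffer buffer radius in metres around points (default 1000).
#' @param edge_depth edge depth in metres (default 100).
#' @return data frame with one row per unit (`unit` column first); units
#'   entirely nodata give an all-NA row.
#' @export
metrics_at_scales <- function(r, cls, units = "whole", buffer = 1000,
                              edge_depth = 100) {
  stopifnot(inherits(r, "cat_raster"))
  masks <- if (identical(units, "whole")) {
    list(whole = matrix(TRUE, nrow(r$values), ncol(r$values)))
  } else if (is.data.frame(units)) {
    ms <- lapply(seq_len(nrow(units)),
                 function(k) circle_mask(r, units$x[k], units$y[k], buffer))
    names(ms) <- as.character(units$id)
    ms
  } else if (is.list(units)) {
    if (is.null(names(units))) abort("unit masks must be named")
    units
  } else abort("`units` must be \"whole\", a named list of masks, or points")

  rows <- lapply(names(masks), function(nm) {
    mask <- masks[[nm]]
    rc <- r
    rc$values[!mask] <- r$nodata
    area_ha <- sum(mask & r$values != r$nodata) * r$cell_size^2 / 1e4
    if (area_ha == 0)
      return(data.frame(unit = nm, n_patches = NA_integer_, pd = NA_real_,
                        ed = NA_real_, mpa = NA_real_, msi = NA_real_,
                        mca = NA_real_, enn = NA_real_))
    cbind(unit = nm,
          class_metrics(delineate_patches(rc, cls), area_ha, edge_depth))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Median-rank fragmentation classifier
#'
#' Ranks each of the six class metrics across units in the direction of
#' increasing fragmentation (higher PD, ED, MSI and ENN rank higher; smaller
#' MPA and MCA rank higher), takes the median of each unit's available ranks
#' (ties get average ranks; missing metrics are excluded from that unit's
#' median), and splits the units into low / moderate / high fragmentation by
#' equal-count tertiles of the median ranks. Tied medians stay together: a
#' tie group is placed in the tertile of its mean sorted position, so a fully
#' tied set of units is uniformly "moderate".
#'
#' @param rows data frame from [metrics_at_scales()] (needs `unit`, `pd`,
#'   `ed`, `mpa`, `msi`, `mca`, `enn`); at least 3 units.
#' @return data frame: `unit`, the six ranks, `median_rank`, `frag_class`
#'   (factor low/moderate/high).
#' @export
classify_fragmentation <- function(rows) {
  if (nrow(rows) < 3L) abort("need at least 3 units to classify")
  rk <- function(x) rank(x, ties.method = "average", na.last = "keep")
  ranks <- data.frame(
    rk_pd = rk(rows$pd), rk_ed = rk(rows$ed), rk_mpa = rk(-rows$mpa),
    rk_msi = rk(rows$msi), rk_mca = rk(-rows$mca), rk_enn = rk(rows$enn))
  med <- apply(ranks, 1, stats::median, na.rm = TRUE)
  k <- length(med)
  pos <- rank(med, ties.method = "average")
  frag <- ifelse(pos <= k / 3, "low",
                 ifelse(pos <= 2 * k / 3, "moderate", "high"))
  cbind(unit = rows$unit, ranks, median_rank = med,
        frag_class = factor(frag, levels = c("low", "moderate", "high")))
}
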
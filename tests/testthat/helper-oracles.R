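# Independent brute-force oracles used to validate the package's
# implementations. These deliberately share no code with the package:
# labeling is a scanline BFS flood fill, metrics are computed by exhaustive
# per-cell loops and pairwise distances.

oracle_label8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!m[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j))
    lab[i, j] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            m[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          stack[[length(stack) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

# exhaustive six-metric computation for one class on a small raster
oracle_class_metrics <- function(vals, code, cs, area_ha, depth) {
  nr <- nrow(vals); nc <- ncol(vals)
  m <- vals == code
  lab <- oracle_label8(m)
  np <- max(lab)
  if (np == 0L)
    return(list(n_patches = 0L, pd = NA, ed = NA, mpa = NA, msi = NA,
                mca = NA, enn = NA))
  area <- perim <- core <- numeric(np)
  cells <- which(m, arr.ind = TRUE)
  for (k in seq_len(np)) {
    pk <- which(lab == k, arr.ind = TRUE)
    area[k] <- nrow(pk) * cs^2
    # perimeter: exhaustive face count
    pfaces <- 0L
    for (q in seq_len(nrow(pk))) {
      i <- pk[q, 1]; j <- pk[q, 2]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii < 1 || ii > nr || jj < 1 || jj > nc || !m[ii, jj])
          pfaces <- pfaces + 1L
      }
    }
    perim[k] <- pfaces * cs
    # core: centre > depth from every cell centre outside this patch
    outside <- which(lab != k, arr.ind = TRUE)
    ncore <- 0L
    for (q in seq_len(nrow(pk))) {
      d2 <- (outside[, 1] - pk[q, 1])^2 + (outside[, 2] - pk[q, 2])^2
      if (all(sqrt(d2) * cs > depth)) ncore <- ncore + 1L
    }
    core[k] <- ncore * cs^2
  }
  enn <- NA_real_
  if (np >= 2L) {
    d <- numeric(np)
    for (k in seq_len(np)) {
      own <- which(lab == k, arr.ind = TRUE)
      oth <- which(lab != k & lab > 0L, arr.ind = TRUE)
      dd <- outer(own[, 1], oth[, 1], `-`)^2 + outer(own[, 2], oth[, 2], `-`)^2
      d[k] <- min(sqrt(dd)) * cs
    }
    enn <- mean(d)
  }
  list(n_patches = np,
       pd = np / area_ha * 100,
       ed = sum(perim) / area_ha,
       mpa = mean(area) / 1e4,
       msi = mean(0.25 * perim / sqrt(area)),
       mca = mean(core) / 1e4,
       enn = enn)
}

# brute-force filter chain: explicit loops over samples/OTUs
oracle_filter <- function(counts, control, keep_otu, labels, threshold) {
  thr <- if (length(control)) max(control) else 0
  counts[counts <= thr] <- 0
  counts <- counts[, keep_otu, drop = FALSE]
  labels <- labels[keep_otu]
  taxa <- unique(labels)
  pres <- matrix(FALSE, nrow(counts), length(taxa),
                 dimnames = list(rownames(counts), taxa))
  for (i in seq_len(nrow(counts))) {
    tot <- sum(counts[i, ])
    if (tot == 0) next
    for (t in taxa) {
      if (sum(counts[i, labels == t]) / tot > threshold)
        pres[i, t] <- TRUE
    }
  }
  pres[, colSums(pres) > 0, drop = FALSE]
}

# exhaustive cell-centre circle membership around (px, py)
oracle_circle_cells <- function(r, px, py, radius) {
  nr <- nrow(r$values); nc <- ncol(r$values); cs <- r$cell_size
  hit <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    cx <- r$origin[1] + (j - 0.5) * cs
    cy <- r$origin[2] + (nr - i + 0.5) * cs
    if ((cx - px)^2 + (cy - py)^2 <= radius^2) hit[i, j] <- TRUE
  }
  hit
}

# exhaustive focal presence of a class within a circular neighbourhood
oracle_focal_presence <- function(r, code, radius) {
  nr <- nrow(r$values); nc <- ncol(r$values); cs <- r$cell_size
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    for (ii in seq_len(nr)) for (jj in seq_len(nc)) {
      if (sqrt((ii - i)^2 + (jj - j)^2) * cs <= radius &&
          r$values[ii, jj] == code) {
        out[i, j] <- TRUE
        break
      }
    }
  }
  out
}

# random categorical raster with a fixed legend
random_raster <- function(seed, nr, nc, p_forest = 0.4, cs = 30) {
  set.seed(seed)
  codes <- c(forest = 1L, agriculture = 2L, built_up = 3L)
  v <- matrix(sample(c(1L, 2L, 3L), nr * nc, replace = TRUE,
                     prob = c(p_forest, (1 - p_forest) * 0.7,
                              (1 - p_forest) * 0.3)),
              nr, nc)
  cat_raster(v, cell_size = cs, legend = codes)
}

# rename a truth presence matrix's columns to the labels the filter chain
# produces, for direct comparison
relabel_truth <- function(fx) {
  sp <- vapply(strsplit(fx$catalog$lineage, ";"),
               function(p) length(p) >= 7 && nzchar(p[7]), logical(1))
  lab <- taxon_label(fx$catalog$lineage, ifelse(sp, "species", "genus"))
  m <- fx$pm$presence
  colnames(m) <- lab[match(colnames(m), fx$catalog$taxon)]
  m[, order(colnames(m)), drop = FALSE]
}
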
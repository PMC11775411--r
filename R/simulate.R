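#' Simulation settings for synthetic scat count tables
#'
#' @param seed integer seed; identical seeds give identical tables.
#' @param reads_per_scat sequencing depth per scat (>= 100; the control and
#'   relative-abundance rules are meaningless at lower depth).
#' @param noise_taxa number of sub-threshold contaminant taxa added to every
#'   scat (their lineages are synthetic and never collide with real prey).
#' @param noise_fraction total read share given to the noise taxa, in
#'   [0, 0.05]; must stay below the presence threshold so noise is removable
#'   by the >1 percent rule in expectation.
#' @param control_contamination maximum leaked reads per OTU in the negative
#'   control sample.
#' @param host_fraction read share taken by the predator's own (host) DNA in
#'   every scat; blocking oligos suppress but rarely eliminate host
#'   amplification, and the share exercises the host-exclusion filter.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, reads_per_scat = 10000L, noise_taxa = 0L,
                       noise_fraction = 0, control_contamination = 0L,
                       host_fraction = 0.1) {
  if (reads_per_scat < 100) abort("reads_per_scat must be >= 100")
  if (noise_fraction < 0 || noise_fraction > 0.05)
    abort("noise_fraction must be in [0, 0.05]")
  if (noise_taxa > 0 && noise_fraction == 0)
    abort("noise_taxa > 0 requires noise_fraction > 0")
  if (host_fraction < 0 || host_fraction + noise_fraction >= 1)
    abort("host_fraction + noise_fraction must be < 1")
  structure(list(seed = as.integer(seed),
                 reads_per_scat = as.integer(reads_per_scat),
                 noise_taxa = as.integer(noise_taxa),
                 noise_fraction = noise_fraction,
                 control_contamination = as.integer(control_contamination),
                 host_fraction = host_fraction),
            class = "sim_config")
}

#' Simulate a scat-by-OTU read count table from a known diet
#'
#' Emulates the sequencing output that the filter chain ingests. For each
#' scat, reads are multinomially distributed over the scat's true prey taxa
#' (equal shares of `1 - host_fraction - noise_fraction`), the noise taxa
#' (equal shares of `noise_fraction`) and a host (predator) OTU at
#' `host_fraction` (which also absorbs the prey share in scats with no prey
#' signal), so every scat sums exactly to `reads_per_scat`. A
#' negative-control sample receives only uniform leaked reads of at most
#' `control_contamination` per OTU.
#'
#' @param truth a `diet_truth` from [diet_fixture()] (or any list with
#'   elements `pm` and `catalog`).
#' @param cfg a [sim_config()].
#' @return a list of class `scat_sim`:
#'   \item{table}{[count_table()] including the flagged control sample.}
#'   \item{assignments}{data frame `otu_id`, `lineage`, `rank` — the true
#'     taxonomy of every OTU, usable directly or via [simulate_hit_table()].}
#'   \item{otu_of_taxon}{named map from catalog taxon to OTU id.}
#' @export
simulate_scat_counts <- function(truth, cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  pm <- truth$pm$presence
  cat <- truth$catalog
  n_scats <- nrow(pm)
  taxa <- colnames(pm)
  lin <- cat$lineage[match(taxa, cat$taxon)]
  if (anyNA(lin)) abort("truth catalog lacks lineages for some taxa")

  predator <- truth$pm$meta$predator[1]
  host_lineage <- switch(
    predator,
    leopard = "Animalia;Chordata;Mammalia;Carnivora;Felidae;Panthera;Panthera pardus",
    leopardcat = "Animalia;Chordata;Mammalia;Carnivora;Felidae;Prionailurus;Prionailurus bengalensis",
    "Animalia;Chordata;Mammalia;Carnivora;Felidae;Felis;Felis catus")

  m <- cfg$noise_taxa
  noise_lin <- if (m > 0)
    sprintf("Animalia;Chordata;Mammalia;Rodentia;Fictidae;Fictus;Fictus species%d",
            seq_len(m)) else character()
  otu_ids <- sprintf("OTU%03d", seq_len(length(taxa) + 1L + m))
  lineages <- c(lin, host_lineage, noise_lin)
  otu_of_taxon <- stats::setNames(otu_ids[seq_along(taxa)], taxa)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  counts <- matrix(0L, n_scats + 1L, length(otu_ids),
                   dimnames = list(c(rownames(pm), "control"), otu_ids))
  host_col <- length(taxa) + 1L
  noise_cols <- if (m > 0) host_col + seq_len(m) else integer()
  for (i in seq_len(n_scats)) {
    pres <- which(pm[i, ])
    pr <- numeric(length(otu_ids))
    prey_share <- 1 - cfg$host_fraction - cfg$noise_fraction
    pr[host_col] <- cfg$host_fraction
    if (length(pres)) pr[pres] <- prey_share / length(pres)
    else pr[host_col] <- pr[host_col] + prey_share
    if (m > 0) pr[noise_cols] <- cfg$noise_fraction / m
    counts[i, ] <- stats::rmultinom(1, cfg$reads_per_scat, pr)[, 1]
  }
  if (cfg$control_contamination > 0)
    counts[n_scats + 1L, ] <- sample.int(cfg$control_contamination + 1L,
                                         length(otu_ids),
                                         replace = TRUE) - 1L

  meta <- rbind(
    truth$pm$meta,
    data.frame(sample = "control", predator = predator, site = NA_character_,
               x = NA_real_, y = NA_real_, stringsAsFactors = FALSE))
  meta$is_control <- c(rep(FALSE, n_scats), TRUE)
  rank <- ifelse(vapply(strsplit(lineages, ";"),
                        function(p) length(p) >= 7 && nzchar(p[7]),
                        logical(1)), "species", "genus")
  structure(
    list(table = count_table(counts, meta),
         assignments = data.frame(otu_id = otu_ids, lineage = lineages,
                                  rank = rank, stringsAsFactors = FALSE),
         otu_of_taxon = otu_of_taxon),
    class = "scat_sim")
}

#' Simulate a BLAST-style hit table with controllable discordance
#'
#' Produces, for each query OTU, `n_hits` reference hits of which a fraction
#' `discordant_fraction` carry a sibling taxon (same genus, different
#' species; for genus-level truths a sibling genus in the same family)
#' instead of the true lineage. Identities and coverages are drawn uniformly
#' from the given ranges, so hits can be placed above or below the 97/85
#' consensus-classifier cutoffs.
#'
#' @param assignment_truth data frame with `otu_id` and `lineage` columns
#'   (e.g. the `assignments` element of [simulate_scat_counts()]).
#' @param n_hits hits per query (<= 50).
#' @param discordant_fraction fraction of hits carrying the sibling lineage.
#' @param seed integer seed.
#' @param identity_range,coverage_range length-2 numeric, uniform draw bounds.
#' @return data frame `otu_id`, `lineage`, `identity`, `coverage`.
#' @export
simulate_hit_table <- function(assignment_truth, n_hits = 50L,
                               discordant_fraction = 0, seed = 1L,
                               identity_range = c(97.5, 100),
                               coverage_range = c(90, 100)) {
  if (discordant_fraction < 0 || discordant_fraction > 1)
    abort("discordant_fraction must be in [0, 1]")
  if (n_hits > 50L) abort("n_hits must be <= 50")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rows <- lapply(seq_len(nrow(assignment_truth)), function(q) {
    lin <- assignment_truth$lineage[q]
    parts <- strsplit(lin, ";")[[1]]
    length(parts) <- 7L
    parts[is.na(parts)] <- ""
    sib <- parts
    if (nzchar(parts[7])) sib[7] <- paste(parts[6], "fictus")
    else sib[6] <- paste0(parts[5], "_fictigenus")
    n_disc <- round(discordant_fraction * n_hits)
    lins <- c(rep(paste(parts, collapse = ";"), n_hits - n_disc),
              rep(paste(sib, collapse = ";"), n_disc))
    data.frame(otu_id = assignment_truth$otu_id[q], lineage = lins,
               identity = stats::runif(n_hits, identity_range[1],
                                       identity_range[2]),
               coverage = stats::runif(n_hits, coverage_range[1],
                                       coverage_range[2]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Landscape specification for the raster simulator
#'
#' @param n_rows,n_cols grid dimensions.
#' @param cell_size cell edge in metres.
#' @param class_codes named integer vector over
#'   {forest, agriculture, built_up, other, water} (defaults 1-5).
#' @param background class name filling unpainted cells.
#' @param placements list of patch specs; each a list with `class`, `type`
#'   ("rect" or "ellipse"), and for rect: `row`, `col`, `nrows`, `ncols`
#'   (top-left cell + extent), for ellipse: `row`, `col` (centre cell),
#'   `ry`, `rx` (semi-axes in cells).
#' @return a `landscape_spec` list.
#' @export
landscape_spec <- function(n_rows, n_cols, cell_size = 30,
                           class_codes = c(forest = 1L, agriculture = 2L,
                                           built_up = 3L, other = 4L,
                                           water = 5L),
                           background = "other", placements = list()) {
  if (cell_size <= 0) abort("cell_size must be > 0")
  if (anyDuplicated(class_codes)) abort("class codes must be distinct")
  for (p in placements) {
    if (!p$class %in% names(class_codes))
      abort("placement class not in class_codes: ", p$class)
    if (p$type == "rect") {
      if (p$row < 1 || p$col < 1 || p$row + p$nrows - 1 > n_rows ||
          p$col + p$ncols - 1 > n_cols)
        abort("rect placement outside the grid")
    } else if (p$type == "ellipse") {
      if (p$row - p$ry < 1 || p$row + p$ry > n_rows ||
          p$col - p$rx < 1 || p$col + p$rx > n_cols)
        abort("ellipse placement outside the grid")
    } else abort("placement type must be 'rect' or 'ellipse'")
  }
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_size = cell_size, class_codes = class_codes,
                 background = background, placements = placements),
            class = "landscape_spec")
}

# cell indices (column-major) covered by one placement on an nr x nc grid
placement_cells <- function(p, nr, nc) {
  if (p$type == "rect") {
    ii <- p$row:(p$row + p$nrows - 1L)
    jj <- p$col:(p$col + p$ncols - 1L)
    as.vector(outer(ii, (jj - 1L) * nr, `+`))
  } else {
    ii <- pmax(1L, floor(p$row - p$ry)):pmin(nr, ceiling(p$row + p$ry))
    jj <- pmax(1L, floor(p$col - p$rx)):pmin(nc, ceiling(p$col + p$rx))
    g <- expand.grid(i = ii, j = jj)
    keep <- ((g$i - p$row) / p$ry)^2 + ((g$j - p$col) / p$rx)^2 <= 1
    g$i[keep] + (g$j[keep] - 1L) * nr
  }
}

#' Simulate a categorical land-cover raster with known patch geometry
#'
#' Paints the placements of a [landscape_spec()] onto a background grid in
#' order (later placements overwrite earlier ones) and returns, alongside the
#' raster, a ground-truth inventory of the visible patches: 8-connected
#' groups of cells painted with each class, with exact cell counts, areas and
#' perimeters derived by direct counting — independent of the patch
#' delineation used by the metrics code, so it can serve as an oracle.
#'
#' @param spec a [landscape_spec()].
#' @return list with `raster` (a [cat_raster()]) and `inventory`
#'   (data frame: `patch`, `class`, `n_cells`, `area_m2`, `perimeter_m`).
#' @export
simulate_landscape <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  nr <- spec$n_rows; nc <- spec$n_cols; cs <- spec$cell_size
  vals <- matrix(spec$class_codes[[spec$background]], nr, nc)
  painted_by <- vector("list", length(spec$placements))
  for (k in seq_along(spec$placements)) {
    cells <- placement_cells(spec$placements[[k]], nr, nc)
    vals[cells] <- spec$class_codes[[spec$placements[[k]]$class]]
    painted_by[[k]] <- cells
  }
  # visibility after overwrites
  for (k in seq_along(spec$placements)) {
    vis <- painted_by[[k]][
      vals[painted_by[[k]]] ==
        spec$class_codes[[spec$placements[[k]]$class]]]
    if (length(painted_by[[k]]) && !length(vis))
      warning(sprintf("placement %d (%s) fully overwritten by later placements",
                      k, spec$placements[[k]]$class))
    painted_by[[k]] <- vis
  }
  # inventory: 8-connected groups of painted cells, per class
  inv <- list()
  for (cls in unique(vapply(spec$placements, `[[`, "", "class"))) {
    cells <- sort(unique(unlist(
      painted_by[vapply(spec$placements, `[[`, "", "class") == cls])))
    if (!length(cells)) next
    comp <- group_cells_8(cells, nr, nc)
    for (g in split(cells, comp)) {
      inv[[length(inv) + 1L]] <- data.frame(
        class = cls, n_cells = length(g),
        area_m2 = length(g) * cs^2,
        perimeter_m = cell_set_perimeter(g, nr, nc) * cs)
    }
  }
  inventory <- if (length(inv)) {
    out <- do.call(rbind, inv)
    cbind(patch = seq_len(nrow(out)), out)
  } else data.frame(patch = integer(), class = character(),
                    n_cells = integer(), area_m2 = numeric(),
                    perimeter_m = numeric())
  r <- cat_raster(vals, cell_size = cs, legend = spec$class_codes)
  list(raster = r, inventory = inventory)
}

# 8-connected grouping of a set of column-major cell indices (BFS)
group_cells_8 <- function(cells, nr, nc) {
  in_set <- new.env(hash = TRUE)
  for (c0 in cells) assign(as.character(c0), TRUE, envir = in_set)
  comp <- integer(length(cells))
  names(comp) <- as.character(cells)
  cur <- 0L
  for (c0 in cells) {
    if (comp[[as.character(c0)]] != 0L) next
    cur <- cur + 1L
    queue <- c0
    comp[[as.character(c0)]] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      i <- (v - 1L) %% nr + 1L; j <- (v - 1L) %/% nr + 1L
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
        w <- ii + (jj - 1L) * nr
        key <- as.character(w)
        if (!is.null(in_set[[key]]) && comp[[key]] == 0L) {
          comp[[key]] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  unname(comp)
}

# number of exposed 4-neighbour faces of a cell set (boundary faces count)
cell_set_perimeter <- function(cells, nr, nc) {
  s <- logical(nr * nc); s[cells] <- TRUE
  i <- (cells - 1L) %% nr + 1L; j <- (cells - 1L) %/% nr + 1L
  p <- 0L
  for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    ii <- i + d[1]; jj <- j + d[2]
    inside <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
    nb <- rep(FALSE, length(cells))
    nb[inside] <- s[ii[inside] + (jj[inside] - 1L) * nr]
    p <- p + sum(!nb)
  }
  p
}
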
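#' Default run configuration
#'
#' All analysis parameters in one list, with defaults equal to the field
#' protocol the package implements: 97 percent identity / 85 percent coverage
#' BLAST cutoffs, 0.51 consensus, >1 percent relative-abundance presence
#' rule, 100 m edge depth, 150 m focal radius, buffer radii
#' 1000/1500/2000/3500/4500 m.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @return a `run_config` list, round-trippable through YAML via
#'   [write_run_config()] / [read_run_config()].
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    predators = c("leopard", "leopardcat"),
    thresholds = list(identity = 97, coverage = 85, consensus = 0.51,
                      presence = 0.01),
    edge_depth = 100,
    focal_radius = 150,
    buffer_radii = c(1000, 1500, 2000, 3500, 4500),
    simulation = list(reads_per_scat = 10000L, noise_taxa = 2L,
                      noise_fraction = 0.005, control_contamination = 5L,
                      host_fraction = 0.1, n_hits = 50L,
                      discordant_fraction = 0)
  ), class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param cfg a `run_config` list.
#' @param path YAML file path.
#' @return `read_run_config` returns the `run_config`; `write_run_config`
#'   returns `path` invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

#' Demonstration landscape with six named forest areas
#'
#' A deterministic 200 x 200 cell (30 m) land-cover grid on an agricultural
#' background with six named forest areas of deliberately different
#' fragmentation structure (from one large compact block to many small
#' scattered fragments), built-up seams and a water body. Used by
#' [run_pipeline()] and convenient for examples.
#'
#' @return list with `raster` (a [cat_raster()]), `inventory`, `unit_masks`
#'   (named list of logical matrices, one per forest area) and `sites`
#'   (the area names).
#' @export
demo_landscape <- function() {
  nr <- 200L; nc <- 200L
  rect <- function(class, row, col, nrows, ncols)
    list(class = class, type = "rect", row = row, col = col,
         nrows = nrows, ncols = ncols)
  pl <- list(
    # SH: one large compact block (low fragmentation)
    rect("forest", 11, 6, 80, 55),
    # NJ: two medium blocks
    rect("forest", 16, 76, 45, 26), rect("forest", 66, 106, 30, 24),
    # CH: three medium blocks
    rect("forest", 11, 141, 30, 26), rect("forest", 46, 171, 26, 22),
    rect("forest", 76, 141, 20, 20),
    # PH: four smaller blocks
    rect("forest", 106, 11, 20, 16), rect("forest", 131, 31, 18, 14),
    rect("forest", 156, 11, 16, 14), rect("forest", 176, 41, 14, 12),
    # ID: many small scattered fragments (high fragmentation)
    rect("forest", 106, 76, 7, 6), rect("forest", 118, 90, 6, 5),
    rect("forest", 131, 78, 6, 6), rect("forest", 143, 92, 5, 5),
    rect("forest", 156, 79, 6, 5), rect("forest", 168, 93, 5, 5),
    rect("forest", 181, 78, 5, 5), rect("forest", 188, 96, 4, 4),
    # NK: small scattered fragments
    rect("forest", 106, 146, 8, 7), rect("forest", 121, 166, 7, 6),
    rect("forest", 136, 146, 7, 6), rect("forest", 151, 171, 6, 6),
    rect("forest", 166, 146, 6, 6), rect("forest", 181, 168, 6, 5),
    # built-up seams and water
    rect("built_up", 96, 1, 8, 200),
    rect("built_up", 1, 131, 95, 6),
    rect("water", 185, 120, 12, 12))
  sim <- simulate_landscape(landscape_spec(nr, nc, cell_size = 30,
                                           background = "agriculture",
                                           placements = pl))
  region <- function(rows, cols) {
    m <- matrix(FALSE, nr, nc)
    m[rows, cols] <- TRUE
    m
  }
  masks <- list(
    SH = region(1:95, 1:70), NJ = region(1:95, 71:130),
    CH = region(1:95, 131:200), PH = region(104:200, 1:70),
    ID = region(104:200, 71:130), NK = region(104:200, 131:200))
  list(raster = sim$raster, inventory = sim$inventory, unit_masks = masks,
       sites = names(masks))
}

# combine presence matrices from several predators (union of taxa)
combine_presence <- function(pms) {
  taxa <- unique(unlist(lapply(pms, function(p) colnames(p$presence))))
  mats <- lapply(pms, function(p) {
    m <- matrix(FALSE, nrow(p$presence), length(taxa),
                dimnames = list(rownames(p$presence), taxa))
    m[, colnames(p$presence)] <- p$presence
    m
  })
  presence_matrix(do.call(rbind, mats),
                  do.call(rbind, lapply(pms, function(p) p$meta)))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the whole analysis pipeline
#'
#' Executes every stage in order on seeded synthetic inputs: diet-table
#' fixtures, simulated count and hit tables, consensus assignment, the
#' filter chain, diet statistics, the demonstration landscape with
#' fragmentation metrics and median-rank classification, buffer composition
#' and forest-edge distances around scat points, interface rasters, PCA
#' reliance scores and the linear models. Every output file is written under
#' `outdir` and hashed (MD5) into a manifest, so a rerun with the same
#' config produces an identical manifest.
#'
#' @param cfg a `run_config` (see [default_config()]) or path to a YAML file.
#' @param outdir output directory (created if needed).
#' @return the manifest (list with `config` and named file hashes),
#'   invisibly; also written to `manifest.json`.
#' @export
run_pipeline <- function(cfg = default_config(), outdir) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e))))
  }
  th <- cfg$thresholds
  files <- character()
  put <- function(path) files <<- c(files, path)

  # --- stage: diet (per predator) ---------------------------------------
  land <- stage("landscape", demo_landscape())
  pms <- list()
  catalogs <- list()
  for (k in seq_along(cfg$predators)) {
    pred <- cfg$predators[k]
    sd <- cfg$seed + k
    res <- stage(paste0("diet_", pred), {
      truth <- diet_fixture(pred, seed = sd)
      scfg <- sim_config(seed = sd,
                         reads_per_scat = cfg$simulation$reads_per_scat,
                         noise_taxa = cfg$simulation$noise_taxa,
                         noise_fraction = cfg$simulation$noise_fraction,
                         control_contamination =
                           cfg$simulation$control_contamination,
                         host_fraction = cfg$simulation$host_fraction)
      sim <- simulate_scat_counts(truth, scfg)
      hits <- simulate_hit_table(sim$assignments,
                                 n_hits = cfg$simulation$n_hits,
                                 discordant_fraction =
                                   cfg$simulation$discordant_fraction,
                                 seed = sd)
      asn <- consensus_assign(hits, min_consensus = th$consensus,
                              min_identity = th$identity,
                              min_coverage = th$coverage)
      pm <- filter_counts(sim$table, asn, threshold = th$presence)
      list(truth = truth, pm = pm,
           profile = diet_profile(pm, truth$catalog))
    })
    pms[[pred]] <- res$pm
    catalogs[[pred]] <- res$truth$catalog
    put(write_tsv(data.frame(sample = rownames(res$pm$presence),
                             res$pm$presence * 1L, check.names = FALSE),
                  file.path(outdir, paste0("presence_", pred, ".tsv"))))
    put(write_tsv(res$profile$table,
                  file.path(outdir, paste0("diet_profile_", pred, ".tsv"))))
    jsonlite::write_json(
      list(N = res$profile$N, n_scats = res$profile$n_scats,
           levins_bsta = round_half_up(res$profile$levins_bsta, 2),
           group_po = as.list(res$profile$group_po),
           origin_po = as.list(res$profile$origin_po)),
      file.path(outdir, paste0("diet_summary_", pred, ".json")),
      auto_unbox = TRUE, digits = NA)
    put(file.path(outdir, paste0("diet_summary_", pred, ".json")))
  }

  # --- stage: scat locations --------------------------------------------
  r <- land$raster
  points <- stage("points", {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(cfg$seed + 100L)
    rows <- list()
    for (pred in cfg$predators) {
      pm <- pms[[pred]]
      sites <- sample(land$sites, nrow(pm$presence), replace = TRUE)
      for (i in seq_len(nrow(pm$presence))) {
        cand <- which(land$unit_masks[[sites[i]]] &
                        r$values == r$legend[["forest"]])
        cell <- cand[sample.int(length(cand), 1)]
        nr <- nrow(r$values)
        ci <- (cell - 1L) %% nr + 1L; cj <- (cell - 1L) %/% nr + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          id = rownames(pm$presence)[i], predator = pred, site = sites[i],
          x = r$origin[1] + (cj - 0.5) * r$cell_size,
          y = r$origin[2] + (nr - ci + 0.5) * r$cell_size,
          contains_cattle = "Bos taurus" %in% colnames(pm$presence) &&
            pm$presence[i, "Bos taurus"])
      }
    }
    do.call(rbind, rows)
  })
  put(write_tsv(points, file.path(outdir, "scat_points.tsv")))

  # --- stage: fragmentation ---------------------------------------------
  frag <- stage("fragmentation", {
    whole <- metrics_at_scales(r, "forest", "whole",
                               edge_depth = cfg$edge_depth)
    units <- metrics_at_scales(r, "forest", land$unit_masks,
                               edge_depth = cfg$edge_depth)
    buf <- metrics_at_scales(r, "forest", points, buffer = 1000,
                             edge_depth = cfg$edge_depth)
    list(whole = whole, units = units, buffers = buf,
         ranking = classify_fragmentation(units),
         buffer_ranking = classify_fragmentation(buf))
  })
  put(write_tsv(rbind(frag$whole, frag$units),
                file.path(outdir, "landscape_metrics.tsv")))
  put(write_tsv(frag$ranking, file.path(outdir, "fragmentation_ranking.tsv")))
  put(write_tsv(frag$buffers, file.path(outdir, "buffer_metrics.tsv")))

  # --- stage: spatial context -------------------------------------------
  ctx <- stage("context", {
    comp <- suppressWarnings(
      buffer_composition(r, points, radii = cfg$buffer_radii))
    edge <- vapply(seq_len(nrow(points)), function(k)
      distance_to_forest_edge(r, points$x[k], points$y[k]), numeric(1))
    cattle <- cattle_context_comparison(r, points)
    list(comp = comp, edge = edge, cattle = cattle)
  })
  put(write_tsv(ctx$comp, file.path(outdir, "buffer_composition.tsv")))
  put(write_tsv(data.frame(id = points$id, edge_dist_m = ctx$edge),
                file.path(outdir, "edge_distance.tsv")))
  put(write_tsv(ctx$cattle, file.path(outdir, "cattle_context.tsv")))

  # --- stage: interfaces -------------------------------------------------
  wui <- stage("interfaces", interface_rasters(r, radius = cfg$focal_radius))
  for (nm in c("fa", "fb", "fab")) {
    ir <- cat_raster((wui[[nm]]) * 1L, cell_size = r$cell_size,
                     origin = r$origin, nodata = -9999L)
    put(write_ascii_grid(ir, file.path(outdir,
                                       paste0("interface_", nm, ".asc"))))
  }
  jsonlite::write_json(list(area_ha = as.list(wui$area_ha),
                            percent = as.list(wui$percent)),
                       file.path(outdir, "interface_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  put(file.path(outdir, "interface_summary.json"))

  # --- stage: statistics --------------------------------------------------
  stats_out <- stage("statistics", {
    pm_all <- combine_presence(pms)
    cat_all <- do.call(rbind, lapply(catalogs, as.data.frame))
    cat_all <- prey_catalog(cat_all[!duplicated(cat_all$taxon), ])
    sc <- reliance_scores(pm_all, cat_all)
    comp1000 <- ctx$comp[ctx$comp$radius == 1000 &
                           ctx$comp$class == "forest", ]
    dat <- data.frame(
      pc1 = sc$pc1,
      patch = points$site[match(sc$sample, points$id)],
      predator = points$predator[match(sc$sample, points$id)],
      forest_prop = comp1000$proportion[match(sc$sample, comp1000$id)],
      edge_dist = ctx$edge[match(sc$sample, points$id)],
      frag_class = frag$buffer_ranking$frag_class[
        match(sc$sample, frag$buffer_ranking$unit)])
    list(scores = sc, data = dat, report = fit_diet_models(dat))
  })
  put(write_tsv(cbind(as.data.frame(stats_out$scores),
                      stats_out$data[c("patch", "forest_prop", "edge_dist",
                                       "frag_class")]),
                file.path(outdir, "reliance_scores.tsv")))
  rep <- stats_out$report
  jsonlite::write_json(list(
    patch_predator = c(list(r_squared = rep$patch_predator$r_squared),
                       rep$patch_predator$f),
    disturbance = c(list(r_squared = rep$disturbance$r_squared),
                    rep$disturbance$f)),
    file.path(outdir, "model_report.json"), auto_unbox = TRUE, digits = NA)
  put(file.path(outdir, "model_report.json"))

  # --- manifest -----------------------------------------------------------
  put(write_run_config(cfg, file.path(outdir, "config.yaml")))
  hashes <- tools::md5sum(sort(unique(files)))
  names(hashes) <- basename(names(hashes))
  manifest <- list(seed = cfg$seed, config = unclass(cfg),
                   files = as.list(hashes))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
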
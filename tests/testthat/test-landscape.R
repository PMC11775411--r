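legend3 <- c(forest = 1L, agriculture = 2L, built_up = 3L)

test_that("diagonal touch merges under the 8-neighbourhood rule", {
  v <- matrix(2L, 10, 10)
  v[2:3, 2:3] <- 1L
  v[4:5, 4:5] <- 1L
  r <- cat_raster(v, 30, legend = legend3)
  expect_equal(nrow(delineate_patches(r, "forest")$patches), 1L)
  # separated by one cell -> two patches
  v[4:5, 4:5] <- 2L
  v[5:6, 5:6] <- 1L
  expect_equal(nrow(delineate_patches(cat_raster(v, 30, legend = legend3),
                                      "forest")$patches), 2L)
})

test_that("full-raster single class: one patch, boundary perimeter", {
  r <- cat_raster(matrix(1L, 6, 9), 30, legend = legend3)
  ps <- delineate_patches(r, "forest")
  expect_equal(nrow(ps$patches), 1L)
  expect_equal(ps$patches$perimeter_m, 2 * (6 + 9) * 30)
  # absent class: empty patch set, all-NA metrics
  ps0 <- delineate_patches(r, "built_up")
  expect_equal(nrow(ps0$patches), 0L)
  m0 <- class_metrics(ps0, 100)
  expect_true(all(is.na(m0[c("pd", "ed", "mpa", "msi", "mca", "enn")])))
})

test_that("patch labeling matches a flood-fill oracle on random grids", {
  for (s in 1:30) {
    set.seed(s)
    m <- matrix(runif(15 * 15) < 0.45, 15, 15)
    r <- cat_raster(matrix(ifelse(m, 1L, 2L), 15, 15), 30, legend = legend3)
    got <- delineate_patches(r, "forest")$labels
    want <- oracle_label8(m)
    # same partition (label ids may differ)
    expect_equal(max(got), max(want))
    if (max(want) > 0) {
      key <- paste(got[m], want[m])
      expect_equal(length(unique(key)), max(want))
    }
  }
})

test_that("closed-form metric values", {
  # 3x3 square, 30 m cells: MSI = 0.25 * 360 / sqrt(8100) = 1
  v <- matrix(2L, 9, 9); v[4:6, 4:6] <- 1L
  r <- cat_raster(v, 30, legend = legend3)
  m <- class_metrics(delineate_patches(r, "forest"), 100)
  expect_equal(m$msi, 1)
  # one patch in a 100-ha landscape: PD = 1 per 100 ha
  expect_equal(m$pd, 1)
  # 10x10-cell patch, 100 m depth: core = inner 4x4 = 16 cells = 1.44 ha
  v2 <- matrix(2L, 20, 20); v2[6:15, 6:15] <- 1L
  m2 <- class_metrics(delineate_patches(cat_raster(v2, 30, legend = legend3),
                                        "forest"), 36, edge_depth = 100)
  expect_equal(m2$mca, 1.44)
  expect_equal(m2$mpa, 9)
})

test_that("MSI is 1 exactly for squares and > 1 for non-square rectangles", {
  for (s in 1:20) {
    set.seed(s)
    a <- sample(2:6, 1); b <- sample(2:6, 1)
    v <- matrix(2L, 12, 12); v[2:(1 + a), 2:(1 + b)] <- 1L
    m <- class_metrics(delineate_patches(cat_raster(v, 30, legend = legend3),
                                         "forest"), 12.96)
    if (a == b) expect_equal(m$msi, 1) else expect_gt(m$msi, 1)
  }
})

test_that("scaling cell size scales areas x4, perimeters x2, MSI unchanged", {
  set.seed(3)
  v <- matrix(sample(1:2, 400, TRUE), 20, 20)
  p1 <- delineate_patches(cat_raster(v, 30, legend = legend3), "forest")
  p2 <- delineate_patches(cat_raster(v, 60, legend = legend3), "forest")
  expect_equal(p2$patches$area_m2, 4 * p1$patches$area_m2)
  expect_equal(p2$patches$perimeter_m, 2 * p1$patches$perimeter_m)
  m1 <- class_metrics(p1, 36); m2 <- class_metrics(p2, 144)
  expect_equal(m1$msi, m2$msi)
})

test_that("MCA <= MPA always, with equality at zero edge depth", {
  for (s in 1:15) {
    r <- random_raster(s, 18, 18)
    ps <- delineate_patches(r, "forest")
    if (nrow(ps$patches) == 0) next
    m100 <- class_metrics(ps, 29.16, edge_depth = 100)
    m0 <- class_metrics(ps, 29.16, edge_depth = 0)
    expect_lte(m100$mca, m100$mpa)
    expect_equal(m0$mca, m0$mpa)
  }
})

test_that("all six metrics match the brute-force oracle on random rasters", {
  for (s in 1:40) {
    set.seed(s)
    nr <- sample(8:20, 1); nc <- sample(8:20, 1)
    r <- random_raster(s + 1000, nr, nc, p_forest = runif(1, 0.2, 0.6))
    area_ha <- nr * nc * 900 / 1e4
    depth <- sample(c(0, 30, 60, 100), 1)
    got <- class_metrics(delineate_patches(r, "forest"), area_ha, depth)
    want <- oracle_class_metrics(r$values, 1L, 30, area_ha, depth)
    expect_equal(got$n_patches, want$n_patches)
    for (f in c("pd", "ed", "mpa", "msi", "mca", "enn"))
      expect_equal(got[[f]], want[[f]], tolerance = 1e-12, label = f)
  }
})

test_that("whole-raster scale equals direct metrics; units are local", {
  r <- random_raster(5, 20, 20)
  whole <- metrics_at_scales(r, "forest", "whole")
  direct <- class_metrics(delineate_patches(r, "forest"), 36)
  expect_equal(whole[names(direct)], direct)
  # disjoint unit masks: metrics depend only on the unit's own content
  m1 <- matrix(FALSE, 20, 20); m1[1:10, ] <- TRUE
  m2 <- !m1
  u <- metrics_at_scales(r, "forest", list(top = m1, bottom = m2))
  r2 <- r; r2$values[11:20, ] <- 2L   # rewrite the other unit
  u2 <- metrics_at_scales(r2, "forest", list(top = m1))
  expect_equal(u[u$unit == "top", -1], u2[, -1])
})

test_that("buffer units clip to circles of cell centres", {
  v <- matrix(1L, 41, 41)
  r <- cat_raster(v, 30, legend = legend3)
  pts <- data.frame(id = "c", x = 41 * 30 / 2, y = 41 * 30 / 2)
  got <- metrics_at_scales(r, "forest", pts, buffer = 300)
  n_cells <- sum(oracle_circle_cells(r, pts$x, pts$y, 300))
  expect_equal(got$n_patches, 1L)
  expect_equal(got$pd, 1 / (n_cells * 900 / 1e4) * 100)
})

test_that("median-rank classifier matches exhaustive rank computation", {
  for (s in 1:60) {
    set.seed(s)
    k <- sample(3:6, 1)
    rows <- data.frame(unit = letters[1:k], pd = runif(k), ed = runif(k),
                       mpa = runif(k), msi = 1 + runif(k), mca = runif(k),
                       enn = runif(k) * 100)
    got <- classify_fragmentation(rows)
    # exhaustive oracle: rank by sorting, median by hand
    meds <- vapply(seq_len(k), function(i) {
      rks <- c(sum(rows$pd <= rows$pd[i]) / 1,
               sum(rows$ed <= rows$ed[i]),
               sum(rows$mpa >= rows$mpa[i]),
               sum(rows$msi <= rows$msi[i]),
               sum(rows$mca >= rows$mca[i]),
               sum(rows$enn <= rows$enn[i]))
      stats::median(rks)
    }, numeric(1))
    expect_equal(got$median_rank, meds)
    # tertile membership from sorted positions (no ties with runif draws)
    pos <- rank(meds)
    want <- ifelse(pos <= k / 3, "low",
                   ifelse(pos <= 2 * k / 3, "moderate", "high"))
    expect_equal(as.character(got$frag_class), want)
  }
})

test_that("a unit dominating every fragmentation direction is classed high", {
  rows <- data.frame(
    unit = c("A", "B", "C"),
    pd = c(1, 2, 9), ed = c(5, 6, 50), mpa = c(40, 30, 2),
    msi = c(1.1, 1.2, 2.5), mca = c(30, 20, 0.5), enn = c(50, 60, 400))
  got <- classify_fragmentation(rows)
  expect_equal(as.character(got$frag_class),
               c("low", "moderate", "high"))
})

test_that("fully tied units are all classed moderate", {
  rows <- data.frame(unit = c("A", "B", "C"), pd = 1, ed = 1, mpa = 1,
                     msi = 1, mca = 1, enn = 1)
  got <- classify_fragmentation(rows)
  expect_equal(as.character(got$frag_class), rep("moderate", 3))
  expect_error(classify_fragmentation(rows[1:2, ]), "at least 3")
})

test_that("small dispersed forest ranks more fragmented than large compact", {
  # synthetic geometries: one compact block vs many small fragments
  rect <- function(class, row, col, nrows, ncols)
    list(class = class, type = "rect", row = row, col = col, nrows = nrows,
         ncols = ncols)
  sp <- landscape_spec(60, 180, cell_size = 30, background = "agriculture",
    placements = c(
      list(rect("forest", 11, 11, 40, 40)),                 # compact
      list(rect("forest", 11, 71, 20, 20),
           rect("forest", 36, 95, 14, 14)),                 # intermediate
      list(rect("forest", 11, 131, 5, 5), rect("forest", 21, 141, 4, 4),
           rect("forest", 31, 131, 5, 4), rect("forest", 41, 145, 4, 5),
           rect("forest", 51, 133, 4, 4), rect("forest", 16, 155, 4, 4))))
  r <- simulate_landscape(sp)$raster
  region <- function(cols) {
    m <- matrix(FALSE, 60, 180); m[, cols] <- TRUE; m
  }
  units <- list(compact = region(1:60), mid = region(61:120),
                dispersed = region(121:180))
  rows <- metrics_at_scales(r, "forest", units)
  got <- classify_fragmentation(rows)
  expect_equal(as.character(got$frag_class[got$unit == "dispersed"]), "high")
  expect_equal(as.character(got$frag_class[got$unit == "compact"]), "low")
})
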
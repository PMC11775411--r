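#' Domestic-prey reliance scores from PCA
#'
#' Collapses the presence matrix to group-by-origin indicator columns (e.g.
#' domestic ungulate, wild rodent: 1 if any member taxon is present in the
#' scat), runs PCA on the indicators (covariance matrix by default, since all
#' variables share the 0/1 scale), and extracts the first principal component
#' as a per-scat reliance score. The sign of PC1 is arbitrary in PCA, so the
#' score is oriented such that scats containing at least one domestic taxon
#' have a mean score no lower than scats with none: higher = more reliant on
#' domestic prey.
#'
#' @param pm a [presence_matrix()] (>= 3 scats).
#' @param catalog a [prey_catalog()].
#' @param use_correlation scale indicators to unit variance before PCA.
#' @return object of class `reliance_scores`: data frame `sample`,
#'   `predator`, `site`, `pc1`, `domestic_any`, with the PCA rotation and
#'   variance share of PC1 in attributes.
#' @export
reliance_scores <- function(pm, catalog, use_correlation = FALSE) {
  stopifnot(inherits(pm, "presence_matrix"))
  if (nrow(pm$presence) < 3) abort("need at least 3 scats for PCA")
  idx <- match_catalog(colnames(pm$presence), catalog)
  grp <- paste(catalog$origin[idx], catalog$group[idx], sep = "_")
  ind <- t(rowsum(t(pm$presence * 1L), group = grp)) > 0L
  ind <- ind * 1
  if (all(apply(ind, 2, stats::var) == 0))
    abort("constant indicator matrix: PCA undefined")
  if (use_correlation) ind <- ind[, apply(ind, 2, stats::var) > 0,
                                  drop = FALSE]
  pca <- stats::prcomp(ind, center = TRUE, scale. = use_correlation)
  pc1 <- pca$x[, 1]
  dom <- catalog$origin[idx] == "domestic"
  domestic_any <- rowSums(pm$presence[, dom, drop = FALSE]) > 0
  if (any(domestic_any) && any(!domestic_any) &&
      mean(pc1[domestic_any]) < mean(pc1[!domestic_any])) {
    pc1 <- -pc1
    pca$rotation[, 1] <- -pca$rotation[, 1]
  }
  out <- data.frame(sample = pm$meta$sample, predator = pm$meta$predator,
                    site = pm$meta$site, pc1 = unname(pc1),
                    domestic_any = domestic_any,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "rotation") <- pca$rotation
  attr(out, "var_share_pc1") <- pca$sdev[1]^2 / sum(pca$sdev^2)
  class(out) <- c("reliance_scores", "data.frame")
  out
}

#' Fit the diet-disturbance linear models
#'
#' Two model contracts on per-scat reliance scores:
#' (i) `pc1 ~ patch * predator` with a two-way ANOVA including the
#' interaction (which forests and which predator drive domestic-prey
#' reliance), and (ii) `pc1 ~ forest_prop + edge_dist + frag_class`
#' (does landscape disturbance around the scat predict reliance). Either
#' model is fitted when its predictors are present in `data`.
#'
#' @param data data frame with `pc1` and any of `patch`, `predator`,
#'   `forest_prop`, `edge_dist`, `frag_class`.
#' @return object of class `diet_model_report`: list with elements
#'   `patch_predator` and/or `disturbance`, each containing the `lm` fit,
#'   `r_squared`, the overall F statistic with df and p, and (for model i)
#'   the ANOVA table.
#' @export
fit_diet_models <- function(data) {
  if (!"pc1" %in% names(data)) abort("`data` needs a pc1 column")
  report <- list()
  fstat <- function(fit) {
    fs <- summary(fit)$fstatistic
    if (is.null(fs)) return(NULL)
    list(F = unname(fs[1]), df1 = unname(fs[2]), df2 = unname(fs[3]),
         p = unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)))
  }
  check_rank <- function(fit) {
    if (anyNA(stats::coef(fit)))
      warning("rank-deficient design: some terms dropped")
    fit
  }
  if (all(c("patch", "predator") %in% names(data))) {
    fit <- check_rank(stats::lm(pc1 ~ patch * predator, data = data))
    report$patch_predator <- list(
      fit = fit, r_squared = summary(fit)$r.squared, f = fstat(fit),
      anova = stats::anova(fit))
  }
  if (all(c("forest_prop", "edge_dist", "frag_class") %in% names(data))) {
    fit <- check_rank(
      stats::lm(pc1 ~ forest_prop + edge_dist + frag_class, data = data))
    report$disturbance <- list(
      fit = fit, r_squared = summary(fit)$r.squared, f = fstat(fit))
  }
  if (!length(report)) abort("no complete predictor set found in `data`")
  class(report) <- "diet_model_report"
  report
}

#' @export
print.diet_model_report <- function(x, ...) {
  if (!is.null(x$patch_predator)) {
    m <- x$patch_predator
    cat(sprintf("PC1 ~ patch * predator: R^2 = %.2f, F(%d,%d) = %.2f, p = %.3g\n",
                m$r_squared, m$f$df1, m$f$df2, m$f$F, m$f$p))
  }
  if (!is.null(x$disturbance)) {
    m <- x$disturbance
    cat(sprintf("PC1 ~ forest + edge + fragmentation: R^2 = %.2f, F(%d,%d) = %.2f, p = %.3g\n",
                m$r_squared, m$f$df1, m$f$df2, m$f$F, m$f$p))
  }
  invisible(x)
}

#' Mean reliance per forest patch and predator, with 95 percent CIs
#'
#' Summary behind the classic CI plot of domestic-prey reliance: for each
#' patch-by-predator cell, the mean PC1 score and a t-based 95 percent
#' confidence interval (NA half-width for singleton cells).
#'
#' @param scores a [reliance_scores()] data frame with a `patch` column (or
#'   `site` used as patch).
#' @return data frame `patch`, `predator`, `n`, `mean`, `lower`, `upper`.
#' @export
reliance_ci_table <- function(scores) {
  patch <- scores$patch %||% scores$site
  grp <- interaction(patch, scores$predator, drop = TRUE)
  rows <- lapply(levels(grp), function(g) {
    v <- scores$pc1[grp == g]
    hw <- if (length(v) > 1)
      stats::qt(0.975, length(v) - 1) * stats::sd(v) / sqrt(length(v))
    else NA_real_
    parts <- strsplit(g, ".", fixed = TRUE)[[1]]
    data.frame(patch = parts[1], predator = parts[2], n = length(v),
               mean = mean(v), lower = mean(v) - hw, upper = mean(v) + hw)
  })
  do.call(rbind, rows)
}
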
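#' Scat-by-OTU count table
#'
#' Read counts per scat sample and OTU, with per-sample metadata. One sample
#' per sequencing run may be flagged as the negative extraction/PCR control;
#' the control drives the minimum-read threshold filter.
#'
#' @param counts non-negative integer matrix, rows = samples, cols = OTUs,
#'   with row and column names.
#' @param meta data frame with one row per sample: columns `sample`,
#'   `predator`, `site`, `x`, `y`, `is_control` (logical).
#' @return an object of class `count_table`.
#' @export
count_table <- function(counts, meta) {
  if (!is.matrix(counts) || is.null(rownames(counts)) ||
      (ncol(counts) > 0L && is.null(colnames(counts))))
    abort("`counts` must be a matrix with row (sample) and column (OTU) names")
  if (ncol(counts) == 0L)
    dimnames(counts) <- list(rownames(counts), character(0))
  if (any(counts < 0) || any(counts != round(counts)))
    abort("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  need <- c("sample", "predator", "site", "x", "y", "is_control")
  if (!all(need %in% names(meta)))
    abort("meta must have columns: ", paste(need, collapse = ", "))
  if (!identical(rownames(counts), as.character(meta$sample)))
    abort("rownames(counts) must equal meta$sample, in order")
  if (sum(meta$is_control) > 1L)
    abort("at most one negative-control sample per run")
  structure(list(counts = counts, meta = meta), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d OTUs (%s control)\n",
              nrow(x$counts), ncol(x$counts),
              if (any(x$meta$is_control)) "with" else "no"))
  invisible(x)
}

#' Scat-by-prey-taxon presence matrix
#'
#' The boolean basis of all diet statistics: one row per scat, one column per
#' prey taxon, `TRUE` where the taxon passed every filter in that scat.
#' All-absent taxon columns are dropped on construction.
#'
#' @param presence logical matrix, rows = scats, cols = prey taxa, named.
#' @param meta data frame with one row per scat: `sample`, `predator`,
#'   `site`, `x`, `y` (x/y may be NA where locations are not used).
#' @param drop_empty_taxa drop all-FALSE columns (default TRUE).
#' @return an object of class `presence_matrix`.
#' @export
presence_matrix <- function(presence, meta = NULL, drop_empty_taxa = TRUE) {
  if (!is.matrix(presence) || !is.logical(presence))
    abort("`presence` must be a logical matrix")
  if (ncol(presence) > 0L && is.null(colnames(presence)))
    abort("presence needs taxon column names")
  if (anyDuplicated(colnames(presence))) abort("duplicate taxon columns")
  if (drop_empty_taxa) {
    keep <- colSums(presence) > 0L
    presence <- presence[, keep, drop = FALSE]
  }
  if (is.null(meta)) {
    meta <- data.frame(sample = rownames(presence) %||%
                         paste0("scat", seq_len(nrow(presence))),
                       predator = NA_character_, site = NA_character_,
                       x = NA_real_, y = NA_real_)
  }
  if (is.null(rownames(presence))) rownames(presence) <- meta$sample
  structure(list(presence = presence, meta = meta),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("presence_matrix: %d scats x %d prey taxa, %d occurrences\n",
              nrow(x$presence), ncol(x$presence), sum(x$presence)))
  invisible(x)
}

#' Prey catalog
#'
#' Registry of prey taxa: broad group, domestic/wild origin, and approximate
#' adult mass. Every presence-matrix column must resolve to one catalog row.
#'
#' @param df data frame with columns `taxon`, `group`, `origin`, `mass_kg`
#'   (and optionally `lineage`, a `;`-separated
#'   kingdom;phylum;class;order;family;genus;species path).
#' @return a `prey_catalog` data frame.
#' @export
prey_catalog <- function(df) {
  need <- c("taxon", "group", "origin", "mass_kg")
  if (!all(need %in% names(df)))
    abort("catalog needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$taxon)) abort("duplicate taxa in catalog")
  ok_groups <- c("ungulate", "carnivore", "primate", "bird", "rodent",
                 "shrew", "fish")
  bad <- setdiff(df$group, ok_groups)
  if (length(bad)) abort("unknown prey group(s): ", paste(bad, collapse = ", "))
  if (!all(df$origin %in% c("domestic", "wild")))
    abort("origin must be 'domestic' or 'wild'")
  class(df) <- c("prey_catalog", "data.frame")
  df
}
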
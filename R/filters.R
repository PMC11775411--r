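#' Consensus taxonomy assignment from a hit table
#'
#' Assigns each query OTU to the deepest taxonomic rank at which a single
#' taxon accounts for at least `min_consensus` of the qualifying reference
#' hits, descending species -> genus -> family. Hits failing the identity or
#' coverage cutoff are discarded first, then the top `max_hits` by identity
#' are used. A query with no qualifying hits, or no family-level consensus,
#' is returned as `unassigned`.
#'
#' @param hits data frame with columns `otu_id`, `lineage` (a `;`-separated
#'   kingdom;phylum;class;order;family;genus;species path, deeper fields may
#'   be empty), `identity`, `coverage` (percent).
#' @param max_hits maximum hits considered per query (default 50).
#' @param min_consensus minimum agreeing fraction (default 0.51, i.e. 26 of
#'   50 hits pass, 25 of 50 do not).
#' @param min_identity,min_coverage percent cutoffs (defaults 97 and 85).
#' @return data frame with one row per query: `otu_id`, `lineage` (truncated
#'   to the achieved rank; NA when unassigned), `rank`
#'   (species/genus/family/unassigned), `consensus` (agreeing fraction).
#' @export
consensus_assign <- function(hits, max_hits = 50L, min_consensus = 0.51,
                             min_identity = 97, min_coverage = 85) {
  need <- c("otu_id", "lineage", "identity", "coverage")
  if (!all(need %in% names(hits)))
    abort("hits must have columns: ", paste(need, collapse = ", "))
  rank_names <- c("kingdom", "phylum", "class", "order", "family", "genus",
                  "species")
  ids <- unique(hits$otu_id)
  out <- lapply(ids, function(id) {
    h <- hits[hits$otu_id == id, , drop = FALSE]
    h <- h[h$identity >= min_identity & h$coverage >= min_coverage, ,
           drop = FALSE]
    h <- h[order(-h$identity), , drop = FALSE]
    if (nrow(h) > max_hits) h <- h[seq_len(max_hits), , drop = FALSE]
    res <- data.frame(otu_id = id, lineage = NA_character_,
                      rank = "unassigned", consensus = NA_real_,
                      stringsAsFactors = FALSE)
    if (nrow(h) == 0L) return(res)
    parts <- strsplit(h$lineage, ";")
    for (depth in 7:5) {
      keys <- vapply(parts, function(p) {
        if (length(p) >= depth && nzchar(p[depth]))
          paste(p[1:depth], collapse = ";") else NA_character_
      }, character(1))
      tab <- table(keys[!is.na(keys)])
      if (!length(tab)) next
      frac <- max(tab) / nrow(h)
      if (frac >= min_consensus) {
        res$lineage <- names(tab)[which.max(tab)]
        res$rank <- rank_names[depth]
        res$consensus <- frac
        return(res)
      }
    }
    res
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Negative-control minimum-read threshold filter
#'
#' Derives the minimum read threshold T as the largest per-OTU count observed
#' in the flagged negative-control sample, zeroes every table entry `<= T`,
#' removes the control sample and drops OTU columns left with no reads.
#'
#' @param tab a [count_table()] with the control flagged.
#' @param missing_control `"warn"` (use T = 0, default) or `"error"`.
#' @return the filtered [count_table()], with attribute `"threshold"`.
#' @export
control_threshold_filter <- function(tab, missing_control = c("warn", "error")) {
  stopifnot(inherits(tab, "count_table"))
  missing_control <- match.arg(missing_control)
  ctrl <- which(tab$meta$is_control)
  if (!length(ctrl)) {
    if (missing_control == "error") abort("no negative control sample flagged")
    warning("no negative control flagged; using threshold T = 0")
    thr <- 0L
    counts <- tab$counts
    meta <- tab$meta
  } else {
    thr <- max(0L, tab$counts[ctrl, ])
    counts <- tab$counts[-ctrl, , drop = FALSE]
    meta <- tab$meta[-ctrl, , drop = FALSE]
  }
  counts[counts <= thr] <- 0L
  keep <- colSums(counts) > 0L
  out <- count_table(counts[, keep, drop = FALSE], meta)
  attr(out, "threshold") <- thr
  out
}

# label at the achieved rank: species epithet string, or "Genus spp."
#' Display label for an assigned lineage
#'
#' @param lineage `;`-separated lineage string(s).
#' @param rank achieved rank per lineage ("species", "genus", ...).
#' @return character labels like `"Bos taurus"` or `"Mus spp."`.
#' @export
taxon_label <- function(lineage, rank) {
  mapply(function(l, rk) {
    if (is.na(l)) return(NA_character_)
    p <- strsplit(l, ";")[[1]]
    if (rk == "species" && length(p) >= 7 && nzchar(p[7])) p[7]
    else if (rk %in% c("species", "genus") && length(p) >= 6)
      paste(p[6], "spp.")
    else if (length(p) >= 5) p[5]
    else NA_character_
  }, lineage, rank, USE.NAMES = FALSE)
}

#' Drop coarse, off-target and host OTUs
#'
#' Removes OTUs that are unassigned or resolved only to family level, OTUs
#' whose class is not a vertebrate class, and zeroes predator-self reads
#' (e.g. leopard reads inside leopard scats; their total is recorded in the
#' `"host_reads_removed"` attribute).
#'
#' @param tab a [count_table()] (control already removed).
#' @param assignments output of [consensus_assign()] covering every OTU.
#' @param vertebrate_classes lineage class fields accepted as target taxa.
#' @param predator_species named map from `meta$predator` values to the
#'   predator's own species name.
#' @return filtered [count_table()].
#' @export
drop_coarse_and_offtarget <- function(
    tab, assignments,
    vertebrate_classes = c("Mammalia", "Aves", "Actinopterygii", "Amphibia",
                           "Reptilia"),
    predator_species = c(leopard = "Panthera pardus",
                         leopardcat = "Prionailurus bengalensis")) {
  stopifnot(inherits(tab, "count_table"))
  otus <- colnames(tab$counts)
  if (length(otus) == 0L) return(tab)
  idx <- match(otus, assignments$otu_id)
  if (anyNA(idx)) abort("every OTU in the table needs an assignment")
  asn <- assignments[idx, , drop = FALSE]
  cls <- vapply(strsplit(ifelse(is.na(asn$lineage), "", asn$lineage), ";"),
                function(p) if (length(p) >= 3) p[3] else "", character(1))
  keep <- asn$rank %in% c("species", "genus") & cls %in% vertebrate_classes
  counts <- tab$counts[, keep, drop = FALSE]
  asn <- asn[keep, , drop = FALSE]

  # host exclusion: zero the predator's own OTUs within its scats
  host_removed <- 0L
  sp <- vapply(strsplit(asn$lineage, ";"),
               function(p) if (length(p) >= 7) p[7] else "", character(1))
  gen <- vapply(strsplit(asn$lineage, ";"),
                function(p) if (length(p) >= 6) p[6] else "", character(1))
  for (i in seq_len(nrow(counts))) {
    self <- predator_species[tab$meta$predator[i]]
    if (is.na(self)) next
    self_gen <- strsplit(self, " ")[[1]][1]
    hit <- sp == self | (asn$rank == "genus" & gen == self_gen)
    if (any(hit)) {
      host_removed <- host_removed + sum(counts[i, hit])
      counts[i, hit] <- 0L
    }
  }
  keep2 <- colSums(counts) > 0L
  out <- count_table(counts[, keep2, drop = FALSE], tab$meta)
  attr(out, "threshold") <- attr(tab, "threshold")
  attr(out, "host_reads_removed") <- host_removed
  out
}

#' Presence/absence from relative abundance
#'
#' Pools OTU counts to their assigned taxon (so genus-level prey such as
#' `Mus spp.` aggregate all member OTUs before thresholding), computes the
#' relative abundance of each taxon per scat over the retained reads, and
#' calls a taxon present where the relative abundance is strictly greater
#' than `threshold`.
#'
#' @param tab a filtered [count_table()].
#' @param assignments output of [consensus_assign()].
#' @param threshold presence cutoff on relative abundance (default 0.01,
#'   i.e. > 1 percent; exactly 1 percent is absent).
#' @return a [presence_matrix()]; scats with zero retained reads give an
#'   all-absent row with a warning.
#' @export
to_presence <- function(tab, assignments, threshold = 0.01) {
  stopifnot(inherits(tab, "count_table"))
  otus <- colnames(tab$counts)
  if (length(otus) == 0L) {
    warning("no OTUs survived filtering: empty presence matrix")
    pres <- matrix(FALSE, nrow(tab$counts), 0,
                   dimnames = list(rownames(tab$counts), character(0)))
    return(presence_matrix(pres, tab$meta))
  }
  idx <- match(otus, assignments$otu_id)
  if (anyNA(idx)) abort("every OTU in the table needs an assignment")
  labels <- taxon_label(assignments$lineage[idx], assignments$rank[idx])
  if (anyNA(labels)) abort("cannot label unassigned OTUs; filter them first")
  agg <- t(rowsum(t(tab$counts), group = labels))
  totals <- rowSums(agg)
  if (any(totals == 0))
    warning(sum(totals == 0), " scat(s) with zero retained reads: all-absent")
  rel <- agg / ifelse(totals == 0, 1, totals)
  pres <- rel > threshold
  presence_matrix(pres, tab$meta)
}

#' Run the full filter chain
#'
#' Fixed order: negative-control threshold, then taxonomy/off-target drop,
#' then the relative-abundance presence rule.
#'
#' @inheritParams control_threshold_filter
#' @inheritParams drop_coarse_and_offtarget
#' @inheritParams to_presence
#' @return a [presence_matrix()].
#' @export
filter_counts <- function(tab, assignments, threshold = 0.01,
                          missing_control = "warn",
                          vertebrate_classes = c("Mammalia", "Aves",
                                                 "Actinopterygii", "Amphibia",
                                                 "Reptilia"),
                          predator_species = c(
                            leopard = "Panthera pardus",
                            leopardcat = "Prionailurus bengalensis")) {
  tab <- control_threshold_filter(tab, missing_control)
  tab <- drop_coarse_and_offtarget(tab, assignments, vertebrate_classes,
                                   predator_species)
  to_presence(tab, assignments, threshold)
}
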
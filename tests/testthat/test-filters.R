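lin <- function(g, s = "") paste("Animalia;Chordata;Mammalia;Rodentia;Muridae",
                                 g, s, sep = ";")

make_hits <- function(otu, lineages, identity = 99, coverage = 95) {
  data.frame(otu_id = otu, lineage = lineages,
             identity = rep_len(identity, length(lineages)),
             coverage = rep_len(coverage, length(lineages)),
             stringsAsFactors = FALSE)
}

test_that("consensus assignment respects the 51 percent rule at each rank", {
  # 50 hits all species A -> species, consensus 1
  h <- make_hits("q1", rep(lin("Mus", "Mus musculus"), 50))
  a <- consensus_assign(h)
  expect_equal(a$rank, "species")
  expect_equal(a$consensus, 1)
  expect_equal(a$lineage, lin("Mus", "Mus musculus"))

  # 26 A + 24 B (same genus): 26/50 = 52% >= 51% -> species A
  h <- make_hits("q1", c(rep(lin("Mus", "Mus musculus"), 26),
                         rep(lin("Mus", "Mus booduga"), 24)))
  a <- consensus_assign(h)
  expect_equal(a$rank, "species")
  expect_equal(a$lineage, lin("Mus", "Mus musculus"))
  expect_equal(a$consensus, 0.52)

  # 25 + 25: species consensus 50% < 51%, genus 100% -> genus
  h <- make_hits("q1", c(rep(lin("Mus", "Mus musculus"), 25),
                         rep(lin("Mus", "Mus booduga"), 25)))
  a <- consensus_assign(h)
  expect_equal(a$rank, "genus")
  expect_equal(a$lineage, "Animalia;Chordata;Mammalia;Rodentia;Muridae;Mus")
  expect_equal(a$consensus, 1)
})

test_that("identity/coverage cutoffs and empty hit lists give unassigned", {
  h <- make_hits("q1", rep(lin("Mus", "Mus musculus"), 50), identity = 96)
  expect_equal(consensus_assign(h)$rank, "unassigned")
  h2 <- make_hits("q1", rep(lin("Mus", "Mus musculus"), 50), coverage = 80)
  expect_equal(consensus_assign(h2)$rank, "unassigned")
  # boundary: exactly at cutoff passes
  h3 <- make_hits("q1", rep(lin("Mus", "Mus musculus"), 10), identity = 97,
                  coverage = 85)
  expect_equal(consensus_assign(h3)$rank, "species")
})

test_that("only the top 50 hits by identity are used", {
  # 60 hits: 30 of species A at high identity, 30 of B at lower identity;
  # among the top 50, A has 30/50 = 60% -> species A
  h <- rbind(make_hits("q1", rep(lin("Mus", "Mus musculus"), 30),
                       identity = 99.5),
             make_hits("q1", rep(lin("Mus", "Mus booduga"), 30),
                       identity = 97.5))
  a <- consensus_assign(h)
  expect_equal(a$lineage, lin("Mus", "Mus musculus"))
  expect_equal(a$consensus, 0.6)
})

test_that("family-only consensus ascends and no consensus is unassigned", {
  # two genera split 25/25, same family -> family rank
  h <- make_hits("q1", c(rep(lin("Mus", "Mus musculus"), 25),
                         rep(lin("Rattus", "Rattus rattus"), 25)))
  a <- consensus_assign(h)
  expect_equal(a$rank, "family")
  # two families split 25/25 -> unassigned
  h2 <- make_hits("q1", c(
    rep(lin("Mus", "Mus musculus"), 25),
    rep("Animalia;Chordata;Mammalia;Rodentia;Hystricidae;Hystrix;Hystrix indica",
        25)))
  expect_equal(consensus_assign(h2)$rank, "unassigned")
})

test_that("negative-control threshold zeroes at the boundary", {
  counts <- rbind(s1 = c(a = 7L, b = 8L, c = 100L),
                  s2 = c(a = 50L, b = 7L, c = 3L),
                  ctl = c(a = 7L, b = 2L, c = 0L))
  meta <- data.frame(sample = c("s1", "s2", "ctl"), predator = "leopard",
                     site = NA, x = NA, y = NA,
                     is_control = c(FALSE, FALSE, TRUE))
  tab <- count_table(counts, meta)
  out <- control_threshold_filter(tab)
  expect_equal(attr(out, "threshold"), 7L)
  expect_equal(nrow(out$counts), 2L)
  # entries <= 7 zeroed: s1/a = 7 -> 0, s1/b = 8 kept
  expect_equal(unname(out$counts["s1", "b"]), 8L)
  expect_equal(unname(out$counts["s2", "a"]), 50L)
  expect_false("a" %in% colnames(out$counts) && out$counts["s1", "a"] > 0)
  # all-zero OTU columns dropped
  counts2 <- rbind(s1 = c(a = 5L, b = 10L), s2 = c(a = 6L, b = 12L),
                   ctl = c(a = 7L, b = 2L))
  tab2 <- count_table(counts2, meta)
  out2 <- control_threshold_filter(tab2)
  expect_equal(colnames(out2$counts), "b")
})

test_that("a control of zeros leaves the table unchanged minus the control", {
  counts <- rbind(s1 = c(a = 1L, b = 2L), ctl = c(a = 0L, b = 0L))
  meta <- data.frame(sample = c("s1", "ctl"), predator = "leopard",
                     site = NA, x = NA, y = NA, is_control = c(FALSE, TRUE))
  out <- control_threshold_filter(count_table(counts, meta))
  expect_equal(out$counts, counts["s1", , drop = FALSE])
  # missing control: threshold 0 with a warning
  meta$is_control <- FALSE
  expect_warning(out2 <- control_threshold_filter(count_table(counts, meta)),
                 "T = 0")
  expect_equal(attr(out2, "threshold"), 0L)
})

test_that("coarse, off-target and host OTUs are removed", {
  counts <- matrix(10L, 2, 5,
                   dimnames = list(c("s1", "s2"), paste0("o", 1:5)))
  meta <- data.frame(sample = c("s1", "s2"), predator = "leopard",
                     site = NA, x = NA, y = NA, is_control = FALSE)
  asn <- data.frame(
    otu_id = paste0("o", 1:5),
    lineage = c(lin("Mus", "Mus musculus"),               # good species
                "Animalia;Chordata;Mammalia;Rodentia;Muridae",  # family only
                NA,                                        # unassigned
                "Animalia;Arthropoda;Insecta;Diptera;Muscidae;Musca;Musca domestica",
                "Animalia;Chordata;Mammalia;Carnivora;Felidae;Panthera;Panthera pardus"),
    rank = c("species", "family", "unassigned", "species", "species"))
  out <- drop_coarse_and_offtarget(count_table(counts, meta), asn)
  expect_equal(colnames(out$counts), "o1")
  expect_equal(attr(out, "host_reads_removed"), 20L)
})

test_that("presence rule is strict at 1 percent and pools genus OTUs", {
  counts <- rbind(s1 = c(o1 = 101L, o2 = 9899L),
                  s2 = c(o1 = 100L, o2 = 9900L),
                  s3 = c(o1 = 5000L, o2 = 5000L))
  meta <- data.frame(sample = c("s1", "s2", "s3"), predator = "x",
                     site = NA, x = NA, y = NA, is_control = FALSE)
  asn <- data.frame(otu_id = c("o1", "o2"),
                    lineage = c(lin("Mus", "Mus musculus"),
                                lin("Rattus", "Rattus rattus")),
                    rank = "species")
  pm <- to_presence(count_table(counts, meta), asn)
  expect_true(pm$presence["s1", "Mus musculus"])    # 1.01% > 1%
  expect_false(pm$presence["s2", "Mus musculus"])   # exactly 1%: absent
  expect_true(all(pm$presence["s3", ]))
  # genus pooling: two OTUs of Mus spp. each at 0.6% pool to 1.2% -> present
  counts2 <- rbind(s1 = c(o1 = 60L, o2 = 60L, o3 = 9880L))
  meta2 <- meta[1, ]
  asn2 <- data.frame(otu_id = c("o1", "o2", "o3"),
                     lineage = c(lin("Mus"), lin("Mus"),
                                 lin("Rattus", "Rattus rattus")),
                     rank = c("genus", "genus", "species"))
  pm2 <- to_presence(count_table(counts2, meta2), asn2)
  expect_true(pm2$presence["s1", "Mus spp."])
})

test_that("presence is invariant to uniform scaling of a scat's counts", {
  set.seed(7)
  counts <- matrix(rpois(40, 300), 4, 10,
                   dimnames = list(paste0("s", 1:4), paste0("o", 1:10)))
  storage.mode(counts) <- "integer"
  meta <- data.frame(sample = paste0("s", 1:4), predator = "x", site = NA,
                     x = NA, y = NA, is_control = FALSE)
  asn <- data.frame(otu_id = paste0("o", 1:10),
                    lineage = lin(paste0("G", 1:10),
                                  paste0("G", 1:10, " sp")),
                    rank = "species")
  pm1 <- to_presence(count_table(counts, meta), asn)
  pm2 <- to_presence(count_table(counts * 13L, meta), asn)
  expect_identical(pm1$presence, pm2$presence)
})

test_that("zero-noise simulation is recovered exactly by the filter chain", {
  for (pred in c("leopard", "leopardcat")) {
    fx <- diet_fixture(pred, seed = 4)
    sim <- simulate_scat_counts(fx, sim_config(seed = 8))
    asn <- consensus_assign(simulate_hit_table(sim$assignments, seed = 9))
    pm <- filter_counts(sim$table, asn)
    got <- pm$presence[, order(colnames(pm$presence)), drop = FALSE]
    expect_identical(got, relabel_truth(fx))
  }
})

test_that("sub-threshold noise is removed in >= 95% of seeded replicates", {
  fx <- diet_fixture("leopard", seed = 1)
  truth <- relabel_truth(fx)
  hits <- consensus_assign(simulate_hit_table(
    simulate_scat_counts(fx, sim_config(seed = 1, noise_taxa = 2,
                                        noise_fraction = 0.005,
                                        control_contamination = 5))$assignments,
    seed = 1))
  ok <- vapply(seq_len(200), function(s) {
    sim <- simulate_scat_counts(fx, sim_config(
      seed = s, noise_taxa = 2, noise_fraction = 0.005,
      control_contamination = 5))
    pm <- filter_counts(sim$table, hits)
    identical(pm$presence[, order(colnames(pm$presence)), drop = FALSE],
              truth)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("filter chain agrees with a brute-force oracle on random tables", {
  lineages <- c(lin("Mus", "Mus musculus"), lin("Rattus"),
                "Animalia;Chordata;Mammalia;Rodentia;Muridae",  # family-only
                "Animalia;Chordata;Aves;Galliformes;Phasianidae;Gallus;Gallus gallus",
                "Animalia;Arthropoda;Insecta;Diptera;Muscidae;Musca;Musca domestica",
                lin("Niviventer", "Niviventer niviventer"))
  ranks <- c("species", "genus", "family", "species", "species", "species")
  keep <- ranks %in% c("species", "genus") &
    c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE)   # vertebrate classes
  labs <- taxon_label(lineages, ranks)
  asn <- data.frame(otu_id = paste0("o", 1:6), lineage = lineages,
                    rank = ranks)
  for (s in 1:50) {
    set.seed(s)
    n <- sample(3:8, 1)
    counts <- matrix(as.integer(rpois(n * 6, lambda = sample(c(3, 80, 400), 1))),
                     n, 6, dimnames = list(paste0("s", 1:n), paste0("o", 1:6)))
    ctl <- as.integer(rpois(6, 2))
    meta <- data.frame(sample = c(paste0("s", 1:n), "ctl"), predator = "x",
                       site = NA, x = NA, y = NA,
                       is_control = c(rep(FALSE, n), TRUE))
    tab <- count_table(rbind(counts, ctl = ctl), meta)
    got <- suppressWarnings(filter_counts(tab, asn))
    want <- oracle_filter(counts, ctl, keep, labs, 0.01)
    if (ncol(want) == 0L) {
      expect_equal(ncol(got$presence), 0L)
    } else {
      got_m <- got$presence[, order(colnames(got$presence)), drop = FALSE]
      want_m <- want[, order(colnames(want)), drop = FALSE]
      expect_identical(got_m, want_m)
    }
  }
})
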
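test_that("pairwise distances implement the fifth-character gap rule", {
  expect_equal(pairwise_distance("ACGT", "ACGT", min_overlap = 1), 0)
  expect_equal(pairwise_distance("AAAA", "AAAT", min_overlap = 1), 0.25)

  # internal gap: difference under the fifth-state rule, excluded otherwise
  expect_equal(pairwise_distance("AA-A", "AAAA", min_overlap = 1), 0.25)
  expect_equal(pairwise_distance("AA-A", "AAAA", gap_fifth = FALSE,
                                 min_overlap = 1), 1 / 3)
  # gap vs gap is a match of the fifth state
  expect_equal(pairwise_distance("A-CA", "A-CA", min_overlap = 1), 0)

  # terminal gap columns are excluded from the comparison
  expect_equal(pairwise_distance("--AAAA", "AAAAAA", min_overlap = 1), 0)
  expect_equal(pairwise_distance("--AATA", "AAAAAA", min_overlap = 1), 0.25)

  # pairs overlapping fewer than min_overlap columns are incomparable
  expect_true(is.na(pairwise_distance("AA----", "----AA", min_overlap = 2)))
  expect_true(is.na(pairwise_distance("AAAA", "AAAA", min_overlap = 5)))
  expect_error(pairwise_distance("AAA", "AAAA"), "equal length")
})

test_that("objective clustering is single linkage at the threshold", {
  # chain A-B 2%, B-C 2%, A-C 4%: one cluster at 3%
  v <- matrix(c(0, 0.02, 0.04,
                0.02, 0, 0.02,
                0.04, 0.02, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  p <- objective_cluster(v, 0.03)
  expect_length(p$clusters, 1)
  expect_setequal(p$clusters[["A"]], c("A", "B", "C"))

  # all pairs above the threshold: singletons
  p0 <- objective_cluster(v, 0.01)
  expect_length(p0$clusters, 3)

  # canonical labels: the smallest member names the cluster
  expect_named(p$clusters, "A")
})

test_that("clustering matches the brute-force union-find oracle", {
  for (seed in 1:3) {
    v <- random_dist_matrix(40, na_frac = 0.1, seed = seed)
    for (t in c(0.03, 0.08, 0.15)) {
      p <- objective_cluster(v, t)
      oracle <- uf_partition(v, rownames(v), t)
      got <- setNames(p$membership$motu_id, p$membership$specimen_id)
      expect_identical(got[names(oracle)], oracle)
    }
  }
})

test_that("partitions are invariant under input permutation", {
  cfg <- small_config()
  pool <- simulate_species_pool(cfg)
  set.seed(4)
  perm <- sample(length(pool))
  d1 <- distance_matrix(pool)
  d2 <- distance_matrix(pool[perm])
  p1 <- objective_cluster(d1, 0.03)
  p2 <- objective_cluster(d2, 0.03)
  expect_identical(p1$membership, p2$membership)
})

test_that("MOTU counts are non-increasing in the threshold", {
  v <- random_dist_matrix(60, seed = 9)
  prof <- cluster_profile(v, thresholds = c(0.01, 0.03, 0.05, 0.1, 0.15))
  expect_true(all(diff(prof$n_motus) <= 0))
  expect_equal(prof$headline, c(FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_error(cluster_profile(v, c(0.05, 0.01)), "ascending")

  # threshold 0: every distinct sequence its own MOTU; threshold 1: one
  # MOTU per comparability component
  seqs <- c(a = "AAAA", b = "AAAA", c = "TTTT", d = "GGGG")
  d <- distance_matrix(seqs, min_overlap = 1)
  expect_length(objective_cluster(d, 0)$clusters, 3)
  expect_length(objective_cluster(d, 1)$clusters, 1)
})

test_that("a world with a barcoding gap recovers its species count", {
  cfg <- small_config()
  pool <- simulate_species_pool(cfg)
  haps <- unlist(lapply(names(pool), function(sp) {
    v <- vapply(1:3, function(i) {
      motuflow:::intra_variant(pool[[sp]], cfg,
                               motuflow:::stop_codons("5"))
    }, character(1))
    setNames(v, sprintf("%s_h%d", sp, 1:3))
  }))
  d <- distance_matrix(haps)
  prof <- cluster_profile(d, thresholds = c(0.01, 0.03, 0.05))
  expect_equal(prof$n_motus[prof$threshold == 0.03], length(pool))
})

test_that("large internal gaps are excluded before clustering", {
  base <- random_dna(200, seed = 12)
  with_gap <- function(at, len) {
    paste0(substr(base, 1, at), strrep("-", len),
           substring(base, at + len + 1))
  }
  aligned <- c(ok = base,
               codon_del = with_gap(90, 3),
               big_gap = with_gap(60, 45))
  out <- exclude_gap_outliers(aligned, max_internal_gap = 30)
  expect_equal(out$excluded$specimen_id, "big_gap")
  expect_match(out$excluded$reason, "45")
  expect_setequal(names(out$aligned), c("ok", "codon_del"))

  none <- exclude_gap_outliers(c(a = base, b = base))
  expect_equal(nrow(none$excluded), 0)
})

test_that("the center-star aligner handles fragments and codon deletions", {
  cfg <- sim_config(amplicon_length = 120, seed = 21)
  long <- simulate_species_pool(sim_config(n_species = 1,
                                           amplicon_length = 120,
                                           seed = 21))[[1]]
  frag <- substr(long, 31, 90)                      # minibarcode fragment
  del <- paste0(substr(long, 1, 45), substring(long, 49))  # codon deletion
  aligned <- align_center_star(c(L = long, F = frag, D = del))
  expect_length(unique(nchar(aligned)), 1)
  expect_equal(gsub("-", "", aligned[["F"]]), frag)
  expect_equal(gsub("-", "", aligned[["D"]]), del)
  # fragment is identical to the center over its span
  expect_equal(pairwise_distance(aligned[["L"]], aligned[["F"]],
                                 min_overlap = 10), 0)
  # codon deletion counts as 3 differing columns under the fifth state
  dd <- pairwise_distance(aligned[["L"]], aligned[["D"]], min_overlap = 10)
  expect_equal(dd, 3 / 120)

  # equal-length ungapped input passes through unchanged
  seqs <- c(a = "ACGTACGTAC", b = "ACGTTCGTAC")
  expect_identical(align_center_star(seqs), seqs)
})

test_that("distance matrices and dendrograms export to standard formats", {
  cfg <- sim_config(n_species = 5, seed = 25)
  pool <- simulate_species_pool(cfg)
  d <- distance_matrix(pool)
  dir <- withr::local_tempdir()
  write_distance_matrix(d, tsv = file.path(dir, "d.tsv"),
                        phylip = file.path(dir, "d.phy"))
  back <- as.matrix(read.delim(file.path(dir, "d.tsv"), row.names = 1))
  expect_equal(unname(back), unname(d$values), tolerance = 1e-12)
  expect_equal(readLines(file.path(dir, "d.phy"))[1], "5")

  export_dendrogram(d, file.path(dir, "tree.nwk"))
  tr <- ape::read.tree(file.path(dir, "tree.nwk"))
  expect_setequal(tr$tip.label, names(pool))
})
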
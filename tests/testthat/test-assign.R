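ref_row <- function(id, seq, phylum = "Arthropoda", family = "Family01",
                    genus = "Genus01", species = "Genus01 species01") {
  data.frame(entry_id = id, phylum = phylum,
             class = paste0(phylum, "_classis"), order = "Order01",
             family = family, genus = genus, species = species,
             sequence = seq, stringsAsFactors = FALSE)
}

test_that("identity and cover follow their definitions on constructed pairs", {
  q <- random_dna(313, seed = 1)
  s <- align_and_score(q, q)
  expect_equal(s$percent_identity, 100)
  expect_equal(s$query_cover, 100)

  # 9 interior mismatches, no gaps: identity = 100 * 304/313
  r9 <- mutate_interior(q, 9, seed = 2)
  s9 <- align_and_score(q, r9)
  expect_equal(s9$percent_identity, 100 * 304 / 313, tolerance = 1e-10)
  expect_equal(s9$query_cover, 100)

  # reference covering only 200 of 313 query bases: cover ~ 63.9, ineligible
  rp <- substr(q, 50, 249)
  sp <- align_and_score(q, rp)
  expect_lt(abs(sp$query_cover - 100 * 200 / 313), 2)
  a <- assign_taxonomy(q, ref_row("R1", rp))
  expect_equal(a$assigned_rank, "none")

  # reverse-complement orientation is found
  src <- align_and_score(revcomp(q), q)
  expect_equal(src$percent_identity, 100)
  expect_equal(src$orientation, "reverse-complement")
})

test_that("alignment scores agree with a brute-force DP oracle (<= 50 bp)", {
  set.seed(33)
  for (i in 1:20) {
    n <- sample(20:50, 1)
    a <- random_dna(n)
    # derive b from a with substitutions and a possible indel, or random
    b <- if (i %% 4 == 0) random_dna(sample(20:50, 1)) else {
      x <- mutate_interior(a, sample(0:4, 1), margin = 5)
      if (i %% 2 == 0) {
        cut <- sample(10:(n - 10), 1)
        paste0(substr(x, 1, cut), substring(x, cut + sample(1:3, 1) + 1))
      } else x
    }
    # the matcher scores both query orientations and keeps the better one
    expected <- max(sw_score_oracle(b, a), sw_score_oracle(b, revcomp(a)))
    expect_equal(align_and_score(a, b)$score, expected,
                 info = sprintf("instance %d", i))
  }
})

test_that("identity bands map to ranks with named/unnamed distinction", {
  q <- random_dna(313, seed = 5)
  th <- assign_thresholds()
  mk_q <- function(k) mutate_interior(q, k, seed = k)

  # ~98.4% identity to a named binomial: species level, named match
  a <- assign_taxonomy(mk_q(5), ref_row("R1", q))
  expect_equal(a$assigned_rank, "species")
  expect_equal(a$assigned_name, "Genus01 species01")
  expect_true(a$named_match)

  # ~92% identity: genus only
  a <- assign_taxonomy(mk_q(25), ref_row("R1", q))
  expect_equal(a$assigned_rank, "genus")
  expect_equal(a$assigned_name, "Genus01")

  # ~86%: family; ~70%: none (cover still high)
  expect_equal(assign_taxonomy(mk_q(44), ref_row("R1", q))$assigned_rank,
               "family")

  # high identity to an unnamed entry: species-rank identity but not a
  # named match (counted as unidentified-to-species downstream)
  a <- assign_taxonomy(mk_q(3), ref_row("R1", q,
                                        species = "Paracalanus sp."))
  expect_equal(a$assigned_rank, "species")
  expect_false(a$named_match)
  a <- assign_taxonomy(mk_q(3), ref_row("R1", q,
                                        species = "uncultured zooplankton"))
  expect_false(a$named_match)

  # empty database
  expect_equal(assign_taxonomy(q, ref_row("R1", q)[0, ])$assigned_rank,
               "none")
})

test_that("equal-identity conflicting hits are demoted to their common rank", {
  q <- random_dna(313, seed = 6)
  rA <- mutate_interior(q, 1, seed = 7)
  rB <- mutate_interior(q, 1, seed = 8)
  expect_false(identical(rA, rB))

  # same genus, different species -> genus
  db <- rbind(ref_row("RA", rA, species = "Genus01 alpha"),
              ref_row("RB", rB, species = "Genus01 beta"))
  a <- assign_taxonomy(q, db)
  expect_equal(a$assigned_rank, "genus")
  expect_equal(a$assigned_name, "Genus01")

  # different genus, same family -> family
  db2 <- rbind(ref_row("RA", rA, genus = "GenusX", species = "GenusX alpha"),
               ref_row("RB", rB, genus = "GenusY", species = "GenusY beta"))
  expect_equal(assign_taxonomy(q, db2)$assigned_rank, "family")

  # disagreement even at family -> none
  db3 <- rbind(ref_row("RA", rA, family = "FamX", genus = "GX",
                       species = "GX alpha"),
               ref_row("RB", rB, family = "FamY", genus = "GY",
                       species = "GY beta"))
  expect_equal(assign_taxonomy(q, db3)$assigned_rank, "none")

  # agreeing tied hits are not demoted
  db4 <- rbind(ref_row("RA", rA), ref_row("RB", rB))
  expect_equal(assign_taxonomy(q, db4)$assigned_rank, "species")
})

test_that("raising identity thresholds never raises the assigned rank", {
  q <- random_dna(313, seed = 9)
  rank_value <- c(none = 0, family = 1, genus = 2, species = 3)
  for (k in c(2, 12, 25, 40, 55)) {
    qq <- mutate_interior(q, k, seed = 100 + k)
    r_base <- assign_taxonomy(qq, ref_row("R1", q))$assigned_rank
    r_high <- assign_taxonomy(qq, ref_row("R1", q),
                              assign_thresholds(species = 99, genus = 95,
                                                family = 90))$assigned_rank
    expect_lte(rank_value[[r_high]], rank_value[[r_base]])
  }
})

test_that("complete named references give full species-level recall", {
  cfg <- sim_config(n_species = 8, specimens_per_species = 2,
                    named_fraction = 1, ref_misid_rate = 0,
                    reads_per_specimen_mean = 1, dropout_rate = 1, seed = 17)
  pool <- simulate_species_pool(cfg)
  w <- simulate_specimens_and_reads(pool, cfg)
  ref <- simulate_reference_db(w, cfg)
  st <- w$specimen_table
  for (i in seq_len(nrow(st))) {
    a <- assign_taxonomy(w$haplotypes[[st$specimen_id[i]]], ref)
    expect_equal(a$assigned_rank, "species")
    truth <- ref$species[ref$true_species_id == st$species_id[i]]
    expect_equal(a$assigned_name, truth)
  }
})

test_that("reference FASTA round-trips through the header convention", {
  cfg <- small_config()
  w <- simulate_world(cfg)
  dir <- withr::local_tempdir()
  write_world(w, dir)
  ref <- read_reference_fasta(file.path(dir, "reference.fasta"))
  expect_equal(ref$entry_id, w$reference$entry_id)
  expect_equal(ref$species, w$reference$species)
  expect_equal(ref$sequence, w$reference$sequence)
  man <- read.delim(file.path(dir, "manifest.tsv"), stringsAsFactors = FALSE)
  expect_equal(man$specimen_id, w$manifest$specimen_id)
})
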
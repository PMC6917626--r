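mk_assignment <- function(specimen_id = "Z1", identity, rank, name,
                          phylum = "Arthropoda", named = TRUE,
                          species_label = name) {
  data.frame(specimen_id = specimen_id, best_hit = "R1",
             percent_identity = identity, query_cover = 95,
             assigned_rank = rank, assigned_name = name,
             named_match = named, hit_phylum = phylum,
             hit_species = species_label, stringsAsFactors = FALSE)
}

test_that("reliability criteria fire in order for filter-passing records", {
  # C1: congruent morphotype, good match
  d <- resolve_congruence(mk_assignment(identity = 99, rank = "species",
                                        name = "Genus01 species01"),
                          morphotype = "Arthropoda", status = "pass")
  expect_equal(d$criterion, "C1")
  expect_equal(d$identity_source, "both")
  expect_equal(d$final_name, "Genus01 species01")

  # C2: poor match (> 85%) at a low rank, consistent with the sort
  d <- resolve_congruence(mk_assignment(identity = 87, rank = "genus",
                                        name = "Sagitta",
                                        phylum = "Chaetognatha"),
                          morphotype = "Chaetognatha", status = "pass")
  expect_equal(d$criterion, "C2")
  expect_equal(d$final_name, "Sagitta")

  # C3 requires an explicit image-consistency record
  inc <- mk_assignment(identity = 99, rank = "species",
                       name = "Genus02 species02", phylum = "Mollusca")
  d <- resolve_congruence(inc, morphotype = "Arthropoda", status = "pass")
  expect_equal(d$criterion, "reject")
  d <- resolve_congruence(inc, morphotype = "Arthropoda", status = "pass",
                          image_consistent = TRUE)
  expect_equal(d$criterion, "C3")
  expect_equal(d$identity_source, "barcode")

  # identity at 85 exactly is not enough for C2 (strict >)
  d <- resolve_congruence(mk_assignment(identity = 85, rank = "family",
                                        name = "Family01"),
                          morphotype = "Arthropoda", status = "pass")
  expect_equal(d$criterion, "reject")
})

test_that("flagged records are retained only when all C4 conditions hold", {
  dom <- mk_assignment(identity = 90, rank = "genus", name = "Genus01")
  second_other <- mk_assignment("Z1", identity = 95, rank = "species",
                                name = "Genus09 species09",
                                phylum = "Mollusca")
  second_same <- mk_assignment("Z1", identity = 95, rank = "species",
                               name = "Genus03 species03",
                               phylum = "Arthropoda")

  d <- resolve_congruence(dom, morphotype = "Arthropoda", status = "flagged",
                          ratio = 0.28, coverage = 60, total_count = 12,
                          second_assignment = second_other)
  expect_equal(d$criterion, "C4")

  # second dominant matching the morphotype violates condition 4
  d <- resolve_congruence(dom, morphotype = "Arthropoda", status = "flagged",
                          ratio = 0.28, coverage = 60, total_count = 12,
                          second_assignment = second_same)
  expect_equal(d$criterion, "reject")
  expect_match(d$rationale, "second")

  # coverage or count at the boundary fails (strict > 50, > 10)
  d <- resolve_congruence(dom, morphotype = "Arthropoda", status = "flagged",
                          ratio = 0.28, coverage = 50, total_count = 12,
                          second_assignment = second_other)
  expect_equal(d$criterion, "reject")

  # ratio at 0.35 exactly is outside the re-evaluation band
  d <- resolve_congruence(dom, morphotype = "Arthropoda", status = "flagged",
                          ratio = 0.35, coverage = 60, total_count = 12,
                          second_assignment = second_other)
  expect_equal(d$criterion, "reject")

  # dominant must be >= 85% and congruent
  d <- resolve_congruence(mk_assignment(identity = 80, rank = "family",
                                        name = "Family01"),
                          morphotype = "Arthropoda", status = "flagged",
                          ratio = 0.28, coverage = 60, total_count = 12,
                          second_assignment = second_other)
  expect_equal(d$criterion, "reject")
})

test_that("failed barcodes fall back to morphology", {
  a <- mk_assignment(identity = NA_real_, rank = "none", name = NA_character_)
  d <- resolve_congruence(a, morphotype = "Arthropoda", status = "fail",
                          morphology_name = "Atergatis floridus")
  expect_equal(d$criterion, "reject")
  expect_equal(d$identity_source, "morphology")
  expect_equal(d$final_name, "Atergatis floridus")

  d <- resolve_congruence(a, morphotype = "Arthropoda", status = "no-reads")
  expect_equal(d$identity_source, "none")

  # missing morphotype label evaluates congruence as false
  d <- resolve_congruence(mk_assignment(identity = 99, rank = "species",
                                        name = "X y"),
                          morphotype = NA_character_, status = "pass")
  expect_equal(d$criterion, "reject")
})

test_that("survey decisions partition specimens and are order-independent", {
  sr <- small_run()
  dec <- sr$res$decisions
  expect_setequal(dec$specimen_id, sr$world$manifest$specimen_id)
  expect_equal(anyDuplicated(dec$specimen_id), 0L)
  expect_true(all(dec$criterion %in% c("C1", "C2", "C3", "C4", "reject")))

  # shuffling the barcode table does not change any decision
  set.seed(8)
  perm <- sample(nrow(sr$res$barcodes))
  dec2 <- resolve_all(sr$res$barcodes[perm, ], sr$res$assignments,
                      sr$world$manifest, sr$world$reference)
  dec2 <- dec2[match(dec$specimen_id, dec2$specimen_id), ]
  expect_equal(dec$criterion, dec2$criterion)
  expect_equal(dec$final_name, dec2$final_name)
})

test_that("perfect sorting with complete named references yields all C1", {
  cfg <- sim_config(n_species = 6, specimens_per_species = 3,
                    missort_rate = 0, contamination_fraction = 0,
                    named_fraction = 1, ref_misid_rate = 0,
                    reads_per_specimen_mean = 120, dropout_rate = 0.2,
                    seed = 19)
  w <- simulate_world(cfg)
  res <- run_pipeline(w)
  passing <- res$barcodes$specimen_id[res$barcodes$status == "pass"]
  crit <- res$decisions$criterion[match(passing, res$decisions$specimen_id)]
  expect_true(all(crit == "C1"))
})

test_that("mis-sorting increases incongruence-driven rejections", {
  base <- sim_config(n_species = 6, specimens_per_species = 4,
                     missort_rate = 0, contamination_fraction = 0,
                     named_fraction = 1, ref_misid_rate = 0,
                     reads_per_specimen_mean = 100, dropout_rate = 0,
                     seed = 23)
  high <- sim_config(n_species = 6, specimens_per_species = 4,
                     missort_rate = 0.4, contamination_fraction = 0,
                     named_fraction = 1, ref_misid_rate = 0,
                     reads_per_specimen_mean = 100, dropout_rate = 0,
                     seed = 23)
  n_reject <- function(cfg) {
    res <- run_pipeline(simulate_world(cfg))
    sum(res$decisions$criterion == "reject")
  }
  expect_gt(n_reject(high), n_reject(base))
})
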
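# motuflow

Specimen-level COI DNA barcoding for biodiversity surveys: tagged-amplicon
demultiplexing, dominant-read barcode calling with contamination filters,
percent-identity taxonomic assignment, morphotype–barcode congruence
resolution, and objective MOTU clustering — with a ground-truthed
synthetic-data generator so the entire pipeline runs and is validated
offline.

## Who this is for

Survey teams using the *reverse workflow*: barcode every specimen first,
cluster barcodes into molecular operational taxonomic units (MOTUs) as
putative species, and let the clusters guide expert identification. The
package covers the analysis chain between raw tagged reads and the survey
summary; wet-lab steps and remote database searches are out of scope (the
matcher runs against a local reference FASTA).

## The methods at the core

* **Error-correcting sample tags.** 9-bp dual tags with pairwise Hamming
  distance ≥ 3; nearest-tag decoding corrects up to ⌊(d−1)/2⌋ = 1 error
  per tag unambiguously.
* **Dominant-read calling.** Per specimen, unique sequences are ranked by
  abundance; the dominant sequence is the barcode if coverage > 50, total
  count > 10 and the second:first ratio ≤ 0.2 (ratios in (0.2, 0.35) are
  flagged for congruence-based re-evaluation). Translation screening under
  mitochondrial genetic codes flags NUMT suspects (stop codons in every
  frame).
* **Taxonomic assignment.** Local alignment (match +1, mismatch −1, gap of
  length L costs 2 + L) against every reference entry in both
  orientations; hits need query cover ≥ 80%, and identity bands set the
  rank: ≥ 97% species, ≥ 90% genus, ≥ 80% family. Matches to unnamed
  entries ("sp.", "uncultured") never count as species-level
  identifications.
* **Congruence criteria C1–C4.** Barcodes are reconciled with phylum-level
  morphotype sorts: C1 congruent + ≥ 97%; C2 congruent + > 85%; C3
  incongruent + ≥ 97% + curated image agreement; C4 rescues flagged
  specimens whose minority read looks like cross-contamination from a
  different phylum.
* **Objective clustering.** Uncorrected p-distances on a common alignment
  with internal gaps as a fifth character state (gap–base differs,
  gap–gap matches, terminal gaps excluded, pairs overlapping < 100
  columns incomparable); MOTUs at threshold *t* are the connected
  components of pairs at distance ≤ *t*, headline *t* = 3%.

See `vignettes/specimen-barcoding.Rmd` for assumptions, parameter
rationale and numerical conventions.

## Worked example

The `analysis/` drivers run the whole study on a simulated survey
(`Rscript analysis/01_simulate.R` … `06_report.R`), writing row-level
tables under `results/`. Equivalently, in R:

```r
library(motuflow)
world <- simulate_world(sim_config(seed = 1))  # 20 species x 5 specimens
res <- run_pipeline(world)
res$report
#> Specimens: 100; barcoded: 65 (65.0%)
#>   long (>= 658 bp): 0 (0.0%); short: 65 (100.0%)
#>   passing filters: 69 of 69 sequenced (100.0%); C4 retained: 0
#>   species-named specimens: 50 (76.9%); named species: 16
#>   MOTUs at 3% threshold: 20
```

Reading: of 100 specimens, 31 dropped out at amplification and 4 more were
rejected by the congruence criteria (mis-sorted morphotypes with no
curated image check), leaving 65 barcoded specimens (65.0%). All 69
sequenced specimens passed the coverage/count/ratio filters — at 10%
cross-contamination spread over ~99 other specimens no single contaminant
approaches the 0.2 ratio. 50 specimens matched named reference species;
the other barcodes hit unnamed ("Genus sp.") entries. Clustering at 3%
recovers exactly the 20 simulated species as MOTUs:

```r
cluster_profile(res$distances, seq(0.01, 0.05, by = 0.01))
#>   threshold n_motus headline
#> 1      0.01      29    FALSE
#> 2      0.02      20    FALSE
#> 3      0.03      20     TRUE
#> 4      0.04      20    FALSE
#> 5      0.05      20    FALSE
```

The profile is flat from 2% on — the simulated barcoding gap (intra ≤ 1%,
inter ≥ 5%) — while 1% oversplits within-species variation, exactly the
behaviour threshold-based delimitation shows on real data when the gap is
clean.

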
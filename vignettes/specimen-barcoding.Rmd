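---
title: "Specimen-level COI barcoding: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Specimen-level COI barcoding: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Biodiversity surveys in poorly characterised marine faunas face a double
shortage: too few taxonomists to sort thousands of specimens to species,
and reference databases too sparse to name most of what is sequenced. The
*reverse workflow* inverts the classical order: every specimen is barcoded
at the mitochondrial COI locus first, barcodes are clustered into
molecular operational taxonomic units (MOTUs) that act as putative
species, and expert identification is directed at the clusters afterwards.
`motuflow` implements the specimen-level analysis chain this workflow
needs, from raw tagged amplicon reads to a survey summary, together with a
ground-truthed simulator so every stage can be validated without any
external data.

The stages are:

1. **Tag design and demultiplexing** (`generate_tag_set()`,
   `demultiplex()`). Specimens are PCR-tagged on both ends with 9-bp tags
   whose pairwise Hamming distance is at least 3, so nearest-tag decoding
   can correct one sequencing error per tag without ambiguity (a distance
   `d` code corrects `floor((d-1)/2)` errors).
2. **Dominant-read barcode calling** (`rank_reads()`, `apply_filters()`).
   Each specimen's reads are grouped into exact-match unique sequences;
   the most abundant is the barcode candidate. Filters: coverage (reads
   identical to the dominant) must exceed 50, total reads must exceed 10,
   and the second:first abundance ratio must be at most 0.2. Ratios
   strictly between 0.2 and 0.35 are *flagged* rather than failed and may
   be rescued by criterion C4 below.
3. **NUMT screening** (`screen_translation()`). Barcodes are translated
   (invertebrate mitochondrial code by default, table 5; table 2 for
   chordates) and sequences with stop codons in every reading frame are
   marked `numt-suspect`. A whole-codon deletion relative to a reference
   keeps the frame and is classified `codon-gap` and retained.
4. **Taxonomic assignment** (`assign_taxonomy()`). A local alignment of
   each barcode against every reference entry (both orientations)
   replaces a remote BLAST search so the analysis is hermetic. Hits are
   eligible at query cover >= 80%; the best eligible hit's identity sets
   the rank: >= 97% species, >= 90% genus, >= 80% family.
5. **Morphotype congruence** (`resolve_congruence()`). Specimens are
   pre-sorted into seven phylum-level morphotypes; reliability criteria
   C1-C4 decide which barcodes are trusted (see below).
6. **MOTU clustering** (`objective_cluster()`). Uncorrected pairwise
   distances with internal gaps as a fifth character state; MOTUs are the
   connected components of pairs at distance <= 3% (single linkage at the
   threshold).
7. **Reporting** (`summarize_survey()`). Every survey tally is recomputed
   from the row-level tables.

## Reliability criteria

For filter-passing barcodes the first matching criterion applies:

* **C1** — morphotype and barcode identity congruent (at phylum level) and
  identity >= 97%: species-level identity, source "both".
* **C2** — identity > 85% (strictly) and congruent: the barcode supplies
  the lowest-rank identity it supports.
* **C3** — identity >= 97% but *incongruent*: retained only when curation
  has explicitly recorded that the specimen images agree with the match.
  The flag defaults to false, so C3 can never fire without human input —
  the package does not automate a judgement that is made by eye.

Flagged barcodes (ratio in the 0.2–0.35 band) are retained as **C4** only
when *all* of: ratio strictly inside (0.2, 0.35); coverage > 50 and total
count > 10; the dominant read is a >= 85% match to a taxon congruent with
the morphotype; and the second dominant read does **not** match the
morphotype (i.e. the minority sequence looks like cross-contamination from
another sort group, not like a genuine mixed signal). One boundary is
deliberately resolved: descriptions of the band as "0.2–0.35" and as
"< 0.35" disagree at exactly 0.35; the filter treats 0.35 as a failure and
C4 requires a strict inequality, so the stricter reading wins at the
boundary.

Rejected specimens fall back to their morphology name when one exists.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| tag length / min distance | 9 bp / 3 | 1-error correction per tag; ~50 tags are easily placed at this distance |
| `max_mismatch` (demux) | 0 (strict); 1 in the drivers | a mismatch tolerance is not part of the filter definitions, so strict is the conservative default; 1 is provably safe under distance >= 3 |
| coverage / count filters | > 50 / > 10 | strict inequalities as printed; "coverage" = reads identical to the dominant sequence, "total count" = all reads retained for the specimen (both interpretations are configurable because the terms admit others; the choice is recorded in output metadata) |
| ratio pass / flag | <= 0.2 / < 0.35 | printed inequality directions followed exactly |
| identity bands | 97 / 90 / 80 % | conservative general thresholds for marine taxa; supraspecific bands should be treated with caution |
| query cover | >= 80% | eligibility rule for any hit |
| MOTU threshold | 3% | the generalised COI barcoding-gap threshold; a profile over 1–5% is always computed since the gap varies across taxa |
| `min_overlap` | 100 columns | keeps 313-bp minibarcodes and 658-bp full barcodes comparable over their shared region |
| `max_internal_gap` | 30 bases | larger internal gaps interfere with fifth-state distances and exclude the sequence from clustering; a 3-base codon deletion is retained |

## Numerical choices

* **Alignment scoring** is fixed and recorded: match +1, mismatch −1, a
  gap of length L costs 2 + L (opening 2, extension 1 per base, the
  `pairwiseAlignment` convention). Percent identity divides identities by
  aligned columns *including* gap columns, the closest analogue of BLAST
  identity; query cover is the aligned query span over query length.
  Tie-breaking is deterministic: highest identity, then score, then
  alignment length, then lowest reference index.
* **Equal-identity conflicts**: when tied best hits disagree at the band
  rank, the assignment is demoted to the deepest rank at which they agree
  (species → genus → family → none). Choosing the first hit instead would
  make the result depend on database order.
* **Gap fifth state**: gap-vs-base is a difference and gap-vs-gap a match
  of the fifth state ("fifth character" admits both readings; this one is
  the default and both are available). Terminal gap columns are excluded
  entirely. In the non-fifth mode, gap columns leave the denominator but
  still count as differences.
* **Read ranking ties** break lexicographically by sequence, so the
  dominant read is well defined even on 50:50 pools.
* **Cluster labels** are canonical (each MOTU is named by its smallest
  member id), making partitions invariant under input permutation.
* **Percentages** round half-up to one decimal (`round_half_up()`), so a
  printed percentage always reproduces from its numerator and denominator;
  banker's rounding would differ at .x5 boundaries.
* **Degenerate inputs**: empty read pools become a `no-reads` outcome
  rather than an error; an empty reference database yields rank "none";
  incomparable sequence pairs (overlap < 100) contribute no clustering
  edge, so at threshold 1.0 each comparability component is one MOTU.

## The synthetic generator

`simulate_world()` builds a survey whose statistical structure matches
what the analysis assumes, with every read traceable to its true source:

* a species pool mutated from a random in-frame ancestor at third-codon
  positions (stop codons rejection-sampled away), with all interspecific
  p-distances >= 5% and intraspecific variants <= 1% by construction — a
  barcoding gap exists by design;
* 20 species × 5 specimens across the seven phylum morphotypes, 5% of
  specimens mis-sorted; dual 9-bp tags at distance >= 3;
* per-specimen pools of mean 200 reads, 10% of reads templated from
  another specimen (cross-contamination that carries the host's tags),
  0.1% per-base substitution error, and 32% specimen dropout so that
  amplification success lands in a realistic range for mixed marine
  phyla;
* a reference database with one within-species variant per species, 80%
  named with binomials, the rest "Genus sp.", and 5% carrying another
  species' taxonomy with the truth recorded.

Defaults are fixed study conditions, not tuning knobs; where no external
value existed (contamination, error, dropout) they were chosen once as
field-realistic and documented here.

What the generator does **not** emulate — and therefore what passing tests
cannot show about real data: chimeric reads, instrument-specific quality
profiles, paired-end structure (reads are pre-merged), indel sequencing
errors, NUMT co-amplification, uneven pooling, taxa without a barcoding
gap (recently diverged species, anthozoans with slow COI), and reference
databases whose errors are correlated with taxonomy rather than random.
The parameter-recovery result (exactly 20 MOTUs at 3%, 100% species-level
recall) is a correctness check of the pipeline under a clean barcoding
gap, not a claim about recall on real communities.

## Problem sizes

The test suite exercises small worlds (6–8 species × 2–4 specimens, 60–120
reads per specimen) for pipeline-level properties, a 20 × 5 world with 10%
contamination for end-to-end parameter recovery, 200 × 200 random distance
matrices against a brute-force union-find oracle, and <= 50-bp alignment
instances against a hand-written affine-gap dynamic-programming oracle.
These sizes were chosen so the whole suite runs in about a minute while
still covering every rule at its boundaries.

## Known limitations

* The center-star aligner is adequate for fragments of a protein-coding
  locus at one or two amplicon lengths; for divergent or indel-rich data,
  supply an externally computed alignment to `distance_matrix()`.
* Congruence is judged at the phylum level of the morphotype vocabulary;
  finer morphological identifications participate only as fallback names.
* Single linkage at a threshold chains clusters through intermediates by
  design (that is what makes the clustering "objective"); where the
  barcoding gap is weak the MOTU profile, not the single 3% count, is the
  meaningful output.
* The tie-demotion rule handles equal-identity conflicts only; it is not
  a lowest-common-ancestor over all sub-threshold hits.
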
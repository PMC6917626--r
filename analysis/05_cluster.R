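#!/usr/bin/env Rscript

## Step 5 - objective clustering of retained barcodes into MOTUs.
##
## Pairwise uncorrected distances with internal gaps as a fifth character
## state; sequences with internal gap runs > 30 bases are excluded first.
## MOTUs are connected components at distance <= threshold, with the
## headline count at 3% and a profile over 1-5%.

suppressPackageStartupMessages({
  library(motuflow)
  library(Biostrings)
})

bc <- read.delim("results/barcode_qc.tsv", stringsAsFactors = FALSE)
decisions <- read.delim("results/decisions.tsv", stringsAsFactors = FALSE)

retained <- decisions$specimen_id[decisions$criterion != "reject"]
seqs <- setNames(bc$sequence, bc$specimen_id)[retained]
seqs <- seqs[!is.na(seqs)]
cat(sprintf("clustering %d retained barcodes\n", length(seqs)))

aligned <- align_center_star(seqs)
kept <- exclude_gap_outliers(aligned, max_internal_gap = 30)
if (nrow(kept$excluded)) {
  cat("excluded for large internal gaps:\n")
  print(kept$excluded)
}

d <- distance_matrix(kept$aligned, gap_fifth = TRUE, min_overlap = 100)
write_distance_matrix(d, tsv = "results/distances.tsv",
                      phylip = "results/distances.phy")
export_dendrogram(d, "results/single_linkage.nwk")

partition <- objective_cluster(d, threshold = 0.03)
write.table(cbind(partition$membership, threshold = partition$threshold),
            "results/motu_partition.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

profile <- cluster_profile(d, thresholds = seq(0.01, 0.05, by = 0.005))
write.table(profile, "results/motu_profile.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("MOTUs at 3%%: %d\n", length(partition$clusters)))
cat("profile:\n")
print(profile)
cat("wrote results/distances.{tsv,phy}, results/single_linkage.nwk,",
    "results/motu_partition.tsv, results/motu_profile.tsv\n")
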
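#!/usr/bin/env Rscript

## Step 2 - demultiplex tagged reads and call per-specimen barcodes.
##
## Reads are assigned to specimens by nearest-tag decoding (1 mismatch per
## tag tolerated, safe under tag distance >= 3), pooled per specimen, and
## the dominant unique sequence is called as the barcode after the coverage
## (> 50), count (> 10) and contamination-ratio (<= 0.2 pass, < 0.35
## flagged) filters plus the stop-codon translation screen.

suppressPackageStartupMessages({
  library(motuflow)
  library(Biostrings)
})

manifest <- read.delim("results/data/manifest.tsv",
                       stringsAsFactors = FALSE)
reads_set <- readDNAStringSet("results/data/reads.fasta")
tagset <- tag_set_from_manifest(manifest)

demux <- demultiplex(reads_set, manifest, tagset, max_mismatch = 1)
cat(sprintf("demultiplexed %d reads: %d assigned (%.1f%%), %d unassigned\n",
            length(reads_set), nrow(demux$assignments),
            100 * nrow(demux$assignments) / length(reads_set),
            nrow(demux$unassigned)))
if (nrow(demux$unassigned)) {
  print(table(demux$unassigned$reason))
}

pools <- demux_pools(demux, manifest)
called <- call_barcodes(pools)
bc <- called$barcodes
cat("filter outcomes:\n")
print(table(bc$status))

dir.create("results", showWarnings = FALSE)
counts <- as.data.frame(table(demux$assignments$specimen_id),
                        stringsAsFactors = FALSE)
names(counts) <- c("specimen_id", "reads_assigned")
write.table(counts, "results/demux_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(bc, "results/barcode_qc.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

ok <- !is.na(bc$sequence)
writeXStringSet(DNAStringSet(setNames(bc$sequence[ok], bc$specimen_id[ok])),
                "results/barcodes.fasta")
cat("wrote results/demux_report.tsv, results/barcode_qc.tsv,",
    "results/barcodes.fasta\n")
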
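#!/usr/bin/env Rscript

## Step 4 - reconcile morphotype sorts with barcode identities.
##
## Applies the reliability criteria: C1 (congruent, >= 97%), C2 (congruent,
## > 85%), C3 (incongruent but >= 97% and images consistent - requires
## explicit curation input, so it never fires in this unsupervised run) and
## C4 (flagged ratio band re-evaluation). Everything else is rejected and
## falls back to morphology.

suppressPackageStartupMessages(library(motuflow))

manifest <- read.delim("results/data/manifest.tsv",
                       stringsAsFactors = FALSE)
bc <- read.delim("results/barcode_qc.tsv", stringsAsFactors = FALSE)
assignments <- read.delim("results/assignments.tsv",
                          stringsAsFactors = FALSE)
ref <- read_reference_fasta("results/data/reference.fasta")

decisions <- resolve_all(bc, assignments, manifest, ref)
write.table(decisions, "results/decisions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("congruence decisions:\n")
print(table(decisions$criterion))
cat(sprintf("retained barcodes: %d of %d specimens\n",
            sum(decisions$criterion != "reject"), nrow(decisions)))
cat("wrote results/decisions.tsv\n")
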
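#!/usr/bin/env Rscript

## Step 6 - survey-level summary.
##
## Recomputes all headline tallies from the row-level tables and checks the
## pipeline's calls against the simulation truth.

suppressPackageStartupMessages(library(motuflow))

manifest <- read.delim("results/data/manifest.tsv",
                       stringsAsFactors = FALSE)
truth <- read.delim("results/data/truth_specimens.tsv",
                    stringsAsFactors = FALSE)
bc <- read.delim("results/barcode_qc.tsv", stringsAsFactors = FALSE)
assignments <- read.delim("results/assignments.tsv",
                          stringsAsFactors = FALSE)
decisions <- read.delim("results/decisions.tsv", stringsAsFactors = FALSE)
partition_tab <- read.delim("results/motu_partition.tsv",
                            stringsAsFactors = FALSE)
partition <- list(clusters = split(partition_tab$specimen_id,
                                   partition_tab$motu_id),
                  membership = partition_tab[, c("specimen_id", "motu_id")],
                  threshold = partition_tab$threshold[1])
class(partition) <- "motu_partition"

report <- summarize_survey(manifest, bc, assignments, decisions, partition)
print(report)
report_json(report, "results/summary.json")
report_markdown(report, "results/summary.md")

## truth checks (possible only because the survey is simulated)
true_n_species <- length(unique(truth$species_id))
cat(sprintf("\ntruth: %d species; pipeline found %d MOTUs at %.0f%%\n",
            true_n_species, report$motu_count_at_headline_threshold,
            100 * report$headline_threshold))
called <- !is.na(bc$sequence)
sp_truth <- truth$species_id[match(bc$specimen_id, truth$specimen_id)]
correct_phylum <- truth$true_phylum[match(assignments$specimen_id,
                                          truth$specimen_id)] ==
  assignments$hit_phylum
cat(sprintf("barcodes whose best hit is in the true phylum: %d of %d\n",
            sum(correct_phylum, na.rm = TRUE), sum(!is.na(correct_phylum))))
cat("wrote results/summary.json, results/summary.md\n")
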
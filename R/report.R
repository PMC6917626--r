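## Survey-level summary tallies.
##
## Every number in the report is recomputed from the row-level tables
## (manifest, barcode QC, assignments, congruence decisions, MOTU
## partition); percentages are rounded half-up to one decimal so a printed
## percentage always equals its numerator/denominator under the same rule.

#' Classify each specimen's identification source
#'
#' `barcode-only`: a retained, named species-level barcode match with no
#' morphology species name (C3 cases, where the barcode overrides a
#' mis-sort, land here with an incongruence note). `both`: congruent named
#' species-level match plus a morphology name. `morphology-only`: a
#' morphology name without a qualifying barcode match. `none`: neither.
#'
#' @param decisions data.frame from [resolve_all()].
#' @param assignments data.frame from [assign_all()].
#' @param morphology_names named character vector (specimen_id -> species
#'   name), possibly empty.
#' @return data.frame: specimen_id, source, note.
#' @export
classify_identification_source <- function(decisions, assignments,
                                           morphology_names = NULL) {
  rows <- lapply(seq_len(nrow(decisions)), function(i) {
    d <- decisions[i, ]
    a <- assignments[assignments$specimen_id == d$specimen_id, , drop = FALSE]
    named_species <- nrow(a) == 1 && a$assigned_rank == "species" &&
      isTRUE(a$named_match) && d$criterion %in% c("C1", "C3", "C4")
    morph <- lookup(morphology_names, d$specimen_id, NA_character_)
    has_morph <- !is.na(morph) && nzchar(morph)
    source <- if (named_species && !has_morph) "barcode-only"
      else if (named_species && has_morph) "both"
      else if (has_morph) "morphology-only"
      else "none"
    note <- if (identical(d$criterion, "C3")) "incongruent with sort" else ""
    data.frame(specimen_id = d$specimen_id, source = source, note = note,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Summarise a barcoding survey
#'
#' Headline tallies: amplification success, long/short barcode split,
#' filter outcomes, identification sources, named-species counts, MOTU
#' count at the headline threshold, and per-phylum specimen shares. All
#' percentages use half-up rounding to one decimal.
#'
#' @param manifest manifest data.frame.
#' @param barcodes data.frame from [call_barcodes()].
#' @param assignments data.frame from [assign_all()].
#' @param decisions data.frame from [resolve_all()].
#' @param partition a `motu_partition` (or NULL).
#' @param morphology_names named character vector of morphology species
#'   names (optional).
#' @return object of class `summary_report` (a list of counts and
#'   percentages).
#' @export
summarize_survey <- function(manifest, barcodes, assignments, decisions,
                             partition = NULL, morphology_names = NULL) {
  ids <- manifest$specimen_id
  miss <- setdiff(barcodes$specimen_id, ids)
  if (length(miss)) {
    stop("barcode records for specimens absent from the manifest: ",
         paste(head(miss, 5), collapse = ", "))
  }
  total <- length(ids)

  retained <- decisions$criterion %in% c("C1", "C2", "C3", "C4")
  retained_ids <- decisions$specimen_id[retained]
  bc <- barcodes[barcodes$specimen_id %in% retained_ids, , drop = FALSE]
  barcoded <- nrow(bc)

  long_count <- sum(bc$length_class == "long", na.rm = TRUE)
  short_count <- sum(bc$length_class == "short", na.rm = TRUE)

  sequenced <- sum(barcodes$status != "no-reads")
  passing <- sum(barcodes$status == "pass")
  flagged <- sum(barcodes$status == "flagged")
  retained_c4 <- sum(decisions$criterion == "C4")

  src <- classify_identification_source(decisions, assignments,
                                        morphology_names)
  n_barcode_only <- sum(src$source == "barcode-only")
  n_both <- sum(src$source == "both")
  n_morph_only <- sum(src$source == "morphology-only")

  named_specimens <- n_barcode_only + n_both
  named_names <- unique(stats::na.omit(
    decisions$final_name[retained &
      decisions$specimen_id %in%
        src$specimen_id[src$source %in% c("barcode-only", "both")]]))

  motus <- if (!is.null(partition)) length(partition$clusters) else NA_integer_
  headline_threshold <- if (!is.null(partition)) partition$threshold else NA_real_

  phylum_tab <- table(manifest$morphotype)
  per_phylum <- data.frame(phylum = names(phylum_tab),
                           n = as.integer(phylum_tab),
                           pct = pct(as.integer(phylum_tab), total),
                           stringsAsFactors = FALSE, row.names = NULL)

  structure(list(
    total_specimens = total,
    barcoded = barcoded,
    amplification_success_pct = pct(barcoded, total),
    long_count = long_count, long_pct = pct(long_count, barcoded),
    short_count = short_count, short_pct = pct(short_count, barcoded),
    sequenced_amplicons = sequenced,
    passing_filters = passing,
    passing_filters_pct = pct(passing, sequenced),
    flagged = flagged, retained_c4 = retained_c4,
    identified_barcode_only = n_barcode_only,
    identified_barcode_only_pct = pct(n_barcode_only, barcoded),
    identified_both = n_both,
    identified_morphology_only = n_morph_only,
    identified_with_species_names = named_specimens,
    identified_with_species_names_pct = pct(named_specimens, barcoded),
    total_named_species = length(named_names),
    motu_count_at_headline_threshold = motus,
    headline_threshold = headline_threshold,
    per_phylum = per_phylum,
    sources = src), class = "summary_report")
}

#' @export
print.summary_report <- function(x, ...) {
  cat(sprintf("Specimens: %d; barcoded: %d (%.1f%%)\n",
              x$total_specimens, x$barcoded, x$amplification_success_pct))
  cat(sprintf("  long (>= 658 bp): %d (%.1f%%); short: %d (%.1f%%)\n",
              x$long_count, x$long_pct, x$short_count, x$short_pct))
  cat(sprintf("  passing filters: %d of %d sequenced (%.1f%%); C4 retained: %d\n",
              x$passing_filters, x$sequenced_amplicons,
              x$passing_filters_pct, x$retained_c4))
  cat(sprintf("  species-named specimens: %d (%.1f%%); named species: %d\n",
              x$identified_with_species_names,
              x$identified_with_species_names_pct, x$total_named_species))
  if (!is.na(x$motu_count_at_headline_threshold)) {
    cat(sprintf("  MOTUs at %.0f%% threshold: %d\n",
                100 * x$headline_threshold,
                x$motu_count_at_headline_threshold))
  }
  invisible(x)
}

#' Write a summary report as JSON
#'
#' @param report a `summary_report`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
report_json <- function(report, path) {
  x <- unclass(report)
  x$sources <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Write a summary report as Markdown
#'
#' @param report a `summary_report`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
report_markdown <- function(report, path) {
  lines <- c(
    "# Barcoding survey summary", "",
    sprintf("- Specimens: %d", report$total_specimens),
    sprintf("- Barcoded: %d (%.1f%%)", report$barcoded,
            report$amplification_success_pct),
    sprintf("- Long barcodes (>= 658 bp): %d (%.1f%%)", report$long_count,
            report$long_pct),
    sprintf("- Short barcodes: %d (%.1f%%)", report$short_count,
            report$short_pct),
    sprintf("- Passing filters: %d of %d sequenced (%.1f%%)",
            report$passing_filters, report$sequenced_amplicons,
            report$passing_filters_pct),
    sprintf("- Retained via re-evaluation (C4): %d", report$retained_c4),
    sprintf("- Identified by barcode only: %d", report$identified_barcode_only),
    sprintf("- Identified by both: %d", report$identified_both),
    sprintf("- Identified by morphology only: %d",
            report$identified_morphology_only),
    sprintf("- Specimens with species names: %d (%.1f%%)",
            report$identified_with_species_names,
            report$identified_with_species_names_pct),
    sprintf("- Named species: %d", report$total_named_species),
    if (!is.na(report$motu_count_at_headline_threshold)) {
      sprintf("- MOTUs at %.0f%% threshold: %d",
              100 * report$headline_threshold,
              report$motu_count_at_headline_threshold)
    },
    "", "## Specimens per morphotype", "",
    sprintf("- %s: %d (%.1f%%)", report$per_phylum$phylum,
            report$per_phylum$n, report$per_phylum$pct))
  writeLines(lines, path)
  invisible(path)
}
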
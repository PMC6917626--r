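## Morphotype-barcode congruence resolution.
##
## Specimens are pre-sorted into phylum-level morphotypes by eye; barcodes
## then confirm, refine or contradict the sort. Four reliability criteria
## decide which barcodes are kept and what the final identification is:
##   C1 - filters passed, morphotype and barcode identity congruent, good
##        match (>= 97% identity: species-level identity).
##   C2 - filters passed, poor match (> 85% identity, lowest-rank identity)
##        but consistent with the morphological sort.
##   C3 - filters passed, >= 97% match but incongruent with the sort; kept
##        only when the specimen images are explicitly recorded as
##        consistent with the match (mis-sort accommodation).
##   C4 - filters flagged (ratio in the 0.2-0.35 re-evaluation band); kept
##        only when coverage > 50, total count > 10, the dominant read is a
##        >= 85% match to a taxon congruent with the morphotype AND the
##        second dominant read does not match the assigned morphotype.
## Anything else is rejected: the specimen falls back to its morphology
## name if one exists.

#' Reconcile one specimen's morphotype with its barcode identity
#'
#' Criteria are evaluated in order C1, C2, C3 for filter-passing records;
#' flagged records are evaluated against the four C4 sub-conditions and
#' accepted only when all hold. Congruence is judged at the phylum level of
#' the morphotype vocabulary by default.
#'
#' @param assignment one-row data.frame from [assign_taxonomy()] /
#'   [assign_all()] for the dominant read.
#' @param morphotype phylum-level morphotype label ("unknown" if missing).
#' @param status filter status: "pass", "flagged", "fail" or "no-reads".
#' @param ratio,coverage,total_count the specimen's read statistics (used
#'   by C4).
#' @param second_assignment assignment of the second dominant read, or NULL.
#' @param image_consistent TRUE only when curation has recorded that the
#'   specimen images agree with the barcode match (required by C3; never
#'   assumed).
#' @param morphology_name optional morphology-based species name, used as
#'   the fallback identification on rejection.
#' @param c2_identity_min minimum identity for C2 (exclusive, default 85).
#' @param c1_identity_min minimum identity for C1/C3 (default 97).
#' @param thresholds a [filter_thresholds()] list (C4 re-checks coverage,
#'   count and the ratio band).
#' @return one-row data.frame: specimen_id (if present in `assignment`),
#'   criterion (C1/C2/C3/C4/reject), identity_source
#'   (barcode/morphology/both/none), final_name, rationale.
#' @export
resolve_congruence <- function(assignment, morphotype, status,
                               ratio = NA_real_, coverage = NA_integer_,
                               total_count = NA_integer_,
                               second_assignment = NULL,
                               image_consistent = FALSE,
                               morphology_name = NA_character_,
                               c2_identity_min = 85,
                               c1_identity_min = 97,
                               thresholds = filter_thresholds()) {
  morphotype <- if (is.na(morphotype) || !nzchar(morphotype)) "unknown" else morphotype
  id <- assignment$percent_identity
  congruent <- !is.na(assignment$hit_phylum) &&
    identical(assignment$hit_phylum, morphotype)
  has_hit <- !is.na(id) && assignment$assigned_rank != "none"

  reject <- function(why) {
    list(criterion = "reject",
         identity_source = if (!is.na(morphology_name)) "morphology" else "none",
         final_name = morphology_name,
         rationale = why)
  }

  out <- if (status %in% c("fail", "no-reads")) {
    reject(paste0("barcode ", status, "; decided by morphology alone"))
  } else if (status == "pass") {
    if (has_hit && id >= c1_identity_min && congruent) {
      list(criterion = "C1", identity_source = "both",
           final_name = assignment$assigned_name,
           rationale = sprintf(
             "congruent morphotype (%s) and good match (%.1f%%)",
             morphotype, id))
    } else if (has_hit && id > c2_identity_min && congruent) {
      list(criterion = "C2", identity_source = "barcode",
           final_name = assignment$assigned_name,
           rationale = sprintf(
             "poor match (%.1f%%) at rank %s, consistent with morphotype %s",
             id, assignment$assigned_rank, morphotype))
    } else if (has_hit && id >= c1_identity_min && !congruent &&
               isTRUE(image_consistent)) {
      list(criterion = "C3", identity_source = "barcode",
           final_name = assignment$assigned_name,
           rationale = sprintf(
             "incongruent with morphotype %s but match %.1f%% and images consistent",
             morphotype, id))
    } else {
      reject("no congruence criterion satisfied")
    }
  } else if (status == "flagged") {
    second_matches_morph <- !is.null(second_assignment) &&
      !is.na(second_assignment$hit_phylum) &&
      identical(second_assignment$hit_phylum, morphotype) &&
      second_assignment$assigned_rank != "none"
    conds <- c(
      ratio_band = !is.na(ratio) && ratio > thresholds$ratio_pass &&
        ratio < thresholds$ratio_flag,
      coverage = !is.na(coverage) && coverage > thresholds$coverage_min,
      total = !is.na(total_count) && total_count > thresholds$count_min,
      dominant_congruent = has_hit && id >= c2_identity_min && congruent,
      second_incongruent = !second_matches_morph)
    if (all(conds)) {
      list(criterion = "C4", identity_source = "both",
           final_name = assignment$assigned_name,
           rationale = sprintf(
             "re-evaluated: ratio %.2f in band, dominant %.1f%% congruent with %s, second dominant incongruent",
             ratio, id, morphotype))
    } else {
      reject(paste("C4 condition(s) failed:",
                   paste(names(conds)[!conds], collapse = ", ")))
    }
  } else {
    stop("unknown filter status: ", status)
  }

  data.frame(
    specimen_id = assignment$specimen_id %||% NA_character_,
    criterion = out$criterion, identity_source = out$identity_source,
    final_name = out$final_name, rationale = out$rationale,
    stringsAsFactors = FALSE)
}

#' Resolve congruence for a whole survey
#'
#' @param barcodes data.frame from [call_barcodes()].
#' @param assignments data.frame from [assign_all()] for dominant reads.
#' @param manifest manifest data.frame (specimen_id, morphotype).
#' @param db reference database (used to assign second dominant reads of
#'   flagged specimens).
#' @param image_consistent named logical vector (specimen_id -> flag) of
#'   curated image checks; specimens absent from it default to FALSE.
#' @param morphology_names named character vector (specimen_id -> species
#'   name) of morphology-based identifications, if any.
#' @param assign_thresholds an [assign_thresholds()] list.
#' @param thresholds a [filter_thresholds()] list.
#' @return data.frame of per-specimen decisions (see
#'   [resolve_congruence()]).
#' @export
resolve_all <- function(barcodes, assignments, manifest, db,
                        image_consistent = NULL, morphology_names = NULL,
                        assign_thresholds = motuflow::assign_thresholds(),
                        thresholds = filter_thresholds()) {
  rows <- lapply(seq_len(nrow(barcodes)), function(i) {
    b <- barcodes[i, ]
    a <- assignments[assignments$specimen_id == b$specimen_id, , drop = FALSE]
    if (nrow(a) == 0) {
      a <- cbind(data.frame(specimen_id = b$specimen_id,
                            stringsAsFactors = FALSE),
                 assign_taxonomy(NA_character_, NULL))
    }
    second <- NULL
    if (identical(b$status, "flagged") && !is.na(b$second_sequence)) {
      second <- assign_taxonomy(b$second_sequence, db, assign_thresholds)
    }
    resolve_congruence(
      a[1, ], morphotype = manifest$morphotype[
        match(b$specimen_id, manifest$specimen_id)],
      status = b$status, ratio = b$ratio, coverage = b$coverage,
      total_count = b$total_count, second_assignment = second,
      image_consistent = isTRUE(lookup(image_consistent, b$specimen_id,
                                       FALSE)),
      morphology_name = lookup(morphology_names, b$specimen_id,
                               NA_character_),
      thresholds = thresholds)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
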
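## End-to-end driver: demultiplex -> call barcodes -> assign taxonomy ->
## resolve congruence -> cluster MOTUs -> summarise.

#' Run the full barcoding pipeline on a simulated (or prepared) survey
#'
#' @param world a `true_world` from [simulate_world()], or any list
#'   providing `reads`, `manifest`, `tagset` and `reference`.
#' @param max_mismatch per-tag mismatch budget for demultiplexing.
#' @param thresholds a [filter_thresholds()] list.
#' @param assign_thresholds an [assign_thresholds()] list.
#' @param motu_threshold headline clustering threshold (default 0.03).
#' @param profile_thresholds thresholds for the MOTU profile.
#' @param image_consistent,morphology_names optional curation inputs passed
#'   to [resolve_all()].
#' @return list with all row-level tables (`demux`, `barcodes`,
#'   `assignments`, `decisions`, `distances`, `partition`, `profile`,
#'   `excluded`) and the `report`.
#' @export
run_pipeline <- function(world,
                         max_mismatch = 1L,
                         thresholds = filter_thresholds(),
                         assign_thresholds = motuflow::assign_thresholds(),
                         motu_threshold = 0.03,
                         profile_thresholds = c(0.01, 0.02, 0.03, 0.04, 0.05),
                         image_consistent = NULL,
                         morphology_names = NULL) {
  demux <- demultiplex(world$reads, world$manifest, world$tagset,
                       max_mismatch = max_mismatch)
  pools <- demux_pools(demux, world$manifest)
  called <- call_barcodes(pools, thresholds = thresholds)
  barcodes <- called$barcodes

  assignments <- assign_all(barcodes, world$reference,
                            thresholds = assign_thresholds)
  decisions <- resolve_all(barcodes, assignments, world$manifest,
                           world$reference,
                           image_consistent = image_consistent,
                           morphology_names = morphology_names,
                           assign_thresholds = assign_thresholds,
                           thresholds = thresholds)

  retained <- decisions$specimen_id[
    decisions$criterion %in% c("C1", "C2", "C3", "C4")]
  seqs <- setNames(barcodes$sequence, barcodes$specimen_id)[retained]
  seqs <- seqs[!is.na(seqs)]

  distances <- partition <- profile <- NULL
  excluded <- data.frame(specimen_id = character(0), reason = character(0))
  if (length(seqs) >= 2) {
    aligned <- align_center_star(seqs)
    kept <- exclude_gap_outliers(aligned)
    excluded <- kept$excluded
    distances <- distance_matrix(kept$aligned)
    partition <- objective_cluster(distances, motu_threshold)
    profile <- cluster_profile(distances, profile_thresholds)
  }

  report <- summarize_survey(world$manifest, barcodes, assignments,
                             decisions, partition, morphology_names)
  list(demux = demux, barcodes = barcodes, assignments = assignments,
       decisions = decisions, distances = distances, partition = partition,
       profile = profile, excluded = excluded, report = report)
}
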
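## Taxonomic assignment by percent identity against a reference database.
##
## A hermetic stand-in for remote BLAST searches: each query is aligned
## locally against every reference entry (both orientations), hits are
## eligible when query cover >= 80%, and the best eligible hit's percent
## identity places the assignment in a rank band: >= 97% species, >= 90%
## genus, >= 80% family, below that no assignment. Matches to unnamed
## reference entries ("sp.", "uncultured", "cf.") are tracked so they are
## not counted as species-level identifications.

## fixed alignment scoring: match +1, mismatch -1; a gap of length L costs
## 2 + L (opening 2, extension 1). N columns score 0 (neutral).
nucleotide_scores <- function() {
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(-1, 5, 5, dimnames = list(bases, bases))
  diag(m) <- 1
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

#' Default taxonomic-assignment thresholds
#'
#' @param species,genus,family minimum percent identity for each rank.
#' @param min_cover minimum query cover (percent) for a hit to be eligible.
#' @return named list.
#' @export
assign_thresholds <- function(species = 97, genus = 90, family = 80,
                              min_cover = 80) {
  stopifnot(family <= genus, genus <= species)
  list(species = species, genus = genus, family = family,
       min_cover = min_cover)
}

#' Patterns marking unnamed reference species labels
#'
#' @return character vector of regular expressions.
#' @export
unnamed_patterns <- function() {
  c("\\bsp\\.", "\\bcf\\.", "uncultured", "^\\s*$")
}

is_unnamed_label <- function(label, patterns = unnamed_patterns()) {
  if (is.na(label)) return(TRUE)
  any(vapply(patterns, function(p) grepl(p, label), logical(1)))
}

## align one query (character) against a set of references; returns a
## data.frame with score, percent identity (identities / aligned columns,
## gap columns included), query cover, and orientation, per reference
score_query <- function(query, ref_seqs) {
  pats <- Biostrings::DNAStringSet(ref_seqs)
  one_orient <- function(subj) {
    aln <- Biostrings::pairwiseAlignment(
      pats, Biostrings::DNAString(subj), type = "local",
      substitutionMatrix = nucleotide_scores(),
      gapOpening = 2, gapExtension = 1)
    qspan <- Biostrings::end(Biostrings::subject(aln)) -
      Biostrings::start(Biostrings::subject(aln)) + 1L
    data.frame(score = Biostrings::score(aln),
               percent_identity = Biostrings::pid(aln, type = "PID1"),
               query_cover = 100 * qspan / nchar(subj),
               aln_length = Biostrings::nchar(aln))
  }
  fwd <- one_orient(query)
  rev <- one_orient(revcomp(query))
  use_rev <- rev$score > fwd$score
  out <- fwd
  out[use_rev, ] <- rev[use_rev, ]
  out$orientation <- ifelse(use_rev, "reverse-complement", "forward")
  out
}

#' Align a query to a single reference and score it
#'
#' Local alignment under fixed scores (match +1, mismatch -1, gap of length
#' L costs 2 + L). Percent identity is identities divided by aligned
#' columns (gap columns included); query cover is the aligned query span
#' divided by query length. Both orientations are scored and the better one
#' kept (forward on ties).
#'
#' @param query,reference nucleotide strings.
#' @return list with `percent_identity`, `query_cover`, `score`,
#'   `orientation`.
#' @export
#' @examples
#' align_and_score("ACGTACGT", "ACGTACGT")
align_and_score <- function(query, reference) {
  stopifnot(nchar(query) > 0, nchar(reference) > 0)
  s <- score_query(query, reference)
  list(percent_identity = s$percent_identity, query_cover = s$query_cover,
       score = s$score, orientation = s$orientation)
}

rank_for_identity <- function(identity, thresholds) {
  if (identity >= thresholds$species) "species"
  else if (identity >= thresholds$genus) "genus"
  else if (identity >= thresholds$family) "family"
  else "none"
}

#' Assign a taxonomic identity to one barcode
#'
#' Hits with query cover below `min_cover` are ineligible. The best eligible
#' hit (highest identity, then highest score, then longest alignment, then
#' lowest reference index) sets the rank band. When several hits tie on
#' identity but conflict at the band rank, the assignment is demoted to
#' their lowest common rank (or "none" if they disagree even at family).
#'
#' @param query nucleotide string (a called barcode).
#' @param db reference data.frame with columns `entry_id`, `phylum`,
#'   `class`, `order`, `family`, `genus`, `species`, `sequence`.
#' @param thresholds an [assign_thresholds()] list.
#' @param patterns unnamed-label patterns, see [unnamed_patterns()].
#' @return one-row data.frame: best_hit, percent_identity, query_cover,
#'   assigned_rank, assigned_name, named_match, hit_phylum, hit_species.
#' @export
assign_taxonomy <- function(query, db, thresholds = assign_thresholds(),
                            patterns = unnamed_patterns()) {
  empty <- data.frame(best_hit = NA_character_, percent_identity = NA_real_,
                      query_cover = NA_real_, assigned_rank = "none",
                      assigned_name = NA_character_, named_match = FALSE,
                      hit_phylum = NA_character_,
                      hit_species = NA_character_, stringsAsFactors = FALSE)
  if (is.null(db) || nrow(db) == 0) return(empty)
  if (is.na(query) || nchar(query) == 0) return(empty)

  s <- score_query(query, db$sequence)
  eligible <- which(s$query_cover >= thresholds$min_cover)
  if (!length(eligible)) return(empty)

  e <- s[eligible, , drop = FALSE]
  ord <- order(-e$percent_identity, -e$score, -e$aln_length, eligible)
  best_i <- eligible[ord[1]]
  best <- s[best_i, ]

  band <- rank_for_identity(best$percent_identity, thresholds)
  tied <- eligible[abs(e$percent_identity - best$percent_identity) < 1e-9]

  rank_order <- c("species", "genus", "family")
  assigned_rank <- band
  if (band != "none" && length(tied) > 1) {
    start <- match(band, rank_order)
    assigned_rank <- "none"
    for (r in rank_order[start:3]) {
      if (length(unique(db[[r]][tied])) == 1L) {
        assigned_rank <- r
        break
      }
    }
  }
  assigned_name <- if (assigned_rank == "none") NA_character_ else {
    db[[assigned_rank]][best_i]
  }
  named <- !is_unnamed_label(db$species[best_i], patterns)
  data.frame(best_hit = db$entry_id[best_i],
             percent_identity = best$percent_identity,
             query_cover = best$query_cover,
             assigned_rank = assigned_rank, assigned_name = assigned_name,
             named_match = named, hit_phylum = db$phylum[best_i],
             hit_species = db$species[best_i], stringsAsFactors = FALSE)
}

#' Assign taxonomy for a table of called barcodes
#'
#' @param barcodes data.frame from [call_barcodes()] (needs `specimen_id`
#'   and `sequence`; rows with no sequence get rank "none").
#' @param db reference data.frame (see [assign_taxonomy()]).
#' @param thresholds an [assign_thresholds()] list.
#' @return data.frame: specimen_id plus the [assign_taxonomy()] columns.
#' @export
assign_all <- function(barcodes, db, thresholds = assign_thresholds()) {
  rows <- lapply(seq_len(nrow(barcodes)), function(i) {
    res <- assign_taxonomy(barcodes$sequence[i], db, thresholds)
    cbind(data.frame(specimen_id = barcodes$specimen_id[i],
                     stringsAsFactors = FALSE), res)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Read a reference database from FASTA
#'
#' Headers must follow `id|phylum;class;order;family;genus;species`.
#'
#' @param path FASTA file path.
#' @return reference data.frame usable by [assign_taxonomy()].
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(x), "|", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("malformed reference header: ", names(x)[bad][1])
  tax <- strsplit(vapply(parts, `[`, character(1), 2L), ";", fixed = TRUE)
  if (any(lengths(tax) != 6L)) {
    stop("reference taxonomy must have 6 ranks phylum;class;order;",
         "family;genus;species")
  }
  tm <- do.call(rbind, tax)
  data.frame(entry_id = vapply(parts, `[`, character(1), 1L),
             phylum = tm[, 1], class = tm[, 2], order = tm[, 3],
             family = tm[, 4], genus = tm[, 5], species = tm[, 6],
             sequence = as.character(x), stringsAsFactors = FALSE,
             row.names = NULL)
}
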
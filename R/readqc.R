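## Dominant-read barcode calling and quality filters.
##
## Each specimen's demultiplexed reads are grouped into exact-match unique
## sequences ranked by abundance. The most abundant ("dominant") sequence is
## the barcode candidate; it must clear a coverage filter (reads identical
## to the dominant > 50), a total read-count filter (> 10) and a
## contamination-ratio filter (second-dominant : dominant coverage <= 0.2,
## with the 0.2-0.35 band flagged for congruence-based re-evaluation).
## Candidate barcodes are translated and screened for internal stop codons
## to catch nuclear mitochondrial pseudogenes (NUMTs).

#' Rank a specimen's reads into unique sequences by abundance
#'
#' Exact-sequence grouping; ties in count are broken lexicographically by
#' sequence. The contamination ratio is the second-dominant count divided by
#' the dominant count (0 when there is no second sequence).
#'
#' @param reads character vector of reads for one specimen (may be empty).
#' @param specimen_id specimen identifier.
#' @return object of class `ranked_reads`: list with `specimen_id`,
#'   `unique_sequences` (data.frame sequence/count, descending),
#'   `coverage` (dominant count), `total_count` and `ratio`.
#' @export
#' @examples
#' r <- rank_reads(c(rep("AAAT", 5), rep("AACT", 2)), "S1")
#' r$ratio # 0.4
rank_reads <- function(reads, specimen_id = NA_character_) {
  if (length(reads) == 0L) {
    return(structure(list(specimen_id = specimen_id,
                          unique_sequences = data.frame(
                            sequence = character(0), count = integer(0),
                            stringsAsFactors = FALSE),
                          coverage = 0L, total_count = 0L, ratio = 0),
                     class = "ranked_reads"))
  }
  tab <- table(reads)
  df <- data.frame(sequence = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$sequence), , drop = FALSE]
  rownames(df) <- NULL
  ratio <- if (nrow(df) >= 2) df$count[2] / df$count[1] else 0
  structure(list(specimen_id = specimen_id, unique_sequences = df,
                 coverage = df$count[1], total_count = sum(df$count),
                 ratio = ratio),
            class = "ranked_reads")
}

#' Default barcode-calling filter thresholds
#'
#' Coverage must exceed `coverage_min`, total read count must exceed
#' `count_min`, and the second:first dominant-read ratio must be at most
#' `ratio_pass` to pass; ratios strictly between `ratio_pass` and
#' `ratio_flag` are flagged for congruence re-evaluation; at or above
#' `ratio_flag` the specimen fails.
#'
#' @param coverage_min strict lower bound on dominant-read coverage.
#' @param count_min strict lower bound on total read count.
#' @param ratio_pass maximum passing second:first ratio.
#' @param ratio_flag ratio at/above which the specimen fails outright.
#' @return named list of thresholds.
#' @export
filter_thresholds <- function(coverage_min = 50, count_min = 10,
                              ratio_pass = 0.2, ratio_flag = 0.35) {
  stopifnot(ratio_pass < ratio_flag)
  list(coverage_min = coverage_min, count_min = count_min,
       ratio_pass = ratio_pass, ratio_flag = ratio_flag)
}

#' Apply coverage, count and contamination-ratio filters
#'
#' @param r a `ranked_reads` with at least one read.
#' @param thresholds a [filter_thresholds()] list.
#' @return object of class `filter_outcome`: list with `status`
#'   (pass/flagged/fail), `reasons` (character) and `thresholds`.
#' @export
apply_filters <- function(r, thresholds = filter_thresholds()) {
  stopifnot(inherits(r, "ranked_reads"))
  if (r$total_count == 0L) {
    stop("apply_filters() requires at least one read; ",
         "empty pools are reported as 'no-reads' by call_barcodes()")
  }
  reasons <- character(0)
  if (r$coverage <= thresholds$coverage_min) {
    reasons <- c(reasons,
                 sprintf("coverage <= %g", thresholds$coverage_min))
  }
  if (r$total_count <= thresholds$count_min) {
    reasons <- c(reasons,
                 sprintf("total count <= %g", thresholds$count_min))
  }
  if (r$ratio >= thresholds$ratio_flag) {
    reasons <- c(reasons,
                 sprintf("second:first ratio >= %g", thresholds$ratio_flag))
  }
  if (length(reasons)) {
    status <- "fail"
  } else if (r$ratio <= thresholds$ratio_pass) {
    status <- "pass"
  } else {
    status <- "flagged"
    reasons <- sprintf("second:first ratio in (%g, %g) re-evaluation band",
                       thresholds$ratio_pass, thresholds$ratio_flag)
  }
  structure(list(status = status, reasons = reasons,
                 thresholds = thresholds),
            class = "filter_outcome")
}

#' Translate a barcode and screen for internal stop codons
#'
#' A sequence is `clean` when some reading frame (the given `frame`, or all
#' three when `search_frames` is TRUE) translates without internal stop
#' codons. When a reference sequence is supplied and the clean sequence
#' differs from it by indels whose lengths are all multiples of three (a
#' whole-codon gap that keeps the frame intact), the status is `codon-gap`.
#' Sequences with stops in every frame are `numt-suspect` (likely nuclear
#' pseudogene copies).
#'
#' @param sequence nucleotide string (A/C/G/T/N only), length >= 30.
#' @param genetic_code NCBI translation table id; default "5"
#'   (invertebrate mitochondrial). Use "2" for chordates.
#' @param frame expected reading frame offset (1, 2 or 3).
#' @param search_frames try all three frames (default TRUE).
#' @param reference optional reference sequence for codon-gap detection.
#' @return one of "clean", "codon-gap", "numt-suspect".
#' @export
screen_translation <- function(sequence, genetic_code = "5", frame = 1L,
                               search_frames = TRUE, reference = NULL) {
  if (is.na(sequence) || nchar(sequence) < 30) {
    stop("sequence must be at least 30 bases for translation screening")
  }
  if (grepl("[^ACGTN]", sequence)) {
    stop("sequence contains characters other than A/C/G/T/N")
  }
  frames <- if (search_frames) 1:3 else frame
  gc <- Biostrings::getGeneticCode(genetic_code)
  clean_in_frame <- function(f) {
    sub <- substring(sequence, f)
    sub <- substr(sub, 1L, 3L * (nchar(sub) %/% 3L))
    if (nchar(sub) < 3L) return(FALSE)
    aa <- Biostrings::translate(Biostrings::DNAString(sub),
                                genetic.code = gc, if.fuzzy.codon = "X",
                                no.init.codon = TRUE)
    !grepl("\\*", as.character(aa))
  }
  if (!any(vapply(frames, clean_in_frame, logical(1)))) {
    return("numt-suspect")
  }
  if (!is.null(reference)) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(sequence), Biostrings::DNAString(reference),
      type = "global-local",
      substitutionMatrix = nucleotide_scores(),
      gapOpening = 2, gapExtension = 1)
    p <- as.character(Biostrings::alignedPattern(aln))
    s <- as.character(Biostrings::alignedSubject(aln))
    gap_runs <- function(x) {
      r <- rle(strsplit(x, "")[[1]] == "-")
      r$lengths[r$values]
    }
    gaps <- c(gap_runs(p), gap_runs(s))
    if (length(gaps) && all(gaps %% 3L == 0L)) return("codon-gap")
  }
  "clean"
}

#' Call barcodes for all specimens of a survey
#'
#' Ranks each specimen's reads, applies the filters, screens the dominant
#' sequence for stop codons, and returns one record per specimen. Specimens
#' with empty pools get status `no-reads`. Sanger-supplied barcodes can be
#' appended with `source = "sanger-supplied"` (read filters bypassed,
#' translation screen still applied) via [sanger_barcode()].
#'
#' @param pools named list specimen_id -> character vector of reads (e.g.
#'   from [demux_pools()]).
#' @param thresholds a [filter_thresholds()] list.
#' @param genetic_code translation table id for the stop-codon screen.
#' @param long_min minimum length of the "long" class (default 658).
#' @return list with `barcodes` (data.frame: specimen_id, sequence,
#'   second_sequence, length, length_class, coverage, total_count, ratio,
#'   status, reasons, translation_status, source) and `ranked` (list of
#'   `ranked_reads`).
#' @export
call_barcodes <- function(pools, thresholds = filter_thresholds(),
                          genetic_code = "5", long_min = 658) {
  ranked <- lapply(names(pools), function(sp) rank_reads(pools[[sp]], sp))
  names(ranked) <- names(pools)
  rows <- lapply(ranked, function(r) {
    if (r$total_count == 0L) {
      return(data.frame(specimen_id = r$specimen_id,
                        sequence = NA_character_,
                        second_sequence = NA_character_,
                        length = NA_integer_, length_class = NA_character_,
                        coverage = 0L, total_count = 0L, ratio = 0,
                        status = "no-reads", reasons = "no reads",
                        translation_status = NA_character_,
                        source = "hts-called", stringsAsFactors = FALSE))
    }
    fo <- apply_filters(r, thresholds)
    dom <- r$unique_sequences$sequence[1]
    second <- if (nrow(r$unique_sequences) >= 2) {
      r$unique_sequences$sequence[2]
    } else NA_character_
    trans <- tryCatch(
      screen_translation(dom, genetic_code = genetic_code),
      error = function(e) "numt-suspect")
    data.frame(specimen_id = r$specimen_id, sequence = dom,
               second_sequence = second, length = nchar(dom),
               length_class = length_class(nchar(dom), long_min),
               coverage = r$coverage, total_count = r$total_count,
               ratio = r$ratio, status = fo$status,
               reasons = paste(fo$reasons, collapse = "; "),
               translation_status = trans, source = "hts-called",
               stringsAsFactors = FALSE)
  })
  list(barcodes = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       ranked = ranked, thresholds = thresholds)
}

#' Barcode length class
#'
#' @param n length in bases.
#' @param long_min minimum length of the long class (default 658; shorter
#'   barcodes, typically 229-657 bp minibarcodes, are "short").
#' @return "long" or "short".
#' @export
length_class <- function(n, long_min = 658) {
  ifelse(n >= long_min, "long", "short")
}

#' Build a record for an externally supplied (Sanger) barcode
#'
#' Read-level filters do not apply to Sanger-assembled barcodes; the
#' translation screen still does.
#'
#' @param specimen_id specimen identifier.
#' @param sequence assembled barcode sequence.
#' @param genetic_code translation table id.
#' @param long_min minimum length of the long class.
#' @return one-row data.frame with the same columns as [call_barcodes()]
#'   barcodes, `source = "sanger-supplied"`, `status = "pass"`, and
#'   `qc = "external"` semantics (coverage/count/ratio are NA).
#' @export
sanger_barcode <- function(specimen_id, sequence, genetic_code = "5",
                           long_min = 658) {
  data.frame(specimen_id = specimen_id, sequence = sequence,
             second_sequence = NA_character_, length = nchar(sequence),
             length_class = length_class(nchar(sequence), long_min),
             coverage = NA_integer_, total_count = NA_integer_,
             ratio = NA_real_, status = "pass", reasons = "external",
             translation_status = screen_translation(
               sequence, genetic_code = genetic_code),
             source = "sanger-supplied", stringsAsFactors = FALSE)
}
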
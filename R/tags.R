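## Sample-tag design and demultiplexing.
##
## Amplicons are labelled on both ends with short sample tags (9 bp by
## default) drawn from a set with minimum pairwise Hamming distance 3, so a
## single sequencing error inside a tag can still be corrected by
## nearest-tag decoding. The simulated construct layout is
##   tag_fwd + amplicon + reverse-complement(tag_rev)
## and reads may come off the instrument in either orientation.

#' Generate an error-tolerant sample tag set
#'
#' Randomly searches for `n` tags of length `tag_length` over {A,C,G,T} such
#' that all pairwise Hamming distances are at least `min_distance` and no tag
#' contains a homopolymer run longer than 3. The search is seeded and
#' deterministic; infeasible requests (or unlucky geometry) fail after a
#' bounded number of proposals.
#'
#' @param n number of tags required.
#' @param tag_length tag length in bases (default 9).
#' @param min_distance minimum pairwise Hamming distance (default 3).
#' @param seed integer seed for the search.
#' @param max_attempts proposal budget before declaring infeasibility.
#' @return an object of class `tag_set`: list with `tags` (character vector),
#'   `tag_length` and `min_distance`.
#' @export
#' @examples
#' ts <- generate_tag_set(8, seed = 1)
#' length(ts$tags)
generate_tag_set <- function(n, tag_length = 9, min_distance = 3, seed = 1,
                             max_attempts = 5000L * n) {
  stopifnot(n >= 1, tag_length >= 1)
  if (min_distance > tag_length) {
    stop("min_distance (", min_distance, ") cannot exceed tag_length (",
         tag_length, ")")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  homopolymer <- "A{4,}|C{4,}|G{4,}|T{4,}"
  tags <- character(0)
  tag_mat <- NULL
  attempts <- 0L
  while (length(tags) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("could not place ", n, " tags of length ", tag_length,
           " at Hamming distance >= ", min_distance, " within ",
           max_attempts, " attempts")
    }
    cand <- paste(sample(DNA_BASES, tag_length, replace = TRUE), collapse = "")
    if (grepl(homopolymer, cand)) next
    cand_chars <- strsplit(cand, "")[[1]]
    if (!is.null(tag_mat)) {
      dists <- rowSums(tag_mat != matrix(cand_chars, nrow = nrow(tag_mat),
                                         ncol = tag_length, byrow = TRUE))
      if (any(dists < min_distance)) next
    }
    tags <- c(tags, cand)
    tag_mat <- rbind(tag_mat, cand_chars)
  }
  structure(list(tags = tags, tag_length = tag_length,
                 min_distance = min_distance),
            class = "tag_set")
}

#' @export
print.tag_set <- function(x, ...) {
  cat("tag_set:", length(x$tags), "tags of length", x$tag_length,
      "(min pairwise Hamming distance", paste0(x$min_distance, ")\n"))
  invisible(x)
}

#' Pairwise Hamming distances of a tag set
#'
#' @param tags character vector of equal-length tags.
#' @return symmetric integer matrix of Hamming distances.
#' @export
tag_distances <- function(tags) {
  m <- seq_char_matrix(tags)
  n <- length(tags)
  d <- matrix(0L, n, n, dimnames = list(tags, tags))
  for (i in seq_len(n - 1)) {
    block <- m[(i + 1):n, , drop = FALSE]
    di <- rowSums(block != matrix(m[i, ], nrow = nrow(block),
                                  ncol = ncol(m), byrow = TRUE))
    d[i, (i + 1):n] <- di
    d[(i + 1):n, i] <- di
  }
  d
}

## nearest-tag decode: for each candidate string, the index of the closest
## tag, its distance, and whether that minimum is unique
nearest_tag <- function(candidates, tags) {
  cm <- seq_char_matrix(candidates)
  nt <- length(tags)
  dmat <- matrix(0L, nrow = length(candidates), ncol = nt)
  for (j in seq_len(nt)) {
    tj <- strsplit(tags[j], "")[[1]]
    dmat[, j] <- rowSums(cm != matrix(tj, nrow = nrow(cm), ncol = ncol(cm),
                                      byrow = TRUE))
  }
  best <- max.col(-dmat, ties.method = "first")
  bestd <- dmat[cbind(seq_along(candidates), best)]
  unique_min <- rowSums(dmat == bestd) == 1L
  list(index = best, distance = bestd, unique = unique_min)
}

#' Demultiplex tagged amplicon reads to specimens
#'
#' Assigns each read to a specimen by nearest-tag decoding of its two
#' terminal tags against the tag set, in both orientations. A read is
#' assigned iff both decoded tags lie within `max_mismatch` of a tag and the
#' decoded (forward, reverse) pair appears in the manifest. Tags are trimmed
#' from assigned reads, which are reported in forward orientation.
#'
#' @param reads named character vector (or `DNAStringSet`) of reads; names
#'   are read ids.
#' @param manifest data.frame with columns `specimen_id`, `tag_fwd`,
#'   `tag_rev`, `morphotype`.
#' @param tagset a `tag_set` from [generate_tag_set()] containing every tag
#'   used in the manifest.
#' @param max_mismatch per-tag mismatch budget; must satisfy
#'   `max_mismatch < ceiling(min_distance / 2)` so decoding is unambiguous.
#'   Default 0 (strict).
#' @return an object of class `demux_result`: list with `assignments`
#'   (data.frame: read_id, specimen_id, fwd_mismatch, rev_mismatch,
#'   orientation, sequence) and `unassigned` (data.frame: read_id, reason).
#' @export
demultiplex <- function(reads, manifest, tagset, max_mismatch = 0L) {
  if (inherits(reads, "DNAStringSet")) {
    reads <- setNames(as.character(reads), names(reads))
  }
  if (is.null(names(reads)) || anyDuplicated(names(reads))) {
    stop("reads must carry unique names (read ids)")
  }
  req <- c("specimen_id", "tag_fwd", "tag_rev", "morphotype")
  if (!all(req %in% names(manifest))) {
    stop("manifest must have columns: ", paste(req, collapse = ", "))
  }
  pair_key <- paste(manifest$tag_fwd, manifest$tag_rev)
  if (anyDuplicated(pair_key)) stop("duplicate tag pairs in manifest")
  if (!all(c(manifest$tag_fwd, manifest$tag_rev) %in% tagset$tags)) {
    stop("manifest uses tags not present in the tag set")
  }
  if (max_mismatch >= ceiling(tagset$min_distance / 2)) {
    stop("max_mismatch must be < ceiling(min_distance/2) = ",
         ceiling(tagset$min_distance / 2),
         " for unambiguous nearest-tag decoding")
  }

  tl <- tagset$tag_length
  ids <- names(reads)
  n <- length(reads)
  too_short <- nchar(reads) < 2L * tl

  specimen <- rep(NA_character_, n)
  fwd_mm <- rep(NA_integer_, n)
  rev_mm <- rep(NA_integer_, n)
  orientation <- rep(NA_character_, n)
  trimmed <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  reason[too_short] <- "read too short"

  todo <- which(!too_short)
  if (length(todo)) {
    fwd_seq <- reads[todo]
    rev_seq <- revcomp(fwd_seq)
    decode_orient <- function(sq) {
      p <- substr(sq, 1L, tl)
      s <- revcomp(substring(sq, nchar(sq) - tl + 1L))
      df <- nearest_tag(p, tagset$tags)
      dr <- nearest_tag(s, tagset$tags)
      within <- df$distance <= max_mismatch & dr$distance <= max_mismatch
      pk <- paste(tagset$tags[df$index], tagset$tags[dr$index])
      list(within = within, pair = pk,
           fwd_mm = df$distance, rev_mm = dr$distance)
    }
    fo <- decode_orient(fwd_seq)
    ro <- decode_orient(rev_seq)
    fwd_hit <- fo$within & fo$pair %in% pair_key
    rev_hit <- !fwd_hit & ro$within & ro$pair %in% pair_key

    idx_pair <- function(pk) match(pk, pair_key)
    sel <- function(hit, o, oriented_reads, label) {
      k <- todo[hit]
      if (!length(k)) return(invisible())
      specimen[k] <<- manifest$specimen_id[idx_pair(o$pair[hit])]
      fwd_mm[k] <<- o$fwd_mm[hit]
      rev_mm[k] <<- o$rev_mm[hit]
      orientation[k] <<- label
      sq <- oriented_reads[hit]
      trimmed[k] <<- substr(sq, tl + 1L, nchar(sq) - tl)
      invisible()
    }
    sel(fwd_hit, fo, fwd_seq, "forward")
    sel(rev_hit, ro, rev_seq, "reverse-complement")

    miss <- !(fwd_hit | rev_hit)
    budget_fail <- miss & !(fo$within | ro$within)
    reason[todo[budget_fail]] <- "tag beyond mismatch budget"
    reason[todo[miss & !budget_fail]] <- "tag pair not in manifest"
  }

  ok <- !is.na(specimen)
  structure(list(
    assignments = data.frame(
      read_id = ids[ok], specimen_id = specimen[ok],
      fwd_mismatch = fwd_mm[ok], rev_mismatch = rev_mm[ok],
      orientation = orientation[ok], sequence = trimmed[ok],
      stringsAsFactors = FALSE),
    unassigned = data.frame(
      read_id = ids[!ok], reason = reason[!ok], stringsAsFactors = FALSE),
    max_mismatch = max_mismatch
  ), class = "demux_result")
}

#' Reconstruct a tag set from a specimen manifest
#'
#' Collects the tags used in a manifest into a `tag_set`, verifying the
#' pairwise-distance invariant. Useful when demultiplexing from files
#' written by an earlier step.
#'
#' @param manifest data.frame with `tag_fwd` and `tag_rev` columns.
#' @param min_distance minimum pairwise Hamming distance to verify
#'   (default 3).
#' @return a `tag_set`.
#' @export
tag_set_from_manifest <- function(manifest, min_distance = 3) {
  tags <- unique(c(manifest$tag_fwd, manifest$tag_rev))
  if (length(unique(nchar(tags))) != 1L) {
    stop("manifest tags must all have the same length")
  }
  if (length(tags) > 1) {
    d <- tag_distances(tags)
    if (any(d[upper.tri(d)] < min_distance)) {
      stop("manifest tags violate the minimum pairwise distance ",
           min_distance)
    }
  }
  structure(list(tags = tags, tag_length = nchar(tags[1]),
                 min_distance = min_distance),
            class = "tag_set")
}

#' Per-specimen read pools from a demultiplexing result
#'
#' @param x a `demux_result`.
#' @param manifest the manifest used for demultiplexing; specimens with no
#'   assigned reads get an empty pool.
#' @return named list specimen_id -> character vector of trimmed reads.
#' @export
demux_pools <- function(x, manifest) {
  pools <- split(x$assignments$sequence, x$assignments$specimen_id)
  missing <- setdiff(manifest$specimen_id, names(pools))
  pools[missing] <- list(character(0))
  pools[manifest$specimen_id]
}

## save/restore global RNG state so seeded helpers do not perturb the
## caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
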
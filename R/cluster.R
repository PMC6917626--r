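## Objective clustering of barcodes into MOTUs.
##
## Pairwise uncorrected distances are computed on a common alignment with
## internal gaps treated as a fifth character state (gap vs base is a
## difference; gap vs gap is a match of the fifth state). Terminal gap
## columns are excluded and pairs overlapping fewer than `min_overlap`
## columns are incomparable, so 313-bp minibarcodes and 658-bp full
## barcodes remain comparable over their shared region. MOTUs are the
## connected components of the graph joining pairs at distance <= threshold
## (single linkage at threshold), with the headline threshold at 3%.

#' Uncorrected pairwise distance with gaps as a fifth state
#'
#' @param a,b aligned sequences of equal length (gaps as `-`).
#' @param gap_fifth treat internal gaps as a fifth character state
#'   (default TRUE): a gap vs a base is a difference and gap vs gap a match,
#'   with every overlap column in the denominator. When FALSE, gap columns
#'   are excluded from the denominator (differences are still counted), so
#'   an internal gap inflates rather than dilutes the distance.
#' @param min_overlap minimum number of comparable columns (default 100);
#'   pairs below it return `NA` (incomparable).
#' @return fraction of differing columns, or `NA`.
#' @export
#' @examples
#' pairwise_distance("AA-A", "AAAA", min_overlap = 1)            # 0.25
#' pairwise_distance("AA-A", "AAAA", gap_fifth = FALSE,
#'                   min_overlap = 1)                            # 1/3
pairwise_distance <- function(a, b, gap_fifth = TRUE, min_overlap = 100) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  if (length(ca) != length(cb)) {
    stop("aligned sequences must have equal length")
  }
  span <- function(x) {
    ng <- which(x != "-")
    if (!length(ng)) return(c(NA_integer_, NA_integer_))
    range(ng)
  }
  sa <- span(ca); sb <- span(cb)
  if (anyNA(c(sa, sb))) return(NA_real_)
  lo <- max(sa[1], sb[1]); hi <- min(sa[2], sb[2])
  if (hi < lo) return(NA_real_)
  ia <- ca[lo:hi]; ib <- cb[lo:hi]
  diffs <- sum(ia != ib)
  denom <- if (gap_fifth) length(ia) else sum(ia != "-" & ib != "-")
  if (denom < min_overlap) return(NA_real_)
  diffs / denom
}

#' Pairwise distance matrix for an alignment
#'
#' @param aligned named character vector of aligned sequences (equal
#'   lengths, gaps as `-`).
#' @param gap_fifth,min_overlap see [pairwise_distance()].
#' @return object of class `dist_matrix`: list with `ids`, `values`
#'   (symmetric matrix, `NA` for incomparable pairs) and `metadata`.
#' @export
distance_matrix <- function(aligned, gap_fifth = TRUE, min_overlap = 100) {
  ids <- names(aligned)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("aligned sequences must carry unique names")
  }
  n <- length(aligned)
  v <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d <- pairwise_distance(aligned[[i]], aligned[[j]],
                               gap_fifth = gap_fifth,
                               min_overlap = min_overlap)
        v[i, j] <- d
        v[j, i] <- d
      }
    }
  }
  structure(list(ids = ids, values = v,
                 metadata = list(gap_fifth = gap_fifth,
                                 min_overlap = min_overlap)),
            class = "dist_matrix")
}

as_dist_matrix <- function(x) {
  if (inherits(x, "dist_matrix")) return(x)
  if (is.matrix(x)) {
    ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
    return(structure(list(ids = ids, values = x, metadata = list()),
                     class = "dist_matrix"))
  }
  stop("expected a dist_matrix or a symmetric matrix")
}

#' Objective clustering at a distance threshold
#'
#' MOTUs are connected components of the graph joining pairs at distance
#' `<= threshold` (single linkage at threshold). Incomparable pairs (`NA`)
#' contribute no edge. Cluster labels are canonical: each cluster is named
#' after its lexicographically smallest member, so the partition is
#' independent of input order.
#'
#' @param d a `dist_matrix` (or plain symmetric matrix).
#' @param threshold distance threshold (default 0.03).
#' @return object of class `motu_partition`: list with `threshold`,
#'   `membership` (data.frame specimen_id/motu_id) and `clusters` (named
#'   list motu_id -> member ids).
#' @export
objective_cluster <- function(d, threshold = 0.03) {
  d <- as_dist_matrix(d)
  v <- d$values
  n <- length(d$ids)
  adj <- !is.na(v) & v <= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  ids <- d$ids
  motu_of_comp <- vapply(split(ids, comp), function(m) min(m), character(1))
  membership <- data.frame(specimen_id = ids,
                           motu_id = unname(motu_of_comp[as.character(comp)]),
                           stringsAsFactors = FALSE)
  membership <- membership[order(membership$specimen_id), , drop = FALSE]
  rownames(membership) <- NULL
  clusters <- split(membership$specimen_id, membership$motu_id)
  structure(list(threshold = threshold, membership = membership,
                 clusters = clusters),
            class = "motu_partition")
}

#' @export
print.motu_partition <- function(x, ...) {
  cat("motu_partition:", length(x$clusters), "MOTUs at threshold",
      x$threshold, "\n")
  invisible(x)
}

#' MOTU counts across a threshold profile
#'
#' @param d a `dist_matrix`.
#' @param thresholds ascending numeric vector of thresholds; the headline
#'   3% level is flagged in the output when present.
#' @return data.frame: threshold, n_motus, headline.
#' @export
cluster_profile <- function(d, thresholds = c(0.01, 0.02, 0.03, 0.04, 0.05)) {
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly ascending")
  }
  n <- vapply(thresholds, function(t) {
    length(objective_cluster(d, t)$clusters)
  }, integer(1))
  data.frame(threshold = thresholds, n_motus = n,
             headline = abs(thresholds - 0.03) < 1e-12)
}

#' Exclude sequences with large internal gaps before clustering
#'
#' Sequences whose longest internal gap run exceeds `max_internal_gap`
#' interfere with distance computation under the fifth-character rule and
#' are removed (a whole-codon 3-base deletion is retained).
#'
#' @param aligned named character vector of aligned sequences.
#' @param max_internal_gap maximum tolerated internal gap run (default 30).
#' @return list with `excluded` (data.frame specimen_id/reason) and
#'   `aligned` (the retained sequences).
#' @export
exclude_gap_outliers <- function(aligned, max_internal_gap = 30) {
  longest_internal_gap <- function(x) {
    ch <- strsplit(x, "")[[1]]
    ng <- which(ch != "-")
    if (length(ng) < 2) return(0L)
    inner <- ch[ng[1]:ng[length(ng)]]
    r <- rle(inner == "-")
    if (!any(r$values)) return(0L)
    max(r$lengths[r$values])
  }
  runs <- vapply(aligned, longest_internal_gap, integer(1))
  bad <- runs > max_internal_gap
  list(excluded = data.frame(
    specimen_id = names(aligned)[bad],
    reason = sprintf("internal gap of %d bases exceeds %d", runs[bad],
                     max_internal_gap),
    stringsAsFactors = FALSE, row.names = NULL),
    aligned = aligned[!bad])
}

#' Naive center-star multiple alignment
#'
#' A lightweight progressive aligner for the pipeline's own data: every
#' sequence is aligned pairwise (global on the sequence, local on the
#' center) to the longest input sequence, and the pairwise alignments are
#' merged on the center's coordinates, adding columns for insertions. For
#' protein-coding COI fragments of one or two amplicon lengths this is
#' adequate; it is not a general-purpose MSA tool, and an externally
#' computed alignment can be supplied to [distance_matrix()] instead.
#'
#' @param seqs named character vector of unaligned sequences.
#' @return named character vector of aligned sequences (equal lengths).
#' @export
align_center_star <- function(seqs) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must carry unique names")
  }
  if (length(unique(nchar(seqs))) == 1L &&
      !any(grepl("-", seqs, fixed = TRUE))) {
    return(seqs)  # equal-length ungapped input is already columnar
  }
  center_i <- which.max(nchar(seqs))
  center <- seqs[[center_i]]
  others <- setdiff(seq_along(seqs), center_i)

  ## per sequence: rows in center coordinates 1..nchar(center), plus a
  ## list of insertions (after-center-position -> inserted string)
  placed <- list()
  insertions <- list()
  for (i in others) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(seqs[[i]]), Biostrings::DNAString(center),
      type = "global-local", substitutionMatrix = nucleotide_scores(),
      gapOpening = 2, gapExtension = 1)
    p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    s_start <- Biostrings::start(Biostrings::subject(aln))
    row <- rep("-", nchar(center))
    ins <- list()
    cpos <- s_start - 1L
    for (k in seq_along(s)) {
      if (s[k] == "-") {
        key <- as.character(cpos)
        ins[[key]] <- paste0(ins[[key]] %||% "", p[k])
      } else {
        cpos <- cpos + 1L
        row[cpos] <- p[k]
      }
    }
    placed[[names(seqs)[i]]] <- row
    insertions[[names(seqs)[i]]] <- ins
  }

  ## union of insertion lengths after each center position
  ins_len <- integer(nchar(center) + 1L)
  names(ins_len) <- as.character(0:nchar(center))
  for (ins in insertions) {
    for (key in names(ins)) {
      ins_len[key] <- max(ins_len[key], nchar(ins[[key]]))
    }
  }

  expand <- function(row, ins) {
    out <- character(0)
    pad <- function(key) {
      L <- ins_len[key]
      if (L == 0L) return(character(0))
      x <- ins[[key]] %||% ""
      strsplit(paste0(x, strrep("-", L - nchar(x))), "")[[1]]
    }
    out <- c(out, pad("0"))
    for (p in seq_len(length(row))) {
      out <- c(out, row[p], pad(as.character(p)))
    }
    paste(out, collapse = "")
  }

  center_row <- strsplit(center, "")[[1]]
  res <- setNames(vector("character", length(seqs)), names(seqs))
  res[center_i] <- expand(center_row, list())
  for (nm in names(placed)) {
    res[nm] <- expand(placed[[nm]], insertions[[nm]])
  }
  res
}

#' Export a single-linkage dendrogram in Newick format
#'
#' @param d a complete `dist_matrix` (no incomparable pairs).
#' @param file output path.
#' @return invisibly, the `phylo` tree written.
#' @export
export_dendrogram <- function(d, file) {
  d <- as_dist_matrix(d)
  if (anyNA(d$values)) {
    stop("dendrogram export requires a complete distance matrix")
  }
  hc <- hclust(as.dist(d$values), method = "single")
  tr <- ape::as.phylo(hc)
  ape::write.tree(tr, file)
  invisible(tr)
}

#' Write a distance matrix to TSV and PHYLIP formats
#'
#' @param d a `dist_matrix`.
#' @param tsv,phylip output paths (either may be NULL to skip).
#' @return invisibly NULL.
#' @export
write_distance_matrix <- function(d, tsv = NULL, phylip = NULL) {
  d <- as_dist_matrix(d)
  if (!is.null(tsv)) {
    write.table(d$values, tsv, sep = "\t", quote = FALSE, col.names = NA)
  }
  if (!is.null(phylip)) {
    con <- file(phylip, "w")
    on.exit(close(con))
    writeLines(sprintf("%d", length(d$ids)), con)
    for (i in seq_along(d$ids)) {
      writeLines(paste(c(sprintf("%-10s", d$ids[i]),
                         sprintf("%.6f", d$values[i, ])), collapse = " "),
                 con)
    }
  }
  invisible(NULL)
}
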
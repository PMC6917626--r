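## Independent oracles and shared fixtures for the test suite.

## uncorrected p-distance on ungapped equal-length sequences
p_dist_oracle <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  mean(ca != cb)
}

## brute-force single-linkage-at-threshold clustering via union-find over
## all pairs; returns canonical membership labels (smallest member id)
uf_partition <- function(values, ids, threshold) {
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d <- values[i, j]
        if (!is.na(d) && d <= threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  labels <- vapply(split(ids, root), min, character(1))
  setNames(unname(labels[as.character(root)]), ids)
}

## brute-force local (Smith-Waterman) alignment score with affine gaps:
## match +1, mismatch -1, a gap of length L costs open + L * ext
sw_score_oracle <- function(a, b, match = 1, mismatch = -1,
                            open = 2, ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in A (consumes B)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in B (consumes A)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      E[i + 1, j + 1] <- max(H[i + 1, j] - (open + ext), E[i + 1, j] - ext)
      F[i + 1, j + 1] <- max(H[i, j + 1] - (open + ext), F[i, j + 1] - ext)
      s <- if (A[i] == B[j]) match else mismatch
      H[i + 1, j + 1] <- max(0, H[i, j] + s,
                             E[i + 1, j + 1], F[i + 1, j + 1])
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## mutate k interior positions (away from the ends so local alignment
## keeps the full span) to a different base
mutate_interior <- function(x, k, margin = 15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ch <- strsplit(x, "")[[1]]
  pos <- sample(seq(margin + 1, length(ch) - margin), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

## a random symmetric distance matrix with optional incomparable (NA) pairs
random_dist_matrix <- function(n, na_frac = 0, seed = 1) {
  set.seed(seed)
  v <- matrix(0, n, n)
  up <- upper.tri(v)
  vals <- runif(sum(up), 0, 0.2)
  if (na_frac > 0) vals[runif(length(vals)) < na_frac] <- NA
  v[up] <- vals
  v <- v + t(v)
  ids <- sprintf("S%03d", seq_len(n))
  dimnames(v) <- list(ids, ids)
  v
}

## small, fast survey worlds for pipeline-level tests
small_config <- function(...) {
  sim_config(n_species = 8, specimens_per_species = 3,
             reads_per_specimen_mean = 80, dropout_rate = 0.2,
             seed = 7, ...)
}

## memoise one small end-to-end run shared across test files
small_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      w <- simulate_world(small_config())
      cache <<- list(world = w, res = run_pipeline(w))
    }
    cache
  }
})
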
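## Ground-truthed synthetic data generator.
##
## Emulates a specimen-level barcoding survey: a pool of protein-coding
## COI-like species sequences separated by a barcoding gap, specimens sorted
## into phylum-level morphotypes (occasionally mis-sorted), per-specimen
## tagged read pools with a dominant self-derived sequence plus
## cross-contaminant reads, sequencing error, specimen-level amplification
## dropout, and a reference database containing named, unnamed ("sp.") and
## deliberately misidentified entries. Every read is traceable to its true
## source specimen, so downstream filters and assignments can be validated
## against ground truth.

#' Default phylum-level morphotype vocabulary
#'
#' The controlled vocabulary used for zooplankton sorts: seven phyla.
#' @export
MORPHOTYPE_VOCABULARY <- c("Arthropoda", "Annelida", "Chaetognatha",
                           "Chordata", "Cnidaria", "Mollusca",
                           "Platyhelminthes")

#' Simulation configuration
#'
#' Validated parameter bundle for the synthetic-data generator. Defaults
#' describe the study conditions the pipeline is tested under: 20 species x
#' 5 specimens across 7 phylum-level morphotypes, 313-bp amplicons, mean 200
#' reads per specimen, 0.1% per-base error, 10% cross-contamination, 5%
#' morphotype mis-sorts, 32% amplification dropout, and a reference database
#' in which 80% of entries carry a full binomial and 5% are misidentified.
#'
#' @param n_species number of species in the pool.
#' @param specimens_per_species specimens sampled per species.
#' @param intra_divergence_max maximum p-distance of any specimen haplotype
#'   (or reference variant) from its species sequence.
#' @param inter_divergence_min minimum p-distance between any two species
#'   sequences (must exceed `intra_divergence_max` so a barcoding gap exists
#'   by construction).
#' @param amplicon_length amplicon length in bases (default 313; the long
#'   barcode alternative is 658).
#' @param reads_per_specimen_mean Poisson mean of reads per non-dropout
#'   specimen.
#' @param per_base_error per-base substitution error probability.
#' @param contamination_fraction probability a read's template comes from a
#'   different specimen (it still carries the host specimen's tags).
#' @param missort_rate probability a specimen's morphotype label is wrong.
#' @param named_fraction fraction of reference entries with a full binomial;
#'   the rest are unnamed ("Genus sp.").
#' @param ref_misid_rate fraction of reference entries carrying a wrong
#'   taxonomy string (truth recorded).
#' @param dropout_rate probability a specimen yields no reads at all.
#' @param tag_length sample tag length (default 9).
#' @param tag_min_distance minimum pairwise Hamming distance between tags.
#' @param seed integer seed; all randomness in the generator derives from it.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_species = 20,
                       specimens_per_species = 5,
                       intra_divergence_max = 0.01,
                       inter_divergence_min = 0.05,
                       amplicon_length = 313,
                       reads_per_specimen_mean = 200,
                       per_base_error = 0.001,
                       contamination_fraction = 0.10,
                       missort_rate = 0.05,
                       named_fraction = 0.8,
                       ref_misid_rate = 0.05,
                       dropout_rate = 0.32,
                       tag_length = 9,
                       tag_min_distance = 3,
                       seed = 1) {
  cfg <- list(n_species = as.integer(n_species),
              specimens_per_species = as.integer(specimens_per_species),
              intra_divergence_max = intra_divergence_max,
              inter_divergence_min = inter_divergence_min,
              amplicon_length = as.integer(amplicon_length),
              reads_per_specimen_mean = reads_per_specimen_mean,
              per_base_error = per_base_error,
              contamination_fraction = contamination_fraction,
              missort_rate = missort_rate,
              named_fraction = named_fraction,
              ref_misid_rate = ref_misid_rate,
              dropout_rate = dropout_rate,
              tag_length = as.integer(tag_length),
              tag_min_distance = as.integer(tag_min_distance),
              seed = as.integer(seed))
  probs <- c("per_base_error", "contamination_fraction", "missort_rate",
             "named_fraction", "ref_misid_rate", "dropout_rate")
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0, 1]")
  }
  if (cfg$n_species < 1) stop("n_species must be >= 1")
  if (cfg$amplicon_length < 100) stop("amplicon_length must be >= 100")
  if (cfg$intra_divergence_max >= cfg$inter_divergence_min) {
    stop("intra_divergence_max must be < inter_divergence_min ",
         "(no barcoding gap by construction otherwise)")
  }
  if (cfg$inter_divergence_min > 0.75) {
    stop("inter_divergence_min > 0.75 is infeasible for 4-letter sequences")
  }
  structure(cfg, class = "sim_config")
}

## stop codons of a genetic code (default invertebrate mitochondrial,
## NCBI translation table 5)
stop_codons <- function(genetic_code = "5") {
  gc <- Biostrings::getGeneticCode(genetic_code)
  names(gc)[gc == "*"]
}

## sample n codons uniformly from the non-stop codons of the code
sample_nonstop_codons <- function(n, stops) {
  all_codons <- as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0),
                                DNA_BASES, paste0))
  ok <- setdiff(all_codons, stops)
  sample(ok, n, replace = TRUE)
}

## mutate `k` distinct sites (drawn from `site_pool`) of a char vector,
## rejecting any substitution that creates a stop codon in frame 1
mutate_sites <- function(chars, k, site_pool, stops) {
  if (k <= 0) return(chars)
  sites <- sample(site_pool, min(k, length(site_pool)))
  n_full <- length(chars) %/% 3L
  for (p in sites) {
    old <- chars[p]
    cands <- sample(setdiff(DNA_BASES, old))
    cp <- (p - 1L) %/% 3L + 1L
    for (b in cands) {
      chars[p] <- b
      if (cp > n_full) break  # partial terminal codon: no stop constraint
      codon <- paste(chars[(3L * cp - 2L):(3L * cp)], collapse = "")
      if (!codon %in% stops) break
      chars[p] <- old
    }
  }
  chars
}

#' Simulate a species pool with a barcoding gap
#'
#' Generates `n_species` protein-coding COI-like sequences of the configured
#' amplicon length by mutating a random in-frame ancestor, preferentially at
#' third codon positions, rejecting substitutions that would create internal
#' stop codons (invertebrate mitochondrial code). Species are
#' rejection-sampled until all pairwise uncorrected p-distances are at least
#' `inter_divergence_min`.
#'
#' @param config a [sim_config()].
#' @return named character vector of species sequences (`sp01`, `sp02`, ...).
#' @export
simulate_species_pool <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  L <- config$amplicon_length
  stops <- stop_codons("5")

  n_codons <- ceiling(L / 3)
  ancestor <- strsplit(paste(sample_nonstop_codons(n_codons, stops),
                             collapse = ""), "")[[1]][seq_len(L)]

  third_sites <- seq(3L, 3L * (L %/% 3L), by = 3L)
  first_sites <- seq(1L, 3L * (L %/% 3L), by = 3L)
  m_target <- ceiling(config$inter_divergence_min * L * 1.8)
  site_pool <- third_sites
  if (m_target > 0.8 * length(third_sites)) {
    site_pool <- c(third_sites, first_sites)
  }
  if (m_target > length(site_pool)) {
    stop("infeasible divergence demands: need ", m_target,
         " mutable sites but only ", length(site_pool), " available")
  }

  species <- list()
  for (i in seq_len(config$n_species)) {
    placed <- FALSE
    for (attempt in seq_len(500L)) {
      cand <- mutate_sites(ancestor, m_target, site_pool, stops)
      sq <- paste(cand, collapse = "")
      ok <- all(vapply(species, function(s) p_distance(s, sq), numeric(1)) >=
                  config$inter_divergence_min)
      if (ok) {
        species[[sprintf("sp%02d", i)]] <- sq
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("infeasible divergence demands: could not place species ", i,
           " at p-distance >= ", config$inter_divergence_min)
    }
  }
  unlist(species)
}

## a within-species variant: <= floor(intra_max * L) third-position changes
intra_variant <- function(species_seq, config, stops) {
  L <- nchar(species_seq)
  kmax <- floor(config$intra_divergence_max * L)
  k <- if (kmax > 0) sample(0:kmax, 1) else 0L
  third_sites <- seq(3L, 3L * (L %/% 3L), by = 3L)
  chars <- mutate_sites(strsplit(species_seq, "")[[1]], k, third_sites, stops)
  paste(chars, collapse = "")
}

#' Simulate specimens, morphotype sorts and tagged read pools
#'
#' Builds the specimen table (species membership, true phylum, possibly
#' mis-sorted morphotype label, dual tag pair), per-specimen haplotypes
#' within the intraspecific divergence bound, and tagged read pools: each
#' read's template is the host specimen's haplotype with probability
#' `1 - contamination_fraction`, otherwise another specimen's haplotype (a
#' cross-contaminant that still carries the host's tags). Substitution
#' errors are applied per base; half the reads are flipped to the reverse
#' strand; specimens drop out entirely with probability `dropout_rate`.
#'
#' @param species named character vector from [simulate_species_pool()].
#' @param config a [sim_config()].
#' @return an object of class `true_world` (without reference database):
#'   list with `config`, `species`, `specimen_table`, `haplotypes`,
#'   `tagset`, `manifest`, `reads` (tagged, named character vector) and
#'   `read_truth` (read_id, specimen_id, source_specimen, is_contaminant).
#' @export
simulate_specimens_and_reads <- function(species, config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 1L)
  stops <- stop_codons("5")
  L <- config$amplicon_length

  n <- config$n_species * config$specimens_per_species
  specimen_id <- sprintf("SP%03d", seq_len(n))
  species_id <- rep(names(species), each = config$specimens_per_species)

  phyla <- rep_len(MORPHOTYPE_VOCABULARY, config$n_species)
  names(phyla) <- names(species)
  true_phylum <- phyla[species_id]

  missorted <- runif(n) < config$missort_rate
  morphotype <- true_phylum
  morphotype[missorted] <- vapply(true_phylum[missorted], function(ph) {
    sample(setdiff(MORPHOTYPE_VOCABULARY, ph), 1)
  }, character(1))

  n_side <- ceiling(sqrt(n))
  tagset <- generate_tag_set(2L * n_side, tag_length = config$tag_length,
                             min_distance = config$tag_min_distance,
                             seed = config$seed + 101L)
  fwd_tags <- tagset$tags[seq_len(n_side)]
  rev_tags <- tagset$tags[n_side + seq_len(n_side)]
  tag_fwd <- fwd_tags[((seq_len(n) - 1L) %/% n_side) + 1L]
  tag_rev <- rev_tags[((seq_len(n) - 1L) %% n_side) + 1L]

  haplotypes <- vapply(species_id, function(sp) {
    intra_variant(species[[sp]], config, stops)
  }, character(1))
  names(haplotypes) <- specimen_id

  dropout <- runif(n) < config$dropout_rate
  n_reads <- ifelse(dropout, 0L, rpois(n, config$reads_per_specimen_mean))

  host <- rep(specimen_id, n_reads)
  total_reads <- length(host)
  contam <- runif(total_reads) < config$contamination_fraction
  source_spec <- host
  if (any(contam) && n > 1) {
    source_spec[contam] <- vapply(host[contam], function(h) {
      sample(setdiff(specimen_id, h), 1)
    }, character(1))
  }

  reads <- character(0)
  read_truth <- data.frame(read_id = character(0), specimen_id = character(0),
                           source_specimen = character(0),
                           is_contaminant = logical(0),
                           stringsAsFactors = FALSE)
  if (total_reads > 0) {
    hap_mat <- seq_char_matrix(unname(haplotypes))
    rownames(hap_mat) <- specimen_id
    read_mat <- hap_mat[source_spec, , drop = FALSE]
    if (config$per_base_error > 0) {
      err <- which(runif(length(read_mat)) < config$per_base_error)
      if (length(err)) {
        cur <- read_mat[err]
        read_mat[err] <- vapply(cur, function(b) {
          sample(setdiff(DNA_BASES, b), 1)
        }, character(1))
      }
    }
    amplicons <- apply(read_mat, 1L, paste, collapse = "")
    idx <- match(host, specimen_id)
    tagged <- paste0(tag_fwd[idx], amplicons, revcomp(tag_rev[idx]))
    flip <- runif(total_reads) < 0.5
    tagged[flip] <- revcomp(tagged[flip])
    read_id <- sprintf("R%07d", seq_len(total_reads))
    reads <- setNames(tagged, read_id)
    read_truth <- data.frame(read_id = read_id, specimen_id = host,
                             source_specimen = source_spec,
                             is_contaminant = contam,
                             stringsAsFactors = FALSE)
  }

  specimen_table <- data.frame(
    specimen_id = specimen_id, species_id = species_id,
    true_phylum = unname(true_phylum), morphotype = morphotype,
    missorted = missorted, dropout = dropout,
    tag_fwd = tag_fwd, tag_rev = tag_rev, stringsAsFactors = FALSE)
  manifest <- specimen_table[, c("specimen_id", "tag_fwd", "tag_rev",
                                 "morphotype")]

  structure(list(config = config, species = species,
                 specimen_table = specimen_table, haplotypes = haplotypes,
                 tagset = tagset, manifest = manifest,
                 reads = reads, read_truth = read_truth),
            class = "true_world")
}

#' Simulate a reference barcode database with realistic imperfections
#'
#' One entry per covered species, each a within-species variant of the true
#' sequence. A `named_fraction` of entries carry a full binomial; the rest
#' are unnamed ("Genus sp."). A `ref_misid_rate` fraction carry the taxonomy
#' string of a *different* species (misidentified), with the truth recorded.
#'
#' @param world a `true_world` from [simulate_specimens_and_reads()].
#' @param config a [sim_config()].
#' @param coverage fraction of species represented in the database
#'   (default 1 = all).
#' @return data.frame of reference entries: entry_id, taxonomy ranks
#'   (phylum..species), `named`, `misidentified`, `true_species_id`,
#'   `sequence`.
#' @export
simulate_reference_db <- function(world, config = world$config,
                                  coverage = 1) {
  stopifnot(inherits(world, "true_world"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 2L)
  stops <- stop_codons("5")

  spp <- names(world$species)
  phyla <- world$specimen_table$true_phylum[
    match(spp, world$specimen_table$species_id)]
  n_cov <- ceiling(coverage * length(spp))
  covered <- if (n_cov >= length(spp)) spp else sort(sample(spp, n_cov))
  if (n_cov == 0) covered <- character(0)

  taxonomy_of <- function(sp) {
    i <- match(sp, spp)
    g <- sprintf("Genus%02d", i)
    list(phylum = phyla[i],
         class = paste0(phyla[i], "_classis"),
         order = sprintf("Order%02d", (i - 1L) %/% 4L + 1L),
         family = sprintf("Family%02d", (i - 1L) %/% 2L + 1L),
         genus = g,
         species = sprintf("%s species%02d", g, i))
  }

  n_e <- length(covered)
  if (n_e == 0) {
    return(data.frame(entry_id = character(0), phylum = character(0),
                      class = character(0), order = character(0),
                      family = character(0), genus = character(0),
                      species = character(0), named = logical(0),
                      misidentified = logical(0),
                      true_species_id = character(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  }
  named <- runif(n_e) < config$named_fraction
  misid <- runif(n_e) < config$ref_misid_rate & length(spp) > 1

  rows <- lapply(seq_len(n_e), function(k) {
    sp <- covered[k]
    tax_src <- if (misid[k]) sample(setdiff(spp, sp), 1) else sp
    tx <- taxonomy_of(tax_src)
    if (!named[k]) tx$species <- paste(tx$genus, "sp.")
    data.frame(entry_id = sprintf("REF%03d", k),
               phylum = tx$phylum, class = tx$class, order = tx$order,
               family = tx$family, genus = tx$genus, species = tx$species,
               named = named[k], misidentified = misid[k],
               true_species_id = sp,
               sequence = intra_variant(world$species[[sp]],
                                        config, stops),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a complete ground-truthed survey
#'
#' Convenience wrapper chaining [simulate_species_pool()],
#' [simulate_specimens_and_reads()] and [simulate_reference_db()].
#'
#' @param config a [sim_config()].
#' @param ref_coverage fraction of species in the reference database.
#' @return a `true_world` with the reference database attached as
#'   `$reference`.
#' @export
simulate_world <- function(config = sim_config(), ref_coverage = 1) {
  species <- simulate_species_pool(config)
  world <- simulate_specimens_and_reads(species, config)
  world$reference <- simulate_reference_db(world, config,
                                           coverage = ref_coverage)
  world
}

#' @export
print.true_world <- function(x, ...) {
  cat("true_world:", length(x$species), "species,",
      nrow(x$specimen_table), "specimens,", length(x$reads), "reads",
      sprintf("(seed %d)\n", x$config$seed))
  invisible(x)
}

#' Write a simulated world to plain-text files
#'
#' Writes the specimen manifest (TSV), tagged reads (FASTA), reference
#' database (FASTA with `id|phylum;class;...;species` headers), truth tables
#' (TSV) and the configuration (JSON, seed included) to a directory.
#'
#' @param world a `true_world`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(manifest = file.path(dir, "manifest.tsv"),
             reads = file.path(dir, "reads.fasta"),
             reference = file.path(dir, "reference.fasta"),
             specimens = file.path(dir, "truth_specimens.tsv"),
             read_truth = file.path(dir, "truth_reads.tsv"),
             config = file.path(dir, "config.json"))
  write.table(world$manifest, paths["manifest"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(world$reads),
                              paths["reads"])
  ref <- world$reference
  headers <- paste0(ref$entry_id, "|",
                    apply(ref[, c("phylum", "class", "order", "family",
                                  "genus", "species")], 1, paste,
                          collapse = ";"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(ref$sequence, headers)),
    paths["reference"])
  write.table(world$specimen_table, paths["specimens"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(world$read_truth, paths["read_truth"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(world$config), paths["config"],
                       auto_unbox = TRUE)
  invisible(paths)
}
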
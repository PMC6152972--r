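## Synthetic small-RNA study generator: genomes with planted pre-miRNA
## hairpins, sister genomes for homology, and read libraries with
## controlled arm bias, 5' jitter, star frequency and sex-biased
## abundances. Defaults emulate the statistical structure of a
## male/female adult small-RNA experiment: six libraries, read-length
## mode at 22 nt, 5' U preference, clustered loci, log-normal locus
## abundances.

#' Configuration for the synthetic small-RNA study
#'
#' @param genome_length genome size in nt.
#' @param n_loci number of planted pre-miRNA loci.
#' @param n_clustered_pairs how many locus pairs are placed as genomic
#'   clusters with exact gaps taken from `cluster_gaps`.
#' @param cluster_gaps intra-cluster gaps in nt, recycled over pairs.
#' @param mature_length_probs named probability vector over mature
#'   lengths 18-30 nt (default peaks at 22 nt).
#' @param arm_bias fraction of a locus's reads produced from its
#'   dominant (mature) arm, in (0.5, 1]. Scalar or per-locus vector.
#' @param star_fraction optional expected star/mature read ratio; when
#'   given it overrides `arm_bias` via `arm_bias = 1/(1+star_fraction)`.
#' @param five_prime_jitter probability vector over 5' start offsets
#'   -2..+2 for mature reads.
#' @param star_five_prime_jitter same for star reads; broader by
#'   default, emulating the lower 5' precision of star species.
#' @param libraries data.frame with columns `name`, `condition`
#'   (`"male"`/`"female"`) and `depth` (reads per library).
#' @param lfc_sd standard deviation of planted per-locus log2 fold
#'   changes (female vs male) for the `n_biased_loci` biased loci.
#' @param n_biased_loci number of sex-biased loci.
#' @param biased_lfc optional fixed |log2FC| for biased loci (random
#'   sign); overrides draws from `N(0, lfc_sd)`.
#' @param first_nt_u_prob probability that a mature sequence starts
#'   with U.
#' @param cpm_meanlog,cpm_sdlog log-normal parameters of per-locus mean
#'   abundance (counts per million).
#' @param decoy_fraction background (non-locus) reads as a fraction of
#'   depth.
#' @param contaminants optional named list of reference sequence sets
#'   (e.g. `list(rRNA = c(...))`) sampled as contaminant reads.
#' @param contaminant_fraction contaminant reads as a fraction of depth.
#' @param error_rate optional per-base substitution error rate in reads.
#' @param homolog_mutation_rate per-base substitution rate used to
#'   derive the two sister genomes.
#' @param loop_len,overhang hairpin geometry passed to [build_hairpin()].
#' @param rng_seed integer seed; the whole simulation is a deterministic
#'   function of the configuration including this seed.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(genome_length = 100000L,
                       n_loci = 30L,
                       n_clustered_pairs = 2L,
                       cluster_gaps = c(73L, 920L),
                       mature_length_probs = NULL,
                       arm_bias = 0.8,
                       star_fraction = NULL,
                       five_prime_jitter = c(`-2` = 0.02, `-1` = 0.08,
                                             `0` = 0.8, `1` = 0.08, `2` = 0.02),
                       star_five_prime_jitter = c(`-2` = 0.10, `-1` = 0.15,
                                                  `0` = 0.50, `1` = 0.15, `2` = 0.10),
                       libraries = NULL,
                       lfc_sd = 2,
                       n_biased_loci = 10L,
                       biased_lfc = NULL,
                       first_nt_u_prob = 0.7,
                       cpm_meanlog = log(100),
                       cpm_sdlog = 1,
                       decoy_fraction = 0.1,
                       contaminants = NULL,
                       contaminant_fraction = 0,
                       error_rate = 0,
                       homolog_mutation_rate = 0.02,
                       loop_len = 10L,
                       overhang = 2L,
                       rng_seed = 1L) {
  if (is.null(mature_length_probs)) {
    mature_length_probs <- c(`18` = 0.01, `19` = 0.02, `20` = 0.06,
                             `21` = 0.18, `22` = 0.40, `23` = 0.18,
                             `24` = 0.08, `25` = 0.03, `26` = 0.015,
                             `27` = 0.01, `28` = 0.005, `29` = 0.005,
                             `30` = 0.005)
  }
  if (is.null(libraries)) {
    libraries <- data.frame(
      name = c("male_1", "male_2", "male_3", "female_1", "female_2", "female_3"),
      condition = rep(c("male", "female"), each = 3),
      depth = 1e5,
      stringsAsFactors = FALSE)
  }
  if (!is.null(star_fraction)) {
    stopifnot(star_fraction > 0)
    arm_bias <- 1 / (1 + star_fraction)
  }
  cfg <- list(genome_length = as.integer(genome_length), n_loci = as.integer(n_loci),
              n_clustered_pairs = as.integer(n_clustered_pairs),
              cluster_gaps = as.integer(cluster_gaps),
              mature_length_probs = mature_length_probs,
              arm_bias = arm_bias,
              five_prime_jitter = five_prime_jitter,
              star_five_prime_jitter = star_five_prime_jitter,
              libraries = libraries, lfc_sd = lfc_sd,
              n_biased_loci = as.integer(n_biased_loci),
              biased_lfc = biased_lfc,
              first_nt_u_prob = first_nt_u_prob,
              cpm_meanlog = cpm_meanlog, cpm_sdlog = cpm_sdlog,
              decoy_fraction = decoy_fraction,
              contaminants = contaminants,
              contaminant_fraction = contaminant_fraction,
              error_rate = error_rate,
              homolog_mutation_rate = homolog_mutation_rate,
              loop_len = as.integer(loop_len), overhang = as.integer(overhang),
              rng_seed = as.integer(rng_seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  lens <- as.integer(names(cfg$mature_length_probs))
  if (any(lens < 18 | lens > 30))
    stop("mature lengths must lie in 18-30 nt")
  for (nm in c("mature_length_probs", "five_prime_jitter", "star_five_prime_jitter")) {
    if (abs(sum(cfg[[nm]]) - 1) > 1e-8)
      stop(nm, " must sum to 1")
    if (any(cfg[[nm]] < 0)) stop(nm, " must be non-negative")
  }
  if (any(cfg$arm_bias <= 0.5) || any(cfg$arm_bias > 1))
    stop("arm_bias must lie in (0.5, 1]")
  if (any(cfg$libraries$depth <= 0)) stop("library depths must be > 0")
  if (!all(cfg$libraries$condition %in% c("male", "female")))
    stop("library conditions must be 'male' or 'female'")
  if (cfg$n_biased_loci > cfg$n_loci)
    stop("n_biased_loci cannot exceed n_loci")
  # generous per-locus footprint: two 30-nt arms + loop + overhang + spacing
  need <- cfg$n_loci * (2 * 30 + cfg$loop_len + cfg$overhang + 250) +
    sum(rep_len(cfg$cluster_gaps, cfg$n_clustered_pairs))
  if (need > cfg$genome_length)
    stop("genome_length too small to place ", cfg$n_loci, " loci")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: ", x$n_loci, " loci in ", x$genome_length, " nt genome, ",
      nrow(x$libraries), " libraries, seed ", x$rng_seed, "\n", sep = "")
  invisible(x)
}

#' Simulate a genome with planted pre-miRNA loci
#'
#' Draws per-locus properties (mature length and sequence, arm, strand,
#' abundance, planted log2 fold change), builds hairpins, plants them in
#' a random genome (clustered pairs at the exact configured gaps) and
#' derives two mutated sister genomes. The result carries a full truth
#' table for downstream parameter-recovery checks.
#'
#' @param config a [sim_config()].
#' @return object of class `mirna_sim`: list with `genome` (string),
#'   `sister_genomes` (named list), `truth` (data.frame), `precursors`
#'   (list of [build_hairpin()] results) and `config`.
#' @export
simulate_genome <- function(config = sim_config()) {
  cfg <- config
  set.seed(cfg$rng_seed)
  n <- cfg$n_loci
  ids <- sprintf("mir-n%03d", seq_len(n))

  lens <- as.integer(sample(names(cfg$mature_length_probs), n, replace = TRUE,
                            prob = cfg$mature_length_probs))
  firsts <- ifelse(runif(n) < cfg$first_nt_u_prob, "U",
                   sample(c("A", "C", "G"), n, replace = TRUE))
  matures <- vapply(seq_len(n), function(i) {
    paste0(firsts[i], paste(sample(c("A", "C", "G", "U"), lens[i] - 1,
                                   replace = TRUE), collapse = ""))
  }, character(1))
  arms <- sample(c("5p", "3p"), n, replace = TRUE)
  strands <- sample(c("+", "-"), n, replace = TRUE)
  arm_bias <- rep_len(cfg$arm_bias, n)
  lfc <- numeric(n)
  biased <- if (cfg$n_biased_loci > 0) sample(n, cfg$n_biased_loci) else integer(0)
  if (length(biased)) {
    lfc[biased] <- if (is.null(cfg$biased_lfc)) {
      rnorm(length(biased), 0, cfg$lfc_sd)
    } else {
      sample(c(-1, 1), length(biased), replace = TRUE) * cfg$biased_lfc
    }
  }
  cpm <- rlnorm(n, cfg$cpm_meanlog, cfg$cpm_sdlog)

  precursors <- lapply(seq_len(n), function(i) {
    build_hairpin(matures[i], loop_len = cfg$loop_len, mature_on = arms[i],
                  overhang = cfg$overhang)
  })

  cluster <- rep(NA_character_, n)
  cluster_gap <- rep(NA_integer_, n)
  if (cfg$n_clustered_pairs > 0) {
    gaps <- rep_len(cfg$cluster_gaps, cfg$n_clustered_pairs)
    for (p in seq_len(cfg$n_clustered_pairs)) {
      members <- c(2 * p - 1, 2 * p)
      cluster[members] <- sprintf("cluster%02d", p)
      cluster_gap[members[2]] <- gaps[p]
      strands[members] <- strands[members[1]]   # clustered loci co-oriented
    }
  }

  genome <- random_dna(cfg$genome_length)
  planted <- plant_loci(genome, data.frame(
    id = ids, seq = vapply(precursors, `[[`, character(1), "precursor"),
    strand = strands, pos = NA_integer_, cluster = cluster,
    cluster_gap = cluster_gap, stringsAsFactors = FALSE))

  truth <- planted$truth
  truth$seqname <- "chr1"
  truth$mature_arm <- arms
  truth$mature_seq <- matures
  truth$star_seq <- vapply(precursors, `[[`, character(1), "star_seq")
  truth$mature_rel_start <- vapply(precursors, function(p) p$mature[[1]], integer(1))
  truth$mature_rel_end <- vapply(precursors, function(p) p$mature[[2]], integer(1))
  truth$star_rel_start <- vapply(precursors, function(p) p$star[[1]], integer(1))
  truth$star_rel_end <- vapply(precursors, function(p) p$star[[2]], integer(1))
  truth$arm_bias <- arm_bias
  truth$lfc <- lfc
  truth$cpm <- cpm
  truth$biased <- seq_len(n) %in% biased

  sisters <- list(
    sisterA = mutate_genome(planted$genome, cfg$homolog_mutation_rate),
    sisterB = mutate_genome(planted$genome, cfg$homolog_mutation_rate))

  structure(list(genome = planted$genome, sister_genomes = sisters,
                 truth = truth, precursors = stats::setNames(precursors, ids),
                 config = cfg),
            class = "mirna_sim")
}

#' @export
print.mirna_sim <- function(x, ...) {
  cat("mirna_sim: ", nrow(x$truth), " planted loci in ",
      nchar(x$genome), " nt genome + ", length(x$sister_genomes),
      " sister genome(s)\n", sep = "")
  invisible(x)
}

## genome-coordinate interval of an arm, honouring strand
arm_genome_interval <- function(locus_start, locus_end, strand, rel) {
  if (strand == "+") c(locus_start + rel[1], locus_start + rel[2])
  else c(locus_end - rel[2], locus_end - rel[1])
}

## expand `n` arm reads with 5' offsets drawn from `probs` (3' end
## fixed); one substring/revcomp per distinct offset, replicated by the
## drawn multiplicities
arm_reads <- function(genome, gs, ge, strand, n, offs, probs) {
  draw <- sample(offs, n, replace = TRUE, prob = probs)
  tab <- table(draw)
  uniq <- as.integer(names(tab))
  seqs <- vapply(uniq, function(o) {
    if (strand == "+") subseq0(genome, gs + o, ge)
    else subseq0(genome, gs, ge - o)
  }, character(1))
  if (strand == "-") seqs <- rc_dna(seqs)
  rep(seqs, as.integer(tab))
}

#' Simulate small-RNA read libraries from planted loci
#'
#' For every library, per-locus read totals are Poisson around the
#' locus's depth-scaled mean abundance (shifted by half the planted
#' log2 fold change in each direction for female/male libraries); reads
#' split between mature and star arms by the planted arm bias, and 5'
#' start positions jitter per the configured offset distributions.
#' Background decoy reads are drawn from non-locus genome positions, and
#' optional contaminant reads from supplied reference sets.
#'
#' @param sim a [simulate_genome()] result.
#' @param config configuration; defaults to the one inside `sim`.
#' @return object of class `sim_reads`: list with `libraries` (named
#'   list of data.frames `sequence`, `origin`, `locus`) and `expected`
#'   (per locus x library expected mature/star counts).
#' @export
simulate_reads <- function(sim, config = sim$config) {
  cfg <- config
  set.seed(cfg$rng_seed + 1000L)
  truth <- sim$truth
  libs <- cfg$libraries
  offs <- as.integer(names(cfg$five_prime_jitter))
  soffs <- as.integer(names(cfg$star_five_prime_jitter))
  out <- list()
  expected <- list()

  for (l in seq_len(nrow(libs))) {
    depth <- libs$depth[l]
    sgn <- if (libs$condition[l] == "female") 1 else -1
    recs <- list()
    for (i in seq_len(nrow(truth))) {
      mean_i <- depth * truth$cpm[i] * 2^(sgn * truth$lfc[i] / 2) / 1e6
      n_tot <- rpois(1, mean_i)
      expected[[length(expected) + 1]] <- data.frame(
        locus = truth$id[i], library = libs$name[l], expected_total = mean_i,
        stringsAsFactors = FALSE)
      if (n_tot == 0) next
      n_m <- rbinom(1, n_tot, truth$arm_bias[i])
      n_s <- n_tot - n_m
      m_iv <- arm_genome_interval(truth$start[i], truth$end[i], truth$strand[i],
                                  c(truth$mature_rel_start[i], truth$mature_rel_end[i]))
      s_iv <- arm_genome_interval(truth$start[i], truth$end[i], truth$strand[i],
                                  c(truth$star_rel_start[i], truth$star_rel_end[i]))
      if (n_m > 0) {
        seqs <- arm_reads(sim$genome, m_iv[1], m_iv[2], truth$strand[i],
                          n_m, offs, cfg$five_prime_jitter)
        recs[[length(recs) + 1]] <- data.frame(
          sequence = seqs, origin = "mature", locus = truth$id[i],
          stringsAsFactors = FALSE)
      }
      if (n_s > 0) {
        seqs <- arm_reads(sim$genome, s_iv[1], s_iv[2], truth$strand[i],
                          n_s, soffs, cfg$star_five_prime_jitter)
        recs[[length(recs) + 1]] <- data.frame(
          sequence = seqs, origin = "star", locus = truth$id[i],
          stringsAsFactors = FALSE)
      }
    }
    ## background decoys from non-locus genome positions
    n_d <- rpois(1, depth * cfg$decoy_fraction)
    if (n_d > 0) {
      dl <- as.integer(sample(names(cfg$mature_length_probs), n_d, replace = TRUE,
                              prob = cfg$mature_length_probs))
      G <- nchar(sim$genome)
      dstart <- as.integer(floor(runif(n_d, 0, G - dl)))
      repeat {
        # redraw any decoy overlapping a planted locus
        bad <- vapply(seq_len(n_d), function(d)
          any(truth$start < dstart[d] + dl[d] & dstart[d] < truth$end),
          logical(1))
        if (!any(bad)) break
        dstart[bad] <- as.integer(floor(runif(sum(bad), 0, G - dl[bad])))
      }
      dstrand <- sample(c("+", "-"), n_d, replace = TRUE)
      dseq <- substring(sim$genome, dstart + 1, dstart + dl)
      dseq[dstrand == "-"] <- rc_dna(dseq[dstrand == "-"])
      recs[[length(recs) + 1]] <- data.frame(
        sequence = dseq, origin = "decoy", locus = NA_character_,
        stringsAsFactors = FALSE)
    }
    ## contaminant reads drawn from known-ncRNA reference sets
    if (!is.null(cfg$contaminants) && cfg$contaminant_fraction > 0) {
      n_c <- rpois(1, depth * cfg$contaminant_fraction)
      if (n_c > 0) {
        classes <- sample(names(cfg$contaminants), n_c, replace = TRUE)
        cseq <- vapply(classes, function(cl) {
          ref <- sample(cfg$contaminants[[cl]], 1)
          w <- min(nchar(ref), sample(18:30, 1))
          s0 <- sample(nchar(ref) - w + 1, 1)
          substr(ref, s0, s0 + w - 1)
        }, character(1), USE.NAMES = FALSE)
        recs[[length(recs) + 1]] <- data.frame(
          sequence = cseq, origin = paste0("contaminant:", classes),
          locus = NA_character_, stringsAsFactors = FALSE)
      }
    }
    lib_df <- if (length(recs)) do.call(rbind, recs) else
      data.frame(sequence = character(0), origin = character(0),
                 locus = character(0), stringsAsFactors = FALSE)
    if (!nrow(lib_df))
      warning("library '", libs$name[l], "' is empty under this configuration")
    if (cfg$error_rate > 0 && nrow(lib_df)) {
      lib_df$sequence <- vapply(lib_df$sequence, function(s) {
        b <- strsplit(s, "")[[1]]
        hit <- which(runif(length(b)) < cfg$error_rate)
        if (length(hit))
          b[hit] <- vapply(b[hit], function(x) sample(setdiff(DNA_BASES, x), 1),
                           character(1))
        paste(b, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    rownames(lib_df) <- NULL
    out[[libs$name[l]]] <- lib_df
  }
  structure(list(libraries = out, expected = do.call(rbind, expected),
                 config = cfg),
            class = "sim_reads")
}

#' @export
print.sim_reads <- function(x, ...) {
  n <- vapply(x$libraries, nrow, integer(1))
  cat("sim_reads: ", length(n), " libraries, ",
      paste(names(n), n, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Simulate a miRNA count matrix directly
#'
#' Count-level shortcut past read simulation, used for differential
#' expression calibration at large miRNA numbers: per-miRNA mean CPM is
#' log-normal, per-library counts are Poisson at the library depth, and
#' female/male means differ by the per-miRNA log2 fold change.
#'
#' @param n_mirna number of miRNAs.
#' @param libraries data.frame `name`, `condition`, `depth` (defaults to
#'   the six-library two-condition design of [sim_config()]).
#' @param lfc scalar or per-miRNA log2 fold change (female vs male).
#' @param cpm_meanlog,cpm_sdlog log-normal abundance parameters.
#' @param seed RNG seed.
#' @return list with `counts` (matrix), `conditions`, `depths`, `lfc`.
#' @export
simulate_count_matrix <- function(n_mirna, libraries = NULL, lfc = 0,
                                  cpm_meanlog = log(100), cpm_sdlog = 1,
                                  seed = 1L) {
  if (is.null(libraries)) libraries <- sim_config()$libraries
  set.seed(seed)
  lfc <- rep_len(lfc, n_mirna)
  cpm <- rlnorm(n_mirna, cpm_meanlog, cpm_sdlog)
  counts <- matrix(0L, n_mirna, nrow(libraries),
                   dimnames = list(sprintf("mir%04d", seq_len(n_mirna)),
                                   libraries$name))
  for (l in seq_len(nrow(libraries))) {
    sgn <- if (libraries$condition[l] == "female") 1 else -1
    mu <- libraries$depth[l] * cpm * 2^(sgn * lfc / 2) / 1e6
    counts[, l] <- rpois(n_mirna, mu)
  }
  list(counts = counts,
       conditions = stats::setNames(libraries$condition, libraries$name),
       depths = stats::setNames(libraries$depth, libraries$name),
       lfc = stats::setNames(lfc, rownames(counts)))
}

#' Simulate a transcriptome with planted miRNA target sites
#'
#' Generates random 3' UTR sequences and plants, for each miRNA, exact
#' full-length complementary sites in randomly chosen genes. Planted
#' sites satisfy both the seed criterion and the hybridisation-energy
#' criterion, so they serve as ground truth for consensus target
#' recovery.
#'
#' @param mirnas named character vector of mature miRNA sequences (RNA).
#' @param n_genes number of UTRs.
#' @param utr_len UTR length in nt.
#' @param sites_per_mirna planted sites per miRNA.
#' @param seed RNG seed.
#' @return list with `utrs` (named character, RNA), `truth`
#'   (data.frame `mirna`, `gene`, `pos` 0-based site start).
#' @export
simulate_transcriptome <- function(mirnas, n_genes = 50L, utr_len = 500L,
                                   sites_per_mirna = 3L, seed = 1L) {
  set.seed(seed)
  genes <- sprintf("gene%03d", seq_len(n_genes))
  utrs <- stats::setNames(vapply(genes, function(g)
    dna2rna(random_dna(utr_len)), character(1)), genes)
  truth <- list()
  for (m in names(mirnas)) {
    site <- dna2rna(rc_dna(rna2dna(mirnas[[m]])))
    w <- nchar(site)
    for (s in seq_len(sites_per_mirna)) {
      g <- sample(genes, 1)
      pos <- sample(utr_len - w + 1, 1) - 1L
      utrs[[g]] <- paste0(substr(utrs[[g]], 1, pos), site,
                          substr(utrs[[g]], pos + w + 1, utr_len))
      truth[[length(truth) + 1]] <- data.frame(
        mirna = m, gene = g, pos = pos, stringsAsFactors = FALSE)
    }
  }
  list(utrs = utrs, truth = do.call(rbind, truth))
}

#' Write a simulated study to disk
#'
#' Writes the genome and sister genomes as FASTA, one FASTQ per library
#' (constant high quality), the locus truth table as GFF3 plus TSVs for
#' expression/cluster/homolog truth, and the configuration as YAML.
#'
#' @param sim a [simulate_genome()] result.
#' @param reads a [simulate_reads()] result.
#' @param dir output directory (created if needed).
#' @return the output directory, invisibly.
#' @export
write_simulation <- function(sim, reads, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gset <- Biostrings::DNAStringSet(c(chr1 = sim$genome))
  Biostrings::writeXStringSet(gset, file.path(dir, "genome.fa"))
  for (nm in names(sim$sister_genomes)) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(stats::setNames(sim$sister_genomes[[nm]], "chr1")),
      file.path(dir, paste0("genome_", nm, ".fa")))
  }
  for (nm in names(reads$libraries)) {
    df <- reads$libraries[[nm]]
    if (!nrow(df)) {
      file.create(file.path(dir, paste0(nm, ".fastq")))
      next
    }
    ds <- Biostrings::DNAStringSet(df$sequence)
    names(ds) <- sprintf("%s_read%06d", nm, seq_len(nrow(df)))
    qual <- Biostrings::BStringSet(strrep("I", nchar(df$sequence)))
    Biostrings::writeXStringSet(ds, file.path(dir, paste0(nm, ".fastq")),
                                format = "fastq", qualities = qual)
  }
  gr <- intervals_to_granges(data.frame(
    seqname = sim$truth$seqname, start = sim$truth$start, end = sim$truth$end,
    strand = sim$truth$strand, ID = sim$truth$id, type = "pre_miRNA",
    stringsAsFactors = FALSE))
  rtracklayer::export(gr, file.path(dir, "loci.gff3"), format = "gff3")
  write_tsv(sim$truth, file.path(dir, "truth_loci.tsv"))
  write_tsv(reads$expected, file.path(dir, "truth_expression.tsv"))
  yaml::write_yaml(unclass(sim$config)[setdiff(names(sim$config),
                                               c("libraries", "contaminants"))],
                   file.path(dir, "config.yaml"))
  write_tsv(sim$config$libraries, file.path(dir, "libraries.tsv"))
  invisible(dir)
}
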
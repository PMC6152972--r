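test_that("build_hairpin constructs perfect and bulged duplexes", {
  hp <- build_hairpin("UGAGGUAGUAGGUUGUAUAGUU", loop_len = 8)
  expect_equal(nchar(hp$precursor), 22 + 8 + 22 + 2)
  expect_equal(hp$mature_seq, "UGAGGUAGUAGGUUGUAUAGUU")
  # arms are exact reverse complements over the core
  core <- substr(hp$precursor, hp$star[1] + 1, hp$star[2] - 2)
  expect_equal(core, chartr("T", "U", oracle_revcomp(
    chartr("U", "T", hp$mature_seq))))

  expect_error(build_hairpin("UGAGGUAGUAGGUUGUAUAGUU", loop_len = 2),
               "sterically")
  expect_error(build_hairpin("ACGU"), "18-30")
  expect_error(build_hairpin("UGAGGUAGUAGGUUGUAUAGUU", bulges = list(
    list(arm = "star", offset = 3, size = -1))), "size")
})

test_that("plant_loci places precursors and clustered pairs exactly", {
  set.seed(21)
  g <- rand_dna(6000)
  hp1 <- build_hairpin(chartr("T", "U", rand_dna(22)))
  hp2 <- build_hairpin(chartr("T", "U", rand_dna(22)))
  hp3 <- build_hairpin(chartr("T", "U", rand_dna(22)))
  loci <- data.frame(
    id = c("a", "b", "c"),
    seq = c(hp1$precursor, hp2$precursor, hp3$precursor),
    strand = c("+", "+", "-"),
    pos = c(NA, NA, NA),
    cluster = c("cl1", "cl1", NA),
    cluster_gap = c(NA, 73L, NA),
    stringsAsFactors = FALSE)
  res <- plant_loci(g, loci)
  tr <- res$truth
  # intra-cluster gap is exact
  expect_equal(tr$start[tr$id == "b"] - tr$end[tr$id == "a"], 73L)
  # plus-strand substring equals precursor (DNA)
  expect_equal(substr(res$genome, tr$start[1] + 1, tr$end[1]),
               chartr("U", "T", hp1$precursor))
  # minus-strand substring equals reverse complement
  expect_equal(substr(res$genome, tr$start[3] + 1, tr$end[3]),
               oracle_revcomp(chartr("U", "T", hp3$precursor)))
  # zero loci: genome unchanged, empty truth
  res0 <- plant_loci(g, loci[0, , drop = FALSE])
  expect_equal(res0$genome, g)
  expect_equal(nrow(res0$truth), 0)
  # overflow names the locus
  expect_error(plant_loci(rand_dna(40), loci), "locus")
})

test_that("simulation is reproducible and reads trace back to planted arms", {
  cfg <- sim_config(genome_length = 30000, n_loci = 6, n_clustered_pairs = 1,
                    n_biased_loci = 2, rng_seed = 33,
                    libraries = data.frame(
                      name = c("m1", "f1"), condition = c("male", "female"),
                      depth = 2e4, stringsAsFactors = FALSE))
  sim1 <- simulate_genome(cfg)
  sim2 <- simulate_genome(cfg)
  expect_identical(sim1$genome, sim2$genome)
  expect_identical(sim1$truth, sim2$truth)
  r1 <- simulate_reads(sim1)
  r2 <- simulate_reads(sim2)
  expect_identical(r1$libraries, r2$libraries)

  # every planted locus appears exactly once; intervals inside the genome
  expect_equal(anyDuplicated(sim1$truth$id), 0)
  expect_true(all(sim1$truth$start >= 0 & sim1$truth$end <= nchar(sim1$genome)))

  # every non-decoy read is a substring of its locus's genomic region
  lib <- r1$libraries$f1
  planted <- lib[lib$origin %in% c("mature", "star"), ]
  ok <- vapply(seq_len(nrow(planted)), function(i) {
    tr <- sim1$truth[sim1$truth$id == planted$locus[i], ]
    region <- substr(sim1$genome, tr$start + 1 - 2, tr$end + 2)
    grepl(planted$sequence[i], region, fixed = TRUE) ||
      grepl(oracle_revcomp(planted$sequence[i]), region, fixed = TRUE)
  }, logical(1))
  expect_true(all(ok))
})

test_that("read-length mode and arm-bias of simulated reads match the configuration", {
  # decoy reads draw their lengths from the same configured distribution,
  # so the pooled read pile carries the configured 22-nt mode
  cfg <- sim_config(genome_length = 50000, n_loci = 12, n_clustered_pairs = 0,
                    n_biased_loci = 0, decoy_fraction = 0.3, rng_seed = 5,
                    cpm_meanlog = log(2000), cpm_sdlog = 0.3,
                    libraries = data.frame(
                      name = c("m1", "f1"), condition = c("male", "female"),
                      depth = 5e4, stringsAsFactors = FALSE))
  sim <- simulate_genome(cfg)
  reads <- simulate_reads(sim)
  all_reads <- do.call(rbind, reads$libraries)
  expect_gt(nrow(all_reads), 10000)
  lens <- table(nchar(all_reads$sequence))
  expect_equal(as.integer(names(lens)[which.max(lens)]), 22L)

  # per-locus arm bias recovered within 3 binomial SDs
  for (l in sim$truth$id) {
    n_m <- sum(all_reads$locus == l & all_reads$origin == "mature", na.rm = TRUE)
    n_s <- sum(all_reads$locus == l & all_reads$origin == "star", na.rm = TRUE)
    n <- n_m + n_s
    if (n < 50) next
    sd3 <- 3 * sqrt(0.8 * 0.2 / n)
    expect_lt(abs(n_m / n - 0.8), sd3 + 1e-9)
  }
})

test_that("star/mature ratio follows star_fraction at depth", {
  cfg <- sim_config(genome_length = 30000, n_loci = 5, n_clustered_pairs = 0,
                    n_biased_loci = 0, decoy_fraction = 0,
                    star_fraction = 0.1, cpm_meanlog = log(1000),
                    cpm_sdlog = 0.2, rng_seed = 11,
                    libraries = data.frame(
                      name = "lib1", condition = "female", depth = 1e5,
                      stringsAsFactors = FALSE))
  sim <- simulate_genome(cfg)
  reads <- simulate_reads(sim)
  lib <- reads$libraries$lib1
  n_m <- sum(lib$origin == "mature")
  n_s <- sum(lib$origin == "star")
  ratio <- n_s / n_m
  p_star <- 0.1 / 1.1
  n <- n_m + n_s
  sd3 <- 3 * sqrt(p_star * (1 - p_star) / n)
  expect_lt(abs(n_s / n - p_star), sd3)
  expect_gt(ratio, 0.05)
})

test_that("planted fold change shows up in condition means", {
  cfg <- sim_config(genome_length = 50000, n_loci = 10, n_clustered_pairs = 0,
                    n_biased_loci = 10, biased_lfc = 2, decoy_fraction = 0,
                    cpm_meanlog = log(500), cpm_sdlog = 0.3, rng_seed = 19)
  sim <- simulate_genome(cfg)
  reads <- simulate_reads(sim)
  libs <- cfg$libraries
  up <- sim$truth$id[sim$truth$lfc > 0]
  for (l in up) {
    cf <- sum(vapply(libs$name[libs$condition == "female"], function(nm)
      sum(reads$libraries[[nm]]$locus == l, na.rm = TRUE), numeric(1)))
    cm <- sum(vapply(libs$name[libs$condition == "male"], function(nm)
      sum(reads$libraries[[nm]]$locus == l, na.rm = TRUE), numeric(1)))
    # planted lfc = +2: female/male ratio about 4 within sampling error
    expect_gt(cf / cm, 2)
    expect_lt(cf / cm, 8)
  }
})

test_that("sim_config rejects invalid settings", {
  expect_error(sim_config(arm_bias = 0.4), "arm_bias")
  expect_error(sim_config(five_prime_jitter = c(`0` = 0.5, `1` = 0.4)),
               "sum to 1")
  expect_error(sim_config(genome_length = 2000, n_loci = 50), "too small")
  expect_error(sim_config(libraries = data.frame(
    name = "x", condition = "female", depth = -1)), "depth")
})

test_that("written simulation files are complete and well-formed", {
  cfg <- sim_config(genome_length = 20000, n_loci = 4, n_clustered_pairs = 1,
                    n_biased_loci = 0, rng_seed = 3,
                    libraries = data.frame(
                      name = c("m1", "f1"), condition = c("male", "female"),
                      depth = 5e3, stringsAsFactors = FALSE))
  sim <- simulate_genome(cfg)
  reads <- simulate_reads(sim)
  dir <- tempfile("simout")
  write_simulation(sim, reads, dir)
  expect_true(file.exists(file.path(dir, "genome.fa")))
  expect_true(file.exists(file.path(dir, "m1.fastq")))
  expect_true(file.exists(file.path(dir, "loci.gff3")))
  # GFF3 round-trip recovers the planted intervals (1-based shift)
  gr <- rtracklayer::import(file.path(dir, "loci.gff3"))
  back <- granges_to_intervals(gr)
  back <- back[order(back$start), ]
  tr <- sim$truth[order(sim$truth$start), ]
  expect_equal(back$start, tr$start)
  expect_equal(back$end, tr$end)
  # FASTQ re-reads to the same sequences
  rr <- read_reads(file.path(dir, "f1.fastq"))
  expect_equal(sort(unname(rr)), sort(reads$libraries$f1$sequence))
  unlink(dir, recursive = TRUE)
})
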
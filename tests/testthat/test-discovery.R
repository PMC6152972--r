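## Hand-built read sets over hand-planted hairpins (helper-fixtures.R)
## give exact control over read evidence at the acceptance thresholds.

test_that("a well-supported clean hairpin is accepted with correct anatomy", {
  fx <- make_locus_fixture(n_mature = 50, n_star = 5)
  called <- call_loci(fx$tags, genome_index(c(chr1 = fx$genome)))
  acc <- accepted_loci(called)
  expect_equal(nrow(acc), 1)
  expect_equal(acc$mature_total, 50)
  expect_equal(acc$star_total, 5)
  expect_equal(acc$mature_arm, "5p")
  expect_equal(acc$mature_seq, fx$hp$mature_seq)
  # precursor window covers the planted locus
  expect_lte(acc$start, fx$truth$start)
  expect_gte(acc$end, fx$truth$end)
})

test_that("read-evidence boundaries reject with the right reason codes", {
  # 9 mature reads: one below the threshold of 10
  fx9 <- make_locus_fixture(n_mature = 9, n_star = 3)
  c9 <- call_loci(fx9$tags, genome_index(c(chr1 = fx9$genome)))
  r9 <- c9$loci[c9$loci$start <= fx9$truth$start &
                  c9$loci$end >= fx9$truth$end, ]
  expect_true(any(r9$status == "rejected" & r9$reason == "low_mature"))
  expect_equal(nrow(accepted_loci(c9)), 0)

  # 10 mature reads, no star read
  fx0 <- make_locus_fixture(n_mature = 10, n_star = 0)
  c0 <- call_loci(fx0$tags, genome_index(c(chr1 = fx0$genome)))
  r0 <- c0$loci[c0$loci$start <= fx0$truth$start &
                  c0$loci$end >= fx0$truth$end, ]
  expect_true(any(r0$status == "rejected" & r0$reason == "no_star"))
  expect_equal(nrow(accepted_loci(c0)), 0)

  # exactly 10 mature + 1 star passes
  fx10 <- make_locus_fixture(n_mature = 10, n_star = 1)
  c10 <- call_loci(fx10$tags, genome_index(c(chr1 = fx10$genome)))
  expect_equal(nrow(accepted_loci(c10)), 1)
})

test_that("duplex-geometry boundaries follow the space/bulge limits exactly", {
  m <- "UAUAUUAUAUUAUAUUAUAUUA"   # G-free so planted C bulges stay unpaired
  # space: loop length is the space between the arms
  for (cs in list(c(35, TRUE), c(36, FALSE))) {
    fx <- make_locus_fixture(mature = m, loop_len = cs[1],
                             n_mature = 40, n_star = 4)
    called <- call_loci(fx$tags, genome_index(c(chr1 = fx$genome)))
    acc <- accepted_loci(called)
    if (cs[2]) {
      expect_equal(nrow(acc), 1)
      expect_equal(acc$space, cs[1])
    } else {
      row <- called$loci[called$loci$start <= fx$truth$start &
                           called$loci$end >= fx$truth$end, ]
      expect_true(any(row$reason == "space_exceeded"))
    }
  }
  for (cs in list(c(5, TRUE), c(6, FALSE))) {
    fx <- make_locus_fixture(mature = m, loop_len = 10,
                             bulges = list(list(arm = "star", offset = 10,
                                                size = cs[1])),
                             n_mature = 40, n_star = 4)
    called <- call_loci(fx$tags, genome_index(c(chr1 = fx$genome)))
    acc <- accepted_loci(called)
    if (cs[2]) {
      expect_equal(nrow(acc), 1)
      expect_equal(acc$max_bulge, cs[1])
    } else {
      row <- called$loci[called$loci$start <= fx$truth$start &
                           called$loci$end >= fx$truth$end, ]
      expect_true(any(row$reason == "bulge_exceeded"))
    }
  }
})

test_that("raising min_mature_reads never grows the accepted set", {
  set.seed(6)
  cfg <- sim_config(genome_length = 40000, n_loci = 8, n_clustered_pairs = 0,
                    n_biased_loci = 0, decoy_fraction = 0.02, rng_seed = 6,
                    libraries = data.frame(
                      name = c("m1", "f1"), condition = c("male", "female"),
                      depth = 3e4, stringsAsFactors = FALSE))
  sim <- simulate_genome(cfg)
  reads <- simulate_reads(sim)
  pp <- preprocess_reads(lapply(reads$libraries, `[[`, "sequence"))
  idx <- genome_index(c(chr1 = sim$genome))
  prev <- Inf
  for (mm in c(5, 10, 20, 50)) {
    acc <- accepted_loci(call_loci(pp$clean, idx,
                                   params = list(min_mature_reads = mm)))
    expect_lte(nrow(acc), prev)
    prev <- nrow(acc)
  }
})

test_that("locus calling is deterministic and handles empty input", {
  fx <- make_locus_fixture()
  idx <- genome_index(c(chr1 = fx$genome))
  c1 <- call_loci(fx$tags, idx)
  c2 <- call_loci(fx$tags, idx)
  expect_identical(c1$loci, c2$loci)
  c0 <- call_loci(fx$tags[0, , drop = FALSE], idx)
  expect_equal(nrow(c0$loci), 0)
})

test_that("repetitive tags (many genomic hits) do not seed loci", {
  set.seed(77)
  unit <- rand_dna(60)
  g <- paste0(rand_dna(300), paste(rep(unit, 8), collapse = ""), rand_dna(300))
  tag <- substr(unit, 10, 31)   # maps 8 times
  tags <- collapse_tags(list(l = rep(tag, 50)))
  called <- call_loci(tags, genome_index(c(chr1 = g)))
  expect_equal(nrow(called$loci), 0)
})

test_that("length spectrum and first-nucleotide bias summarise accepted loci", {
  loci <- data.frame(
    status = "accepted",
    mature_seq = c("UGAGGUAGUAGGUUGUAUAGUU",    # 22 nt, U
                   "UGAGGUAGUAGGUUGUAUAGU",     # 21 nt, U
                   "AGAGGUAGUAGGUUGUAUAGUU",    # 22 nt, A
                   "UGAGGUAGUAGGUUGUAUAGUUA"),  # 23 nt, U
    stringsAsFactors = FALSE)
  sp <- length_spectrum(loci)
  expect_equal(sp$mode, 22L)
  expect_equal(sum(sp$lengths), 1)
  expect_equal(unname(sp$lengths["22"]), 0.5)

  bias <- first_nt_bias(loci)
  expect_equal(sum(bias), 1)
  expect_equal(unname(bias["U"]), 0.75)
  expect_equal(unname(bias["A"]), 0.25)

  empty <- length_spectrum(loci[0, , drop = FALSE])
  expect_true(is.na(empty$mode))
  expect_equal(sum(first_nt_bias(loci[0, , drop = FALSE])), 0)
})
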
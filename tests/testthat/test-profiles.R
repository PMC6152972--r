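test_that("arm usage calls dominance at the configured ratio", {
  u <- arm_usage(100, 10)
  expect_equal(u$dominant, "5p")
  expect_equal(u$fraction_5p, 100 / 110, tolerance = 1e-9)

  expect_equal(arm_usage(55, 45)$dominant, "codominant")  # ratio 1.22 < 2
  expect_equal(arm_usage(10, 100)$dominant, "3p")
  expect_equal(arm_usage(55, 45, ratio = 1.2)$dominant, "5p")
  expect_error(arm_usage(0, 0), "at least one read")

  # invariance under uniform scaling
  u10 <- arm_usage(1000, 100)
  expect_equal(u10$fraction_5p, u$fraction_5p)
  expect_equal(u10$dominant, u$dominant)
})

test_that("arm switching is detected symmetrically", {
  a5 <- arm_usage(100, 10, id = "mir-281")
  b3 <- arm_usage(8, 90, id = "mir-281")
  co <- arm_usage(50, 45, id = "mir-281")
  expect_equal(detect_arm_switch(a5, b3), "switch")
  expect_equal(detect_arm_switch(b3, a5), "switch")
  expect_equal(detect_arm_switch(a5, a5), "stable")
  expect_equal(detect_arm_switch(a5, co), "indeterminate")
  expect_error(detect_arm_switch(a5, arm_usage(1, 10, id = "mir-9")),
               "different families")
})

test_that("planted arm bias is recovered within 3 binomial SDs across loci", {
  cfg <- sim_config(genome_length = 60000, n_loci = 15, n_clustered_pairs = 0,
                    n_biased_loci = 0, decoy_fraction = 0, arm_bias = 0.8,
                    cpm_meanlog = log(500), cpm_sdlog = 0.3, rng_seed = 23,
                    libraries = data.frame(
                      name = c("m1", "f1"), condition = c("male", "female"),
                      depth = 5e4, stringsAsFactors = FALSE))
  sim <- simulate_genome(cfg)
  reads <- simulate_reads(sim)
  pp <- preprocess_reads(lapply(reads$libraries, `[[`, "sequence"))
  called <- call_loci(pp$clean, genome_index(c(chr1 = sim$genome)))
  acc <- accepted_loci(called)
  expect_gte(nrow(acc), 12)
  for (i in seq_len(nrow(acc))) {
    u <- arm_usage(acc[i, , drop = FALSE])
    n <- u$reads_5p + u$reads_3p
    frac_mature <- max(u$reads_5p, u$reads_3p) / n
    expect_lt(abs(frac_mature - 0.8), 3 * sqrt(0.8 * 0.2 / n) + 1e-9)
  }
})

test_that("isomiR fidelity summarises 5' offset spectra", {
  expect_equal(isomir_profile(c(`0` = 40))$fidelity, 1)
  expect_equal(isomir_profile(c(`0` = 20, `1` = 20))$fidelity, 0.5)
  p <- isomir_profile(c(`-1` = 5, `0` = 80, `1` = 10, `2` = 5))
  expect_equal(p$fidelity, 0.8)
  expect_equal(p$secondary_offsets[1], 1L)
  # offsets outside the window are not isomiRs
  p2 <- isomir_profile(c(`0` = 10, `5` = 100))
  expect_equal(p2$fidelity, 1)
  expect_error(isomir_profile(c(`0` = 0)), "no reads")
})

test_that("fidelity is invariant under relabeling offsets by a constant", {
  x <- c(`-1` = 5, `0` = 80, `1` = 15)
  y <- c(`0` = 5, `1` = 80, `2` = 15)   # same spectrum shifted by +1
  expect_equal(isomir_profile(x)$fidelity, isomir_profile(y)$fidelity)
})

test_that("planted jitter mass is recovered in locus offset spectra", {
  cfg <- sim_config(genome_length = 60000, n_loci = 15, n_clustered_pairs = 0,
                    n_biased_loci = 0, decoy_fraction = 0,
                    five_prime_jitter = c(`-2` = 0.02, `-1` = 0.08, `0` = 0.8,
                                          `1` = 0.08, `2` = 0.02),
                    cpm_meanlog = log(3000), cpm_sdlog = 0.3, rng_seed = 29,
                    libraries = data.frame(
                      name = c("m1", "f1"), condition = c("male", "female"),
                      depth = 5e4, stringsAsFactors = FALSE))
  sim <- simulate_genome(cfg)
  reads <- simulate_reads(sim)
  pp <- preprocess_reads(lapply(reads$libraries, `[[`, "sequence"))
  idx <- genome_index(c(chr1 = sim$genome))
  called <- call_loci(pp$clean, idx)
  acc <- accepted_loci(called)
  hits <- map_exact(pp$clean$sequence, idx)
  hits$total <- pp$clean$total[hits$read]
  checked <- 0
  for (i in seq_len(nrow(acc))) {
    spec <- locus_offset_spectra(acc[i, , drop = FALSE], hits)
    n <- sum(spec$mature)
    if (n < 60) next
    fid <- isomir_profile(spec$mature)$fidelity
    expect_lt(abs(fid - 0.8), 3 * sqrt(0.8 * 0.2 / n) + 0.02)
    checked <- checked + 1
  }
  expect_gte(checked, 8)
})

test_that("fidelity contrast separates mature from star under planted jitter gap", {
  set.seed(31)
  n_loci <- 50
  # depth-limited multinomial draws from the planted jitter spectra
  m_f <- vapply(1:n_loci, function(i) {
    x <- as.vector(stats::rmultinom(1, 200, c(0.025, 0.05, 0.85, 0.05, 0.025)))
    max(x) / sum(x)
  }, numeric(1))
  s_f <- vapply(1:n_loci, function(i) {
    x <- as.vector(stats::rmultinom(1, 60, c(0.1, 0.15, 0.5, 0.15, 0.1)))
    max(x) / sum(x)
  }, numeric(1))
  res <- fidelity_contrast(m_f, s_f)
  expect_lt(res$p_value, 0.01)
  expect_equal(nrow(res$table), n_loci)

  # identical spectra: no signal (p stays away from tiny values)
  s_same <- vapply(1:n_loci, function(i) {
    x <- as.vector(stats::rmultinom(1, 200, c(0.025, 0.05, 0.85, 0.05, 0.025)))
    max(x) / sum(x)
  }, numeric(1))
  m_same <- vapply(1:n_loci, function(i) {
    x <- as.vector(stats::rmultinom(1, 200, c(0.025, 0.05, 0.85, 0.05, 0.025)))
    max(x) / sum(x)
  }, numeric(1))
  expect_gt(fidelity_contrast(m_same, s_same)$p_value, 0.01)

  # single locus: no power, table still emitted
  one <- fidelity_contrast(0.9, 0.5)
  expect_equal(one$p_value, 1)
  expect_equal(nrow(one$table), 1)
  # all ties
  expect_equal(fidelity_contrast(c(0.8, 0.9), c(0.8, 0.9))$p_value, 1)
})
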
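test_that("seed matching finds exact WC complements and rejects wobble", {
  mir <- "UGAGGUAGUAGGUUGUAUAGUU"   # seed GAGGUAG
  site <- "CUACCUC"                  # exact WC reverse complement of seed
  utr <- paste0("AAAA", site, "AAAA")
  expect_equal(seed_match(mir, utr), 4L)

  # one G:U wobble: seed G could wobble-pair U, but that is forbidden
  utr_wobble <- paste0("AAAA", "CUACCUU", "AAAA")
  expect_equal(length(seed_match(mir, utr_wobble)), 0)

  # planted 3x, overlapping scan oracle by construction
  utr3 <- paste0("GG", site, "CC", site, "AA", site)
  expect_equal(seed_match(mir, utr3), c(2L, 11L, 20L))

  expect_equal(length(seed_match(mir, "ACG")), 0)
})

test_that("duplex energy is strong for GC duplexes, weak for short AU, zero when unpairable", {
  gc_mir <- "GCGCGGCGCGGCGCGGCGCGGC"
  ctx <- as.character(Biostrings::reverseComplement(
    Biostrings::RNAString(gc_mir)))
  dg <- duplex_energy(gc_mir, ctx)
  # 21 stacks of GC-rich pairs: far below the -20 kcal/mol threshold
  expect_lt(dg, -40)

  au_mir <- "AUAUAUAU"
  au_ctx <- as.character(Biostrings::reverseComplement(
    Biostrings::RNAString(au_mir)))
  dg_au <- duplex_energy(au_mir, au_ctx)
  expect_lt(dg_au, 0)
  expect_gt(dg_au, -20)   # 7 AU stacks cannot reach the threshold

  # poly-A against poly-C: no pair possible
  expect_equal(duplex_energy("AAAAAAAAAAAAAAAAAAAA", "CCCCCCCCCCCCCCCCCCCC"), 0)
})

test_that("duplex energy is monotone under extending the complementary core", {
  set.seed(5)
  mir <- "GCUAGCUAGGCAUCGAUGCUAG"
  full_ctx <- as.character(Biostrings::reverseComplement(Biostrings::RNAString(mir)))
  dgs <- vapply(8:22, function(k) {
    # context complementary to only the first k miRNA bases
    ctx <- substr(full_ctx, 23 - k, 22)
    duplex_energy(substr(mir, 1, k), ctx)
  }, numeric(1))
  expect_true(all(diff(dgs) <= 1e-9))
})

test_that("consensus requires both seed and energy criteria", {
  pairs <- data.frame(
    mirna = c("m1", "m1", "m2"), gene = c("g1", "g2", "g1"),
    pos = c(5L, 9L, 2L),
    seed = c(TRUE, TRUE, TRUE), energy = c(TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  res <- consensus_targets(pairs)
  expect_equal(nrow(res$targets), 2)
  expect_false(any(res$targets$gene == "g2" & res$targets$mirna == "m1"))
  # invariant to input order
  res2 <- consensus_targets(pairs[c(3, 1, 2), ])
  expect_equal(res$targets, res2$targets)
  expect_equal(res$mean_targets_per_mirna, 1)
})

test_that("planted full-complement sites are recovered as consensus targets", {
  set.seed(9)
  mirnas <- c(mirA = chartr("T", "U", rand_dna(22)),
              mirB = chartr("T", "U", rand_dna(22)))
  tx <- simulate_transcriptome(mirnas, n_genes = 20, utr_len = 300,
                               sites_per_mirna = 3, seed = 4)
  pred <- predict_targets(mirnas, tx$utrs)
  cons <- consensus_targets(pred)$targets
  found <- mapply(function(m, g) any(cons$mirna == m & cons$gene == g),
                  tx$truth$mirna, tx$truth$gene)
  expect_gte(mean(found), 0.9)
})

test_that("BH adjustment matches the step-up formula", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_fdr(p), oracle_bh(p))
  }
})

test_that("Fisher enrichment equals the hypergeometric tail", {
  # balanced table: no enrichment; one-sided p equals the central tail
  tm <- data.frame(gene = paste0("g", 1:20),
                   term = rep(c("T", "other"), each = 10),
                   stringsAsFactors = FALSE)
  set_bal <- c(paste0("g", 1:5), paste0("g", 11:15))   # (5,5,5,5)
  res <- fisher_enrichment(set_bal, tm$gene, tm)
  expect_equal(res$p_value[res$term == "T"], oracle_hyper_tail(5, 5, 5, 5),
               tolerance = 1e-9)
  expect_gt(res$p_value[res$term == "T"], 0.5)

  # (8,2,2,8) against enumeration
  tm2 <- data.frame(gene = paste0("g", 1:20),
                    term = rep(c("T", "other"), each = 10),
                    stringsAsFactors = FALSE)
  set2 <- c(paste0("g", 1:8), paste0("g", 11:12))
  res2 <- fisher_enrichment(set2, tm2$gene, tm2)
  expect_equal(res2$p_value[res2$term == "T"], oracle_hyper_tail(8, 2, 2, 8),
               tolerance = 1e-9)

  # random small tables vs enumeration
  set.seed(13)
  for (i in 1:15) {
    n_with <- sample(3:15, 1); n_wo <- sample(3:15, 1)
    genes <- paste0("g", seq_len(n_with + n_wo))
    tm3 <- data.frame(gene = genes,
                      term = rep(c("T", "Z"), c(n_with, n_wo)),
                      stringsAsFactors = FALSE)
    gs <- sample(genes, sample(2:(n_with + n_wo - 1), 1))
    res3 <- fisher_enrichment(gs, genes, tm3)
    a <- sum(gs %in% genes[seq_len(n_with)])
    expect_equal(res3$p_value[res3$term == "T"],
                 oracle_hyper_tail(a, length(gs) - a, n_with - a,
                                   n_wo - (length(gs) - a)),
                 tolerance = 1e-9)
  }

  expect_error(fisher_enrichment("x", paste0("g", 1:3), tm), "subset")
})

test_that("the exact binomial DE test behaves at fixtures", {
  counts <- matrix(c(50L, 50L, 50L, 50L), 1,
                   dimnames = list("mirX", c("f1", "f2", "m1", "m2")))
  res <- de_test(counts, c("female", "female", "male", "male"),
                 depths = rep(1e5, 4))
  expect_equal(res$p_value, 1)
  expect_equal(res$biased, "none")

  # strongly female-shifted counts
  counts2 <- matrix(c(400L, 400L, 100L, 100L), 1,
                    dimnames = list("mirY", c("f1", "f2", "m1", "m2")))
  res2 <- de_test(counts2, c("female", "female", "male", "male"),
                  depths = rep(1e5, 4))
  expect_lt(res2$p_value, 1e-6)
  expect_equal(res2$biased, "female")
  expect_gt(res2$log2fc, 1.5)

  expect_error(de_test(counts2, rep("female", 4)), "per condition")
})

test_that("ddCt fold change follows the closed form", {
  expect_equal(ddct_fold_change(20, 15, 20, 15), 1)
  expect_equal(ddct_fold_change(19, 15, 20, 15), 2)   # ddCt = -1
  expect_equal(ddct_fold_change(22, 15, 20, 15), 0.25) # ddCt = +2
  expect_equal(ddct_fold_change(20, 15, 22, 15), 4)
})
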
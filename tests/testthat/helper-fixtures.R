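## Shared fixture builders: hand-planted hairpins with exact control
## over read evidence, used by discovery, comparative and acceptance
## tests.

make_locus_fixture <- function(seed = 101, n_mature = 50, n_star = 5,
                               mature = NULL, loop_len = 10,
                               bulges = list(), genome_len = 3000) {
  set.seed(seed)
  if (is.null(mature)) mature <- chartr("T", "U", paste0("T", rand_dna(21)))
  hp <- build_hairpin(mature, loop_len = loop_len, bulges = bulges)
  g <- rand_dna(genome_len)
  res <- plant_loci(g, data.frame(
    id = "hp1", seq = hp$precursor, strand = "+", pos = 1000L,
    stringsAsFactors = FALSE))
  mature_read <- chartr("U", "T", hp$mature_seq)
  star_read <- chartr("U", "T", hp$star_seq)
  reads <- c(rep(mature_read, n_mature), rep(star_read, n_star))
  list(genome = res$genome, truth = res$truth, hp = hp,
       tags = collapse_tags(list(lib = reads)))
}

comp_fixture <- function(seed = 55, n = 6, genome_len = 20000) {
  set.seed(seed)
  matures <- vapply(seq_len(n), function(i)
    chartr("T", "U", paste0("T", rand_dna(21))), character(1))
  hps <- lapply(matures, build_hairpin, loop_len = 10)
  res <- plant_loci(rand_dna(genome_len), data.frame(
    id = sprintf("mir%02d", seq_len(n)),
    seq = vapply(hps, `[[`, character(1), "precursor"),
    strand = rep(c("+", "-"), length.out = n),
    stringsAsFactors = FALSE))
  list(genome = res$genome, truth = res$truth, matures = matures, hps = hps)
}
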
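## Independent oracles used across the suite. These deliberately use
## different algorithms from the implementation they check.

## exhaustive maximum weighted-pair score over all nested structures
## (plain recursion, no memoisation) — oracle for fold()
oracle_fold_score <- function(seq, min_loop = 3,
                              weights = c(GC = 3, AU = 2, GU = 1)) {
  b <- strsplit(toupper(seq), "")[[1]]
  w <- function(x, y) {
    if ((x == "G" && y == "C") || (x == "C" && y == "G")) return(weights[["GC"]])
    if ((x == "A" && y == "U") || (x == "U" && y == "A")) return(weights[["AU"]])
    if ((x == "G" && y == "U") || (x == "U" && y == "G")) return(weights[["GU"]])
    0
  }
  rec <- function(i, j) {
    if (j - i <= min_loop) return(0)
    best <- rec(i + 1, j)                   # i unpaired
    for (k in (i + min_loop + 1):j) {
      wk <- w(b[i], b[k])
      if (wk == 0) next
      inner <- if (k - i >= 2) rec(i + 1, k - 1) else 0
      rest <- if (k < j) rec(k + 1, j) else 0
      best <- max(best, wk + inner + rest)
    }
    best
  }
  if (length(b) < 2) 0 else rec(1, length(b))
}

## naive full-scan exact mapper — oracle for map_exact()
oracle_map_scan <- function(read, genome_name, genome) {
  w <- nchar(read)
  n <- nchar(genome)
  if (w > n || grepl("[^ACGT]", read)) {
    return(data.frame(seqname = character(0), start = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  subs <- substring(genome, 1:(n - w + 1), w:n)
  fwd <- which(subs == read) - 1L
  rev <- which(subs == oracle_revcomp(read)) - 1L
  out <- rbind(
    if (length(fwd)) data.frame(seqname = genome_name, start = fwd,
                                strand = "+", stringsAsFactors = FALSE),
    if (length(rev)) data.frame(seqname = genome_name, start = rev,
                                strand = "-", stringsAsFactors = FALSE))
  if (is.null(out))
    out <- data.frame(seqname = character(0), start = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  out[order(out$start, out$strand), , drop = FALSE]
}

## reverse complement written without Biostrings
oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

## Benjamini-Hochberg step-up written from the definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

## hypergeometric upper-tail P(X >= a) by direct enumeration with choose()
oracle_hyper_tail <- function(a, b, c_, d) {
  n_set <- a + b
  n_with <- a + c_
  N <- a + b + c_ + d
  ks <- max(0, n_set + n_with - N):min(n_set, n_with)
  pk <- choose(n_with, ks) * choose(N - n_with, n_set - ks) / choose(N, n_set)
  sum(pk[ks >= a])
}

## random DNA convenience for tests
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
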
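## Target prediction (seed + hybridisation energy, two-criterion
## consensus), differential expression by exact binomial test on
## condition-pooled depth-normalised counts, Fisher-exact term
## enrichment, and the 2^-ddCt qPCR fold change.

#' Seed-match sites of a miRNA in a UTR
#'
#' The seed is miRNA positions 2..(1+seed_len). A site is every UTR
#' position whose sequence is the exact Watson-Crick reverse complement
#' of the seed — no mismatches and no G:U pairs, by construction.
#' Overlapping sites are all reported.
#'
#' @param mirna mature miRNA sequence (RNA or DNA).
#' @param utr UTR sequence (RNA or DNA).
#' @param seed_len 7 or 8.
#' @return integer vector of 0-based site start positions in the UTR
#'   (empty when the UTR is shorter than the seed).
#' @export
seed_match <- function(mirna, utr, seed_len = 7L) {
  seed <- seed_of(mirna, seed_len)
  site <- rc_dna(rna2dna(seed))
  utr_dna <- rna2dna(utr)
  if (nchar(utr_dna) < nchar(site)) return(integer(0))
  m <- Biostrings::matchPattern(site, Biostrings::DNAString(utr_dna))
  Biostrings::start(m) - 1L
}

## Nearest-neighbour Watson-Crick stack free energies (kcal/mol, 37 C),
## keyed by the 5'->3' top-strand dinucleotide; the bottom strand is its
## complement. Duplex initiation +4.09; +0.45 per terminal A:U pair.
NN_STACK <- c(AA = -0.93, UU = -0.93, AU = -1.10, UA = -1.33,
              CU = -2.08, AG = -2.08, CA = -2.11, UG = -2.11,
              GU = -2.24, AC = -2.24, GA = -2.35, UC = -2.35,
              CG = -2.36, GG = -3.26, CC = -3.26, GC = -3.42)
NN_INIT <- 4.09
NN_AU_END <- 0.45

#' Hybridisation free energy of a miRNA against a target site
#'
#' Scores the best ungapped duplex core between the miRNA and the
#' target context: over all antiparallel offsets, the contiguous run of
#' Watson-Crick pairs minimising the summed nearest-neighbour stack
#' energies, plus duplex initiation and terminal A:U penalties. G:U
#' wobbles are treated as unpaired (consistent with the seed
#' criterion). Returns 0 when no pairable region exists or the best
#' duplex is not stabilising — a non-site.
#'
#' @param mirna mature miRNA sequence (RNA or DNA).
#' @param context target-site context sequence (RNA or DNA), e.g. the
#'   site plus flanking UTR sequence.
#' @return free energy change in kcal/mol (<= 0).
#' @export
duplex_energy <- function(mirna, context) {
  m <- strsplit(dna2rna(mirna), "")[[1]]
  t_rev <- rev(strsplit(dna2rna(context), "")[[1]])
  nm <- length(m); nt <- length(t_rev)
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  best <- 0
  for (off in (-(nm - 1)):(nt - 1)) {
    i <- max(1, 1 - off):min(nm, nt - off)
    if (length(i) < 2) next
    paired <- comp[m[i]] == t_rev[i + off]
    if (!any(paired)) next
    ## best contiguous run: scan runs of consecutive paired positions
    r <- rle(paired)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (run in which(r$values & r$lengths >= 2)) {
      ii <- i[starts[run]:ends[run]]
      stacks <- NN_STACK[paste0(m[ii[-length(ii)]], m[ii[-1]])]
      dg <- sum(stacks) + NN_INIT +
        NN_AU_END * ((m[ii[1]] %in% c("A", "U")) +
                     (m[ii[length(ii)]] %in% c("A", "U")))
      if (dg < best) best <- dg
    }
  }
  best
}

#' Predict miRNA targets by seed and energy criteria
#'
#' For every miRNA x UTR pair, seed-match sites are located and the
#' hybridisation energy of each site's context (site plus the
#' mirna-length upstream flank) computed. A site passes `seed` always
#' (it was found by seed matching) and `energy` when its free energy is
#' at most `dg_cutoff`. Consensus requires both criteria.
#'
#' @param mirnas named character vector of mature miRNA sequences.
#' @param utrs named character vector of UTR sequences.
#' @param seed_len 7 or 8.
#' @param dg_cutoff energy threshold in kcal/mol (default -20).
#' @return data.frame `mirna`, `gene`, `pos` (0-based site start),
#'   `duplex_dG`, `seed`, `energy`, `consensus`.
#' @export
predict_targets <- function(mirnas, utrs, seed_len = 7L, dg_cutoff = -20) {
  out <- list()
  for (m in names(mirnas)) {
    for (g in names(utrs)) {
      pos <- seed_match(mirnas[[m]], utrs[[g]], seed_len)
      for (p0 in pos) {
        ## context: the site plus enough upstream UTR to pair the whole miRNA
        ctx_start <- max(0L, p0 + seed_len - nchar(mirnas[[m]]) - 3L)
        ctx_end <- min(nchar(utrs[[g]]), p0 + seed_len + 3L)
        ctx <- substr(utrs[[g]], ctx_start + 1, ctx_end)
        dg <- duplex_energy(mirnas[[m]], ctx)
        out[[length(out) + 1]] <- data.frame(
          mirna = m, gene = g, pos = p0, duplex_dG = dg,
          seed = TRUE, energy = dg <= dg_cutoff,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(mirna = character(0), gene = character(0),
                      pos = integer(0), duplex_dG = numeric(0),
                      seed = logical(0), energy = logical(0),
                      consensus = logical(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res$consensus <- res$seed & res$energy
  res
}

#' Consensus filter and per-miRNA target census
#'
#' Retains target pairs supported by at least two criteria and reports
#' the mean number of consensus target genes per miRNA. Output is
#' invariant to input row order.
#'
#' @param pairs data.frame from [predict_targets()] (or any frame with
#'   `mirna`, `gene` and logical criterion columns `seed`, `energy`).
#' @return list with `targets` (consensus rows, sorted), `n_criteria`
#'   per row of `targets`, and `mean_targets_per_mirna` (mean count of
#'   distinct consensus genes over miRNAs present in `pairs`).
#' @export
consensus_targets <- function(pairs) {
  crit <- intersect(c("seed", "energy"), names(pairs))
  n_crit <- rowSums(as.matrix(pairs[, crit, drop = FALSE]))
  pairs$consensus <- n_crit >= 2
  keep <- pairs[pairs$consensus, , drop = FALSE]
  keep <- keep[order(keep$mirna, keep$gene, keep$pos), , drop = FALSE]
  rownames(keep) <- NULL
  per_mirna <- vapply(unique(pairs$mirna), function(m)
    length(unique(keep$gene[keep$mirna == m])), numeric(1))
  list(targets = keep, n_criteria = n_crit[pairs$consensus],
       mean_targets_per_mirna = if (length(per_mirna)) mean(per_mirna) else NA_real_)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment of raw p-values (delegates to
#' [stats::p.adjust()]).
#'
#' @param p numeric vector of p-values.
#' @return adjusted values, same order as input.
#' @export
bh_fdr <- function(p) p.adjust(p, method = "BH")

#' Two-condition differential expression by exact binomial test
#'
#' Counts are pooled within each condition and each miRNA is tested
#' with a two-sided exact binomial test of the female pool against the
#' null proportion implied by the condition depths (sum of library
#' sizes). The log2 fold change is the depth-normalised female/male
#' ratio (0.5-count offset). Bias is called at raw `p < p_cutoff` with
#' direction from the fold-change sign; BH-adjusted FDR is reported
#' alongside. miRNAs with zero total count are excluded.
#'
#' @param counts integer matrix, miRNAs x libraries.
#' @param conditions per-library condition labels
#'   (`"male"`/`"female"`), in column order or named by column.
#' @param depths per-library sequencing depths; defaults to column
#'   sums.
#' @param p_cutoff significance threshold on the raw p-value.
#' @return data.frame `id`, `count_female`, `count_male`, `log2fc`,
#'   `p_value`, `fdr`, `biased` (`"female"`, `"male"` or `"none"`).
#' @export
de_test <- function(counts, conditions, depths = NULL, p_cutoff = 0.05) {
  stopifnot(is.matrix(counts), length(conditions) == ncol(counts))
  if (!all(conditions %in% c("male", "female")))
    stop("conditions must be 'male' or 'female'")
  if (!all(c("male", "female") %in% conditions))
    stop("need at least one library per condition")
  if (is.null(depths)) depths <- colSums(counts)
  d_f <- sum(depths[conditions == "female"])
  d_m <- sum(depths[conditions == "male"])
  p0 <- d_f / (d_f + d_m)
  x_f <- rowSums(counts[, conditions == "female", drop = FALSE])
  x_m <- rowSums(counts[, conditions == "male", drop = FALSE])
  keep <- (x_f + x_m) > 0
  if (!all(keep))
    message(sum(!keep), " miRNA(s) with zero total count excluded")
  x_f <- x_f[keep]; x_m <- x_m[keep]
  ids <- rownames(counts)[keep]
  if (is.null(ids)) ids <- sprintf("mir%04d", which(keep))

  pv <- vapply(seq_along(x_f), function(i)
    binom.test(x_f[i], x_f[i] + x_m[i], p = p0)$p.value, numeric(1))
  log2fc <- log2(((x_f + 0.5) / d_f) / ((x_m + 0.5) / d_m))
  fdr <- bh_fdr(pv)
  biased <- ifelse(pv < p_cutoff, ifelse(log2fc > 0, "female", "male"), "none")
  data.frame(id = ids, count_female = x_f, count_male = x_m,
             log2fc = log2fc, p_value = pv, fdr = fdr, biased = biased,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Annotation-term enrichment by Fisher's exact test
#'
#' For every term, the 2x2 table of gene-set membership against term
#' membership over the universe is tested one-sided for enrichment
#' (hypergeometric tail), with BH adjustment across terms.
#'
#' @param gene_set character vector of genes of interest (subset of
#'   `universe`).
#' @param universe character vector of all genes.
#' @param term_map data.frame with columns `gene`, `term`.
#' @return data.frame `term`, `set_with`, `set_without`, `bg_with`,
#'   `bg_without`, `odds_ratio`, `p_value`, `fdr`, sorted by p-value.
#' @export
fisher_enrichment <- function(gene_set, universe, term_map) {
  if (!all(gene_set %in% universe))
    stop("gene_set must be a subset of the universe")
  term_map <- term_map[term_map$gene %in% universe, , drop = FALSE]
  terms <- unique(term_map$term)
  res <- lapply(terms, function(tm) {
    with_term <- unique(term_map$gene[term_map$term == tm])
    a <- sum(gene_set %in% with_term)
    b <- length(gene_set) - a
    c_ <- length(setdiff(with_term, gene_set))
    d <- length(universe) - length(gene_set) - c_
    ft <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                      alternative = "greater")
    data.frame(term = tm, set_with = a, set_without = b, bg_with = c_,
               bg_without = d, odds_ratio = unname(ft$estimate),
               p_value = ft$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- bh_fdr(out$p_value)
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Relative qPCR fold change by the 2^-ddCt method
#'
#' `fold = 2^-((Ct_target_a - Ct_ref_a) - (Ct_target_b - Ct_ref_b))`,
#' i.e. condition a relative to condition b after normalising each to
#' its reference gene.
#'
#' @param ct_target_a,ct_ref_a target and reference Ct in condition a.
#' @param ct_target_b,ct_ref_b target and reference Ct in condition b.
#' @return fold change (condition a relative to condition b).
#' @export
ddct_fold_change <- function(ct_target_a, ct_ref_a, ct_target_b, ct_ref_b) {
  ddct <- (ct_target_a - ct_ref_a) - (ct_target_b - ct_ref_b)
  2^(-ddct)
}
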
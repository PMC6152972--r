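## Cross-genome homolog search with flank-extended hairpin validation,
## conservation classification, genomic cluster detection and seed
## analysis.

#' Search a genome for homologs of a mature miRNA
#'
#' Word-seeded (default 7-mer), ungapped-extended matching: every
#' seeded diagonal implies a full-length placement of the query, which
#' is kept when it covers at least `min_cov` of the query with identity
#' at least `min_ident`. Each retained location is extended by `flank`
#' nt on both sides, the window folded, and the implied mature/star
#' duplex validated against the geometry limits (space <= `max_space`,
#' bulge <= `max_bulge`). Verdicts: `homolog` (hairpin and geometry
#' pass), `no_hairpin` (the query's match barely pairs outside itself),
#' `geometry_fail` (pairs but violates the duplex limits). Locations
#' failing the identity screen are not reported; a query with no
#' reported location has no homolog in the target (`no_match`).
#'
#' @param query mature miRNA sequence, 18-30 nt (RNA or DNA; no N).
#' @param target a [genome_index()] of the target genome.
#' @param flank extension on each side of the matched location (nt).
#' @param min_cov minimum fraction of query positions covered by the
#'   ungapped placement.
#' @param min_ident minimum identity over the covered positions.
#' @param max_space,max_bulge duplex geometry limits.
#' @param min_paired minimum fraction of match positions paired outside
#'   the match for a hairpin verdict.
#' @param min_duplex_density minimum mean pair weight per match
#'   position (G:C = 3, A:U = 2, G:U = 1). A perfect all-A:U duplex
#'   scores 2.0; chance complements found by pair maximisation are
#'   wobble-rich and score lower, so 2.0 separates planted duplexes
#'   from spurious matchings in random sequence.
#' @param min_register minimum fraction of match positions paired on
#'   the modal duplex diagonal. Homologs diverged by substitution keep
#'   a fixed pairing register; a bulge of up to 5 nt splits the match
#'   at worst in half, hence the default 0.5. Chance duplexes
#'   assembled by pair maximisation scatter across registers.
#' @param query_id identifier carried into the result.
#' @return data.frame with one row per retained location: `query_id`,
#'   `seqname`, `start`, `end`, `strand` (match location, 0-based
#'   half-open), `identity`, `coverage`, `window_start`, `window_end`,
#'   `space`, `max_bulge`, `paired_fraction`, `verdict`. Zero rows when
#'   nothing matches.
#' @export
homolog_search <- function(query, target, flank = 90L,
                           min_cov = 0.8, min_ident = 0.85,
                           max_space = 35L, max_bulge = 5L,
                           min_paired = 0.6, min_duplex_density = 2.0,
                           min_register = 0.5, query_id = "query") {
  stopifnot(inherits(target, "genome_index"))
  qdna <- rna2dna(query)
  if (grepl("[^ACGT]", qdna)) stop("query contains ambiguous bases")
  qlen <- nchar(qdna)
  if (qlen < 18 || qlen > 30) stop("query must be 18-30 nt")
  k <- target$k
  empty <- data.frame(query_id = character(0), seqname = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), identity = numeric(0),
                      coverage = numeric(0), window_start = integer(0),
                      window_end = integer(0), space = integer(0),
                      max_bulge = integer(0), paired_fraction = numeric(0),
                      duplex_density = numeric(0), register = numeric(0),
                      verdict = character(0), stringsAsFactors = FALSE)

  ## seed: collect implied query placements from every k-mer word hit
  cand <- list()
  for (off in 0:(qlen - k)) {
    word <- substr(qdna, off + 1, off + k)
    wh <- word_hits(target, word)
    if (!nrow(wh)) next
    # implied 0-based start of the full query on the forward strand
    qstart <- ifelse(wh$strand == "+", wh$start - off,
                     wh$start - (qlen - k - off))
    cand[[length(cand) + 1]] <- data.frame(
      seqname = wh$seqname, qstart = qstart, strand = wh$strand,
      stringsAsFactors = FALSE)
  }
  if (!length(cand)) return(empty)
  cand <- unique(do.call(rbind, cand))

  out <- list()
  for (i in seq_len(nrow(cand))) {
    sq <- target$sequences[[match(cand$seqname[i], names(target$sequences))]]
    L <- length(sq)
    qs <- cand$qstart[i]
    lo <- max(0L, qs); hi <- min(L, qs + qlen)
    if (hi - lo < 1) next
    covered <- hi - lo
    tgt <- as.character(Biostrings::subseq(sq, lo + 1, hi))
    if (cand$strand[i] == "-") tgt <- rc_dna(tgt)
    qsub <- if (cand$strand[i] == "+") substr(qdna, lo - qs + 1, hi - qs)
    else substr(qdna, qs + qlen - hi + 1, qs + qlen - lo)
    matches <- sum(strsplit(qsub, "")[[1]] == strsplit(tgt, "")[[1]])
    identity <- matches / covered
    coverage <- covered / qlen
    if (coverage < min_cov || identity < min_ident) next
    out[[length(out) + 1]] <- data.frame(
      seqname = cand$seqname[i], start = lo, end = hi,
      strand = cand$strand[i], identity = identity, coverage = coverage,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  hits <- unique(do.call(rbind, out))
  ## collapse near-identical placements (within 3 nt) to the best one
  hits <- hits[order(hits$seqname, hits$strand, -hits$identity, hits$start), ]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    dup <- keep & seq_len(nrow(hits)) > i & hits$seqname == hits$seqname[i] &
      hits$strand == hits$strand[i] & abs(hits$start - hits$start[i]) <= 3
    keep[dup] <- FALSE
  }
  hits <- hits[keep, , drop = FALSE]

  ## flank-extend, fold, validate duplex geometry
  res <- lapply(seq_len(nrow(hits)), function(i) {
    sq <- target$sequences[[match(hits$seqname[i], names(target$sequences))]]
    L <- length(sq)
    ws <- max(0L, hits$start[i] - flank)
    we <- min(L, hits$end[i] + flank)
    win <- as.character(Biostrings::subseq(sq, ws + 1, we))
    if (hits$strand[i] == "-") win <- rc_dna(win)
    win <- dna2rna(win)
    f <- fold(win)
    m_rel <- if (hits$strand[i] == "+") c(hits$start[i] - ws, hits$end[i] - ws)
    else c(we - hits$end[i], we - hits$start[i])
    mpos <- (m_rel[1] + 1):m_rel[2]
    partner <- f$pairing[mpos]
    cross <- !is.na(partner) & (partner <= m_rel[1] | partner > m_rel[2])
    ## keep the side of the mature match holding most duplex partners
    on_left <- cross & partner <= m_rel[1]
    on_right <- cross & partner > m_rel[2]
    side <- if (sum(on_right) >= sum(on_left)) on_right else on_left
    partners <- partner[side]
    pf <- length(partners) / length(mpos)
    b <- strsplit(win, "")[[1]]
    density <- sum(pair_weight(b[mpos[side]], b[partners])) / length(mpos)
    # register: antiparallel pairs on one diagonal share i + partner(i)
    register <- if (length(partners))
      max(table(mpos[side] + partners)) / length(mpos) else 0
    space <- NA_integer_; bulge <- NA_integer_
    # below 20% pairing the match sits in an effectively unpairable
    # context (no_hairpin); above it a duplex forms but may violate
    # the geometry screens (geometry_fail)
    if (length(partners) < 2 || pf < 0.2) {
      verdict <- "no_hairpin"
    } else {
      partners <- sort(partners)
      star_rel <- c(min(partners) - 1L, max(partners))
      geom <- duplex_geometry(f, m_rel, star_rel)
      space <- geom$space; bulge <- geom$max_bulge
      verdict <- if (pf >= min_paired && density >= min_duplex_density &&
                     register >= min_register &&
                     space <= max_space && bulge <= max_bulge)
        "homolog" else "geometry_fail"
    }
    data.frame(query_id = query_id, seqname = hits$seqname[i],
               start = hits$start[i], end = hits$end[i],
               strand = hits$strand[i], identity = hits$identity[i],
               coverage = hits$coverage[i], window_start = ws,
               window_end = we, space = space, max_bulge = bulge,
               paired_fraction = pf, duplex_density = density,
               register = register, verdict = verdict,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Classify cross-genome conservation of a miRNA set
#'
#' A miRNA is "found" in a genome when any of its homolog-search hits
#' there has verdict `homolog`.
#'
#' @param mirna_ids character vector of miRNA identifiers.
#' @param hits_per_genome named list (one element per target genome) of
#'   [homolog_search()] result data.frames, rbind-ed over queries.
#' @return list with `classes` (data.frame `id`, `n_genomes`, `class`
#'   in both/one/neither) and `fractions` (named numeric summary).
#' @export
classify_conservation <- function(mirna_ids, hits_per_genome) {
  found <- vapply(hits_per_genome, function(h) {
    mirna_ids %in% h$query_id[h$verdict == "homolog"]
  }, logical(length(mirna_ids)))
  if (is.null(dim(found))) found <- matrix(found, nrow = length(mirna_ids))
  n_found <- rowSums(found)
  n_gen <- length(hits_per_genome)
  cls <- ifelse(n_found == n_gen, "both",
                ifelse(n_found == 0, "neither", "one"))
  classes <- data.frame(id = mirna_ids, n_genomes = n_found, class = cls,
                        stringsAsFactors = FALSE)
  fr <- c(both = mean(cls == "both"), one = mean(cls == "one"),
          neither = mean(cls == "neither"))
  list(classes = classes, fractions = fr)
}

#' Detect genomic miRNA clusters
#'
#' Single-linkage chaining of loci along each sequence: consecutive
#' loci whose gap (start of the next minus end of the previous
#' precursor) is at most `max_gap` join one cluster. Singletons are not
#' clusters. Pairwise shared seeds are reported when mature sequences
#' are available.
#'
#' @param loci data.frame with columns `id`, `seqname`, `start`, `end`
#'   (0-based half-open), optional `genome` and `mature_seq`.
#' @param max_gap maximum inter-locus gap in nt (default 10,000).
#' @return data.frame with one row per cluster member: `cluster`,
#'   `genome`, `seqname`, `id`, `start`, `end`, `gap_to_next` (NA for
#'   the last member), `seed` and `shared_seed` (TRUE when the member's
#'   seed equals another member's seed in the same cluster).
#' @export
find_clusters <- function(loci, max_gap = 10000L) {
  if (!nrow(loci))
    return(data.frame(cluster = character(0), genome = character(0),
                      seqname = character(0), id = character(0),
                      start = integer(0), end = integer(0),
                      gap_to_next = integer(0), seed = character(0),
                      shared_seed = logical(0), stringsAsFactors = FALSE))
  if (is.null(loci$genome)) loci$genome <- "genome"
  loci <- loci[order(loci$genome, loci$seqname, loci$start), , drop = FALSE]
  out <- list()
  cl_n <- 0L
  for (g in split(loci, paste(loci$genome, loci$seqname, sep = "\r"))) {
    gap <- g$start[-1] - g$end[-nrow(g)]
    brk <- c(0, which(gap > max_gap), nrow(g))
    for (b in seq_len(length(brk) - 1)) {
      members <- (brk[b] + 1):brk[b + 1]
      if (length(members) < 2) next
      cl_n <- cl_n + 1L
      m <- g[members, , drop = FALSE]
      seeds <- if (!is.null(m$mature_seq)) seed_of(m$mature_seq)
      else rep(NA_character_, nrow(m))
      shared <- vapply(seq_along(seeds), function(i)
        !is.na(seeds[i]) && seeds[i] %in% seeds[-i], logical(1))
      out[[cl_n]] <- data.frame(
        cluster = sprintf("cluster-%03d", cl_n), genome = m$genome,
        seqname = m$seqname, id = m$id, start = m$start, end = m$end,
        gap_to_next = c(m$start[-1] - m$end[-nrow(m)], NA_integer_),
        seed = seeds, shared_seed = shared, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(find_clusters(loci[0, , drop = FALSE], max_gap))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Seed region of a mature miRNA
#'
#' Nucleotides 2-8 (7-mer) by default; an 8-mer (positions 2-9) is
#' available via `seed_len`.
#'
#' @param mature character vector of mature sequences (RNA or DNA).
#' @param seed_len 7 or 8.
#' @return character vector of seeds (RNA alphabet).
#' @export
seed_of <- function(mature, seed_len = 7L) {
  stopifnot(seed_len %in% c(7L, 8L))
  substr(dna2rna(mature), 2, 1 + seed_len)
}

#' Fold-ratio of one genome's intra-cluster distance to the others
#'
#' For one orthologous cluster observed in several genomes, the focal
#' genome's gap divided by the mean gap of the remaining genomes,
#' reported raw and rounded to the nearest integer fold.
#'
#' @param gaps named numeric vector of intra-cluster gaps (nt), one per
#'   genome.
#' @param focal name of the focal genome.
#' @return list with `ratio` (raw) and `fold` (rounded).
#' @export
cluster_distance_ratio <- function(gaps, focal) {
  stopifnot(focal %in% names(gaps), length(gaps) >= 2)
  others <- gaps[setdiff(names(gaps), focal)]
  ratio <- unname(gaps[[focal]] / mean(others))
  list(ratio = ratio, fold = round(ratio))
}
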
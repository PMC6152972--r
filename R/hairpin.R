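#' Construct a pre-miRNA hairpin around a mature sequence
#'
#' Builds a precursor whose two arms form a duplex between the given
#' mature sequence and its reverse complement (the star), separated by a
#' terminal loop. The star carries a 3' overhang (default 2 nt, the
#' canonical Drosha/Dicer signature). Bulges — unpaired runs inside the
#' duplex — can be planted at chosen positions: a bulge on the star arm
#' inserts unpairable bases into the star; a bulge on the mature arm
#' deletes the corresponding star bases so the mature side loops out.
#'
#' @param mature_seq mature miRNA sequence, 18-30 nt (RNA; T read as U).
#' @param loop_len terminal loop length in nt (>= 3).
#' @param bulges list of `list(arm=, offset=, size=)` entries with
#'   `arm` in `"mature"`/`"star"`, `offset` a 0-based position within
#'   the star core (counted 5'->3' on the star) and `size >= 0`.
#' @param mature_on which precursor arm carries the mature product,
#'   `"5p"` or `"3p"`.
#' @param overhang star 3' overhang length, 0-3 nt.
#' @param loop_seq optional explicit loop sequence (overrides
#'   `loop_len`); defaults to an A-run, which cannot pair with itself.
#' @param bulge_base base used for inserted bulges; by default the base
#'   (C or A) whose pairing partners are rarest in the mature sequence,
#'   so planted bulges stay unpaired under pair-maximising folding.
#' @return list with `precursor` (RNA string), `mature`, `star`, `loop`
#'   (0-based half-open intervals on the precursor), `mature_seq`,
#'   `star_seq`, `mature_arm` (`"5p"`/`"3p"`).
#' @export
build_hairpin <- function(mature_seq, loop_len = 10L, bulges = list(),
                          mature_on = "5p", overhang = 2L,
                          loop_seq = NULL, bulge_base = NULL) {
  mature_seq <- dna2rna(mature_seq)
  L <- nchar(mature_seq)
  if (L < 18 || L > 30) stop("mature sequence must be 18-30 nt")
  if (is.null(loop_seq)) {
    if (loop_len < 3) stop("loop_len must be >= 3 (sterically impossible hairpin)")
    loop_seq <- strrep("A", loop_len)
  }
  loop_len <- nchar(loop_seq)
  if (loop_len < 3) stop("loop sequence must be >= 3 nt")
  if (overhang < 0 || overhang > 3) stop("overhang must be 0-3 nt")
  if (is.null(bulge_base)) {
    nG <- lengths(regmatches(mature_seq, gregexpr("G", mature_seq)))
    nU <- lengths(regmatches(mature_seq, gregexpr("U", mature_seq)))
    # C pairs only G; A pairs only U — pick the one with fewer partners
    bulge_base <- if (nG <= nU) "C" else "A"
  }

  star_core <- dna2rna(rc_dna(rna2dna(mature_seq)))
  for (b in bulges) {
    stopifnot(all(c("arm", "offset", "size") %in% names(b)))
    if (b$size < 0) stop("bulge size must be >= 0")
    if (b$size == 0) next
    off <- b$offset
    if (b$arm == "star") {
      star_core <- paste0(substr(star_core, 1, off),
                          strrep(bulge_base, b$size),
                          substr(star_core, off + 1, nchar(star_core)))
    } else if (b$arm == "mature") {
      star_core <- paste0(substr(star_core, 1, off),
                          substr(star_core, off + 1 + b$size, nchar(star_core)))
    } else stop("bulge arm must be 'mature' or 'star'")
  }
  # overhang base chosen so it cannot pair the mature 5' base, keeping
  # the designed outermost stem pair unambiguous under pair maximisation
  first <- substr(mature_seq, 1, 1)
  oh <- strrep(if (first %in% c("G", "C")) "A" else "C", overhang)
  Ls <- nchar(star_core) + overhang

  if (mature_on == "5p") {
    precursor <- paste0(mature_seq, loop_seq, star_core, oh)
    mature <- iv(0, L)
    loop <- iv(L, L + loop_len)
    star <- iv(L + loop_len, L + loop_len + Ls)
  } else if (mature_on == "3p") {
    # star's 3' end (and its overhang) sits loop-proximal on the 5' arm
    precursor <- paste0(star_core, oh, loop_seq, mature_seq)
    star <- iv(0, Ls)
    loop <- iv(Ls, Ls + loop_len)
    mature <- iv(Ls + loop_len, Ls + loop_len + L)
  } else stop("mature_on must be '5p' or '3p'")

  list(precursor = precursor, mature = mature, star = star, loop = loop,
       mature_seq = mature_seq,
       star_seq = subseq0(precursor, star[1], star[2]),
       mature_arm = mature_on)
}

#' Plant precursor sequences into a genome
#'
#' Overwrites genome positions with the given precursors (as DNA;
#' reverse-complemented for minus-strand loci) and returns the modified
#' genome with a truth table of planted intervals. Positions may be
#' given explicitly (0-based starts) or left NA for automatic placement;
#' automatic placement keeps loci non-overlapping with at least
#' `min_sep` nt between them. Loci sharing a `cluster` label are placed
#' consecutively with exactly the requested `cluster_gap` between the
#' end of one precursor and the start of the next.
#'
#' @param genome DNA string.
#' @param loci data.frame with columns `id`, `seq` (precursor DNA or
#'   RNA), `strand` (`"+"`/`"-"`), optional `pos` (0-based start or NA),
#'   optional `cluster` (NA or label) and `cluster_gap`.
#' @param min_sep minimum separation between auto-placed loci (nt).
#' @return list with `genome` (modified string) and `truth`
#'   (data.frame `id`, `start`, `end`, `strand`, `cluster`).
#' @export
plant_loci <- function(genome, loci, min_sep = 200L) {
  G <- nchar(genome)
  if (!nrow(loci))
    return(list(genome = genome,
                truth = data.frame(id = character(0), start = integer(0),
                                   end = integer(0), strand = character(0),
                                   cluster = character(0),
                                   stringsAsFactors = FALSE)))
  if (is.null(loci$pos)) loci$pos <- NA_integer_
  if (is.null(loci$cluster)) loci$cluster <- NA_character_
  if (is.null(loci$cluster_gap)) loci$cluster_gap <- NA_integer_
  seqs <- rna2dna(loci$seq)
  widths <- nchar(seqs)

  ## group loci into placement blocks: clustered groups placed as one
  ## block with exact internal gaps, singletons alone
  keys <- ifelse(is.na(loci$cluster), paste0(".solo", seq_len(nrow(loci))),
                 loci$cluster)
  blocks <- split(seq_len(nrow(loci)), factor(keys, levels = unique(keys)))
  placed <- data.frame(start = integer(0), end = integer(0))
  starts <- integer(nrow(loci))

  for (bl in blocks) {
    gaps <- loci$cluster_gap[bl][-1]
    if (anyNA(gaps) && length(bl) > 1)
      stop("clustered loci need a cluster_gap for every member after the first")
    block_w <- sum(widths[bl]) + sum(gaps)
    fixed <- loci$pos[bl[1]]
    if (!is.na(fixed)) {
      s0 <- as.integer(fixed)
    } else {
      ## deterministic scan from a random offset for a free slot
      ok <- FALSE
      for (try in seq_len(2000)) {
        s0 <- as.integer(floor(runif(1, 0, max(1, G - block_w))))
        lo <- s0 - min_sep; hi <- s0 + block_w + min_sep
        if (lo >= 0 && hi <= G &&
            !any(placed$start < hi & lo < placed$end)) { ok <- TRUE; break }
      }
      if (!ok)
        stop("could not place locus '", loci$id[bl[1]],
             "': genome too small for the requested loci")
    }
    if (s0 < 0 || s0 + block_w > G)
      stop("locus '", loci$id[bl[1]], "' does not fit in the genome")
    offs <- c(0L, cumsum(widths[bl][-length(bl)] + gaps))
    starts[bl] <- s0 + offs
    placed <- rbind(placed, data.frame(start = s0, end = s0 + block_w))
  }

  g <- strsplit(genome, "")[[1]]
  for (i in seq_len(nrow(loci))) {
    ins <- if (loci$strand[i] == "-") rc_dna(seqs[i]) else seqs[i]
    g[(starts[i] + 1):(starts[i] + widths[i])] <- strsplit(ins, "")[[1]]
  }
  truth <- data.frame(id = loci$id, start = starts,
                      end = starts + widths, strand = loci$strand,
                      cluster = loci$cluster, stringsAsFactors = FALSE)
  list(genome = paste(g, collapse = ""), truth = truth)
}

#' Mutate a genome by random substitutions
#'
#' Each base is substituted, independently with probability `rate`, by
#' one of the three other bases. Used to derive sister genomes carrying
#' diverged homologous loci.
#'
#' @param genome DNA string.
#' @param rate per-base substitution probability in `[0, 1]`.
#' @return mutated DNA string of the same length.
#' @export
mutate_genome <- function(genome, rate) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(genome)
  g <- strsplit(genome, "")[[1]]
  hit <- which(runif(length(g)) < rate)
  if (length(hit)) {
    g[hit] <- vapply(g[hit], function(b) {
      sample(setdiff(DNA_BASES, b), 1)
    }, character(1), USE.NAMES = FALSE)
  }
  paste(g, collapse = "")
}
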
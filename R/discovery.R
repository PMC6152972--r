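## Novel miRNA locus calling from mapped clean tags: cluster read
## stacks, excise candidate precursor windows around the dominant
## stack, fold, locate the star on the opposite arm and apply the
## read-evidence and duplex-geometry filters.

#' Default parameters for locus calling
#'
#' Read-evidence thresholds (at least 10 mature-strand reads and at
#' least one star read, summed across libraries), duplex-geometry
#' limits (space <= 35 nt between mature and star through the loop,
#' bulges <= 5 nt), the repetitive-locus cutoff and the precursor
#' excision window.
#'
#' @return named list of parameters.
#' @export
discovery_params <- function() {
  list(min_mature_reads = 10L,  # summed across libraries
       min_star_reads = 1L,
       max_space = 35L,
       max_bulge = 5L,
       max_hits = 5L,           # tags mapping to more positions are repetitive
       window_near = 15L,       # nt excised on the mature's distal side
       window_far = 70L,        # nt excised toward the putative star side
       jitter_window = 2L,      # 5'-offset window defining a read family
       min_anchor_reads = 2L,   # minimum reads in a stack to seed a candidate
       min_paired = 0.6)        # fraction of mature positions in the duplex
}

## map stacks (genome intervals) into precursor-window coordinates
rel_coords <- function(start, end, ws, we, strand) {
  if (strand == "+") cbind(start - ws, end - ws)
  else cbind(we - end, we - start)
}

#' Call candidate miRNA loci from clean tags
#'
#' Maps tags to the genome with zero mismatches, drops repetitive tags
#' (more than `max_hits` genomic positions), piles the remaining
#' alignments into read stacks, and seeds a candidate locus at every
#' stack whose 5'-offset family reaches `min_anchor_reads`. Around each
#' seed two precursor windows are excised (star side unknown a priori),
#' folded by [fold()], and the window with the stronger mature/star
#' duplex kept. The star is the most abundant stack on the opposite arm
#' whose 5' end lies within `jitter_window` nt of the position the fold
#' predicts. Candidates then pass or fail the read-evidence and
#' geometry filters; rejected candidates carry a machine-readable
#' reason (`no_hairpin`, `space_exceeded`, `bulge_exceeded`,
#' `low_mature`, `no_star`).
#'
#' @param tags clean tag data.frame (see [collapse_tags()]): `sequence`
#'   plus `count_<library>` columns.
#' @param index a [genome_index()].
#' @param params parameter list, see [discovery_params()].
#' @return object of class `mirna_loci`: list with `loci` (one row per
#'   candidate: coordinates, sequences, read support, geometry,
#'   `status`), and matrices `mature_counts`, `star_counts` (loci x
#'   libraries).
#' @export
call_loci <- function(tags, index, params = discovery_params()) {
  p <- modifyList(discovery_params(), params)
  lib_cols <- grep("^count_", names(tags), value = TRUE)
  libs <- sub("^count_", "", lib_cols)
  empty <- empty_loci(libs)
  if (!nrow(tags)) return(empty)

  hits <- map_exact(tags$sequence, index)
  if (!nrow(hits)) return(empty)
  nhit <- table(hits$read)
  repetitive <- as.integer(names(nhit))[nhit > p$max_hits]
  hits <- hits[!hits$read %in% repetitive, , drop = FALSE]
  if (!nrow(hits)) return(empty)

  ## stacks: unique alignment intervals with per-library counts
  key <- paste(hits$seqname, hits$strand, hits$start, hits$end, sep = "\r")
  first <- !duplicated(key)
  stacks <- hits[first, c("seqname", "strand", "start", "end"), drop = FALSE]
  grp <- match(key, key[first])
  cnt <- matrix(0L, nrow(stacks), length(lib_cols),
                dimnames = list(NULL, libs))
  for (j in seq_along(lib_cols))
    cnt[, j] <- as.integer(rowsum(tags[[lib_cols[j]]][hits$read], grp)[, 1])
  stacks$total <- as.integer(rowSums(cnt))
  stacks$bio5 <- ifelse(stacks$strand == "+", stacks$start, stacks$end)
  rownames(stacks) <- NULL

  ## 5'-family totals: reads on the same seq/strand whose 5' ends lie
  ## within the jitter window (such reads necessarily overlap at >= 18 nt)
  fam <- integer(nrow(stacks))
  ord_key <- paste(stacks$seqname, stacks$strand)
  w <- p$jitter_window
  for (g in split(seq_len(nrow(stacks)), ord_key)) {
    pos <- stacks$bio5[g]
    lo <- min(pos)
    dense <- integer(max(pos) - lo + 1L + 2L * w)
    at <- pos - lo + w + 1L
    tot <- rowsum(stacks$total[g], at)
    dense[as.integer(rownames(tot))] <- tot[, 1]
    cs <- c(0L, cumsum(dense))
    fam[g] <- cs[at + w + 1L] - cs[at - w]
  }
  stacks$family_total <- fam

  anchors <- which(stacks$total >= p$min_anchor_reads)
  # strongest families first; within a family the modal (highest-count)
  # stack defines the annotated mature 5' end
  anchors <- anchors[order(-stacks$family_total[anchors],
                           -stacks$total[anchors],
                           stacks$seqname[anchors], stacks$start[anchors],
                           stacks$strand[anchors])]
  if (!length(anchors)) return(empty)

  seqs <- index$sequences
  # arm intervals of already-called loci; anchors inside them (jittered
  # mature variants, star stacks) must not seed duplicate candidates
  covered <- list()  # per "seq\rstrand": matrix of claimed intervals
  records <- list()

  for (a in anchors) {
    st <- stacks[a, ]
    ckey <- paste(st$seqname, st$strand, sep = "\r")
    cov <- covered[[ckey]]
    if (!is.null(cov) &&
        any(cov[, 1] - p$jitter_window <= st$start &
            st$end <= cov[, 2] + p$jitter_window)) next

    L <- Biostrings::width(seqs)[match(st$seqname, names(seqs))]
    cand <- list(
      c(max(0L, st$start - p$window_near), min(L, st$end + p$window_far)),
      c(max(0L, st$start - p$window_far), min(L, st$end + p$window_near)))
    near <- which(stacks$seqname == st$seqname & stacks$strand == st$strand &
                    stacks$start >= st$start - p$window_far - 5L &
                    stacks$end <= st$end + p$window_far + 5L)

    best <- NULL
    for (w in cand) {
      ws <- w[1]; we <- w[2]
      if (st$start < ws || st$end > we) next
      pre <- as.character(Biostrings::subseq(seqs[[match(st$seqname, names(seqs))]],
                                             ws + 1, we))
      if (st$strand == "-") pre <- rc_dna(pre)
      pre <- dna2rna(pre)
      m_rel <- as.integer(rel_coords(st$start, st$end, ws, we, st$strand))

      rcn <- rel_coords(stacks$start[near], stacks$end[near], ws, we, st$strand)
      inw <- rcn[, 1] >= 0 & rcn[, 2] <= we - ws
      is_m <- inw & abs(rcn[, 1] - m_rel[1]) <= p$jitter_window &
        rcn[, 1] < m_rel[2] & m_rel[1] < rcn[, 2]

      ## candidate star stacks: read-supported, inside the window, not
      ## overlapping the mature; validate each by folding only the
      ## trimmed putative precursor (arms + loop, no flanking sequence)
      is_c <- inw & !(rcn[, 1] < m_rel[2] & m_rel[1] < rcn[, 2])
      cand_idx <- near[is_c]
      cand_rel <- rcn[is_c, , drop = FALSE]
      ord <- order(-stacks$total[cand_idx])[seq_len(min(5L, length(cand_idx)))]
      cand_idx <- cand_idx[ord]
      cand_rel <- cand_rel[ord, , drop = FALSE]

      win_best <- NULL
      for (ci in seq_along(cand_idx)) {
        c_rel <- as.integer(cand_rel[ci, ])
        trim <- c(min(m_rel[1], c_rel[1]), max(m_rel[2], c_rel[2]))
        f_t <- fold(subseq0(pre, trim[1], trim[2]))
        geom <- duplex_geometry(f_t, m_rel - trim[1], c_rel - trim[1])
        sc <- c(geom$paired_fraction, stacks$total[cand_idx[ci]])
        if (is.null(win_best) || sc[1] > win_best$sc[1] ||
            (sc[1] == win_best$sc[1] && sc[2] > win_best$sc[2]))
          win_best <- list(sc = sc, c_rel = c_rel, geom = geom)
      }

      if (!is.null(win_best) && win_best$sc[1] >= p$min_paired) {
        s_rel <- win_best$c_rel
        is_s <- inw & !is_m & abs(rcn[, 1] - s_rel[1]) <= p$jitter_window &
          rcn[, 1] < s_rel[2] & s_rel[1] < rcn[, 2]
        entry <- list(ws = ws, we = we, pre = pre, m_rel = m_rel,
                      star_rel = s_rel, star_idx = near[is_s],
                      m_fam = near[is_m], geom = win_best$geom,
                      pf = win_best$geom$paired_fraction)
      } else {
        ## no read-supported duplex partner: infer the star arm from the
        ## window fold, then re-measure geometry on the trimmed precursor
        f <- fold(pre)
        partner <- f$pairing[(m_rel[1] + 1):m_rel[2]]
        crossp <- partner[!is.na(partner) &
                            (partner <= m_rel[1] | partner > m_rel[2])]
        left <- crossp[crossp <= m_rel[1]]
        right <- crossp[crossp > m_rel[2]]
        partners <- if (length(right) >= length(left)) right else left
        pf <- length(partners) / (m_rel[2] - m_rel[1])
        geom <- NULL; s_rel <- NULL
        if (length(partners) >= 2) {
          s_rel <- c(min(partners) - 1L, max(partners))
          trim <- c(min(m_rel[1], s_rel[1]), max(m_rel[2], s_rel[2]))
          f_t <- fold(subseq0(pre, trim[1], trim[2]))
          geom <- duplex_geometry(f_t, m_rel - trim[1], s_rel - trim[1])
          pf <- geom$paired_fraction
        }
        entry <- list(ws = ws, we = we, pre = pre, m_rel = m_rel,
                      star_rel = s_rel, star_idx = integer(0),
                      m_fam = near[is_m], geom = geom, pf = pf)
      }
      entry$score <- c(length(entry$star_idx) > 0, entry$pf)
      if (is.null(best) || entry$score[1] > best$score[1] ||
          (entry$score[1] == best$score[1] && entry$score[2] > best$score[2]))
        best <- entry
    }
    if (is.null(best)) next

    ws <- best$ws; we <- best$we
    mature_total <- sum(stacks$total[best$m_fam])
    mature_lib <- colSums(cnt[best$m_fam, , drop = FALSE])
    star_total <- sum(stacks$total[best$star_idx])
    star_lib <- colSums(cnt[best$star_idx, , drop = FALSE])

    status <- "accepted"; reason <- NA_character_
    space <- NA_integer_; bulge <- NA_integer_
    if (!is.null(best$geom)) {
      space <- best$geom$space; bulge <- best$geom$max_bulge
    }
    if (is.null(best$geom) || best$pf < p$min_paired) {
      status <- "rejected"; reason <- "no_hairpin"
    } else if (mature_total < p$min_mature_reads) {
      status <- "rejected"; reason <- "low_mature"
    } else if (star_total < p$min_star_reads) {
      status <- "rejected"; reason <- "no_star"
    } else if (space > p$max_space) {
      status <- "rejected"; reason <- "space_exceeded"
    } else if (bulge > p$max_bulge) {
      status <- "rejected"; reason <- "bulge_exceeded"
    }

    ## genome coordinates of mature/star
    to_genome <- function(rel) {
      if (st$strand == "+") c(ws + rel[1], ws + rel[2])
      else c(we - rel[2], we - rel[1])
    }
    m_g <- to_genome(best$m_rel)
    s_g <- if (!is.null(best$star_rel)) to_genome(best$star_rel) else c(NA, NA)
    mature_arm <- if (!is.null(best$star_rel) && best$m_rel[1] < best$star_rel[1])
      "5p" else "3p"

    records[[length(records) + 1]] <- list(
      row = data.frame(
        seqname = st$seqname, start = ws, end = we, strand = st$strand,
        status = status, reason = reason, mature_arm = mature_arm,
        mature_start = m_g[1], mature_end = m_g[2],
        star_start = s_g[1], star_end = s_g[2],
        mature_seq = dna2rna(subseq0(best$pre, best$m_rel[1], best$m_rel[2])),
        star_seq = if (!is.null(best$star_rel))
          dna2rna(subseq0(best$pre, best$star_rel[1], best$star_rel[2]))
        else NA_character_,
        precursor = dna2rna(best$pre),
        mature_total = mature_total, star_total = star_total,
        space = space, max_bulge = bulge,
        paired_fraction = best$pf,
        stringsAsFactors = FALSE),
      mature_lib = mature_lib, star_lib = star_lib)
    claims <- rbind(m_g, if (!anyNA(s_g)) s_g)
    covered[[ckey]] <- rbind(cov, claims)
  }

  if (!length(records)) return(empty)
  loci <- do.call(rbind, lapply(records, `[[`, "row"))
  ord <- order(loci$seqname, loci$start, loci$strand)
  loci <- loci[ord, , drop = FALSE]
  loci <- cbind(id = sprintf("mirloc-%04d", seq_len(nrow(loci))), loci,
                stringsAsFactors = FALSE)
  rownames(loci) <- NULL
  mat <- do.call(rbind, lapply(records, `[[`, "mature_lib"))[ord, , drop = FALSE]
  str <- do.call(rbind, lapply(records, `[[`, "star_lib"))[ord, , drop = FALSE]
  rownames(mat) <- rownames(str) <- loci$id
  structure(list(loci = loci, mature_counts = mat, star_counts = str,
                 libraries = libs, params = p),
            class = "mirna_loci")
}

empty_loci <- function(libs) {
  structure(list(
    loci = data.frame(id = character(0), seqname = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), status = character(0),
                      reason = character(0), stringsAsFactors = FALSE),
    mature_counts = matrix(0L, 0, length(libs), dimnames = list(NULL, libs)),
    star_counts = matrix(0L, 0, length(libs), dimnames = list(NULL, libs)),
    libraries = libs, params = discovery_params()),
    class = "mirna_loci")
}

#' @export
print.mirna_loci <- function(x, ...) {
  n_acc <- sum(x$loci$status == "accepted")
  cat("mirna_loci: ", nrow(x$loci), " candidates, ", n_acc, " accepted\n",
      sep = "")
  if (nrow(x$loci) > n_acc) {
    tab <- table(x$loci$reason[x$loci$status == "rejected"])
    cat("rejections: ", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Accepted loci of a discovery result
#'
#' @param x a [call_loci()] result.
#' @return data.frame of accepted loci.
#' @export
accepted_loci <- function(x) {
  stopifnot(inherits(x, "mirna_loci"))
  out <- x$loci[x$loci$status == "accepted", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mature length spectrum of accepted loci
#'
#' @param x a [call_loci()] result or a data.frame of accepted loci.
#' @return list with `lengths` (probability vector named by length; sums
#'   to 1) and `mode` (modal mature length, NA when empty).
#' @export
length_spectrum <- function(x) {
  loci <- if (inherits(x, "mirna_loci")) accepted_loci(x) else x
  if (!nrow(loci)) return(list(lengths = numeric(0), mode = NA_integer_))
  tab <- table(nchar(loci$mature_seq))
  probs <- as.numeric(tab) / sum(tab)
  names(probs) <- names(tab)
  list(lengths = probs, mode = as.integer(names(tab)[which.max(tab)]))
}

#' First-nucleotide bias of accepted mature sequences
#'
#' @param x a [call_loci()] result or a data.frame of accepted loci.
#' @return named frequency vector over A/C/G/U (sums to 1; all zero
#'   when empty).
#' @export
first_nt_bias <- function(x) {
  loci <- if (inherits(x, "mirna_loci")) accepted_loci(x) else x
  out <- c(A = 0, C = 0, G = 0, U = 0)
  if (!nrow(loci)) return(out)
  first <- substr(dna2rna(loci$mature_seq), 1, 1)
  tab <- table(factor(first, levels = names(out)))
  out[] <- as.numeric(tab) / sum(tab)
  out
}

#' Evaluate discovery against a simulation truth table
#'
#' Recall is measured over *expressed* planted loci — those whose
#' simulated read support meets the evidence thresholds (at least
#' `min_mature_reads` mature-origin reads and `min_star_reads`
#' star-origin reads across libraries, per the reads' truth labels).
#' Precision is the fraction of accepted loci whose precursor interval
#' overlaps a planted locus.
#'
#' @param called a [call_loci()] result.
#' @param sim a [simulate_genome()] result.
#' @param reads a [simulate_reads()] result.
#' @return list with `recall`, `precision`, `n_expressed`, `n_accepted`.
#' @export
discovery_performance <- function(called, sim, reads) {
  p <- called$params
  all_reads <- do.call(rbind, reads$libraries)
  support <- function(locus, origin)
    sum(all_reads$origin == origin & !is.na(all_reads$locus) &
          all_reads$locus == locus)
  truth <- sim$truth
  m_sup <- vapply(truth$id, support, numeric(1), origin = "mature")
  s_sup <- vapply(truth$id, support, numeric(1), origin = "star")
  expressed <- truth[m_sup >= p$min_mature_reads & s_sup >= p$min_star_reads, ]
  acc <- accepted_loci(called)
  hit <- function(t_start, t_end) {
    any(acc$seqname == "chr1" & acc$start < t_end & t_start < acc$end)
  }
  found <- mapply(hit, expressed$start, expressed$end)
  tp <- vapply(seq_len(nrow(acc)), function(i)
    any(truth$start < acc$end[i] & acc$start[i] < truth$end), logical(1))
  list(recall = if (nrow(expressed)) mean(found) else NA_real_,
       precision = if (nrow(acc)) mean(tp) else NA_real_,
       n_expressed = nrow(expressed), n_accepted = nrow(acc))
}
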
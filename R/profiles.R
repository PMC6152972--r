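## Arm-usage quantification, cross-dataset arm-switch detection, and
## 5'-isomiR fidelity profiling.

#' Arm-usage profile of a miRNA locus
#'
#' The dominant arm must carry at least `ratio` times the reads of the
#' other arm; otherwise the locus is codominant. The default ratio of 2
#' operationalises "dominant product" for qualitative cross-species
#' comparison.
#'
#' @param reads_5p,reads_3p read counts on the 5' and 3' arms, or a
#'   single-row slice of [call_loci()] output passed as `reads_5p` (the
#'   mature/star counts are assigned to arms via `mature_arm`).
#' @param ratio dominance ratio threshold (> 1).
#' @param id locus identifier carried through to the profile.
#' @return object of class `arm_usage`: list with `id`, `reads_5p`,
#'   `reads_3p`, `fraction_5p`, `dominant` (`"5p"`, `"3p"` or
#'   `"codominant"`).
#' @export
arm_usage <- function(reads_5p, reads_3p = NULL, ratio = 2, id = NA_character_) {
  if (is.data.frame(reads_5p)) {
    row <- reads_5p
    stopifnot(nrow(row) == 1)
    id <- row$id
    if (row$mature_arm == "5p") {
      reads_5p <- row$mature_total; reads_3p <- row$star_total
    } else {
      reads_5p <- row$star_total; reads_3p <- row$mature_total
    }
  }
  stopifnot(ratio > 1, reads_5p >= 0, reads_3p >= 0)
  total <- reads_5p + reads_3p
  if (total == 0) stop("arm_usage requires at least one read on the locus")
  dominant <- if (reads_5p >= ratio * reads_3p) "5p"
  else if (reads_3p >= ratio * reads_5p) "3p"
  else "codominant"
  structure(list(id = id, reads_5p = reads_5p, reads_3p = reads_3p,
                 fraction_5p = reads_5p / total, dominant = dominant),
            class = "arm_usage")
}

#' @export
print.arm_usage <- function(x, ...) {
  cat("arm_usage", if (!is.na(x$id)) paste0(" [", x$id, "]"), ": 5p=",
      x$reads_5p, " 3p=", x$reads_3p, " (fraction_5p=",
      round(x$fraction_5p, 3), ", ", x$dominant, ")\n", sep = "")
  invisible(x)
}

#' Detect an arm switch between two datasets
#'
#' A switch is called when both profiles are arm-dominant on opposite
#' arms; two profiles dominant on the same arm are stable; if either is
#' codominant the comparison is indeterminate. Symmetric in its
#' arguments.
#'
#' @param profile_a,profile_b [arm_usage()] profiles of the same miRNA
#'   family in two datasets/species; their `id`s must agree.
#' @return `"switch"`, `"stable"` or `"indeterminate"`.
#' @export
detect_arm_switch <- function(profile_a, profile_b) {
  stopifnot(inherits(profile_a, "arm_usage"), inherits(profile_b, "arm_usage"))
  if (!is.na(profile_a$id) && !is.na(profile_b$id) &&
      profile_a$id != profile_b$id)
    stop("profiles describe different families: ", profile_a$id, " vs ",
         profile_b$id)
  if (profile_a$dominant == "codominant" || profile_b$dominant == "codominant")
    return("indeterminate")
  if (profile_a$dominant == profile_b$dominant) "stable" else "switch"
}

#' 5'-isomiR profile of one miRNA species
#'
#' Catalogues read counts by 5'-start offset relative to the annotated
#' 5' end (offsets beyond `window` are not isomiRs and are ignored) and
#' computes the 5' fidelity: the fraction of in-window reads sharing
#' the modal start.
#'
#' @param offset_counts named numeric vector of read counts keyed by
#'   offset (e.g. `c("-1"=2, "0"=40, "1"=5)`), or a data.frame with
#'   columns `offset`, `count`.
#' @param species `"mature"` or `"star"`.
#' @param id locus identifier.
#' @param window maximum |offset| retained (default 2).
#' @return object of class `isomir_profile`: list with `id`, `species`,
#'   `start_offsets` (counts by offset), `fidelity` and
#'   `secondary_offsets` (next-ranked offsets by count).
#' @export
isomir_profile <- function(offset_counts, species = "mature",
                           id = NA_character_, window = 2L) {
  if (is.data.frame(offset_counts))
    offset_counts <- stats::setNames(offset_counts$count, offset_counts$offset)
  offs <- as.integer(names(offset_counts))
  keep <- abs(offs) <= window & offset_counts > 0
  offset_counts <- offset_counts[keep]
  offs <- offs[keep]
  if (!length(offset_counts) || sum(offset_counts) == 0)
    stop("no reads within ", window, " nt of the annotated 5' end")
  ord <- order(-offset_counts, abs(offs), offs)
  structure(list(id = id, species = match.arg(species, c("mature", "star")),
                 start_offsets = offset_counts[ord],
                 fidelity = max(offset_counts) / sum(offset_counts),
                 secondary_offsets = offs[ord][-1]),
            class = "isomir_profile")
}

#' @export
print.isomir_profile <- function(x, ...) {
  cat("isomir_profile [", x$species, "]: fidelity ", round(x$fidelity, 3),
      "; offsets: ", paste(names(x$start_offsets), x$start_offsets,
                           sep = ":", collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Offset spectra of mapped stacks around a called locus
#'
#' Helper that turns a [call_loci()] result plus the mapped tag stacks
#' into per-locus 5'-offset count tables for the mature and star
#' species, ready for [isomir_profile()].
#'
#' @param locus one row of `call_loci()$loci`.
#' @param hits mapped tag hits (from [map_exact()]) joined with per-tag
#'   total counts in a `total` column.
#' @param window offset window.
#' @return list with `mature` and `star` named count vectors.
#' @export
locus_offset_spectra <- function(locus, hits, window = 2L) {
  spec <- function(arm_start, arm_end) {
    h <- hits[hits$seqname == locus$seqname & hits$strand == locus$strand, ,
              drop = FALSE]
    bio5 <- if (locus$strand == "+") h$start else h$end
    ref5 <- if (locus$strand == "+") arm_start else arm_end
    off <- if (locus$strand == "+") bio5 - ref5 else ref5 - bio5
    keep <- abs(off) <= window & h$start < arm_end & arm_start < h$end
    tapply(h$total[keep], off[keep], sum)
  }
  list(mature = spec(locus$mature_start, locus$mature_end),
       star = spec(locus$star_start, locus$star_end))
}

#' Paired mature/star 5'-fidelity contrast
#'
#' Builds the per-locus table of (mature fidelity, star fidelity) and
#' tests whether mature 5' precision exceeds star 5' precision across
#' loci with an exact two-sided sign test on the non-tied pairs.
#'
#' @param mature_fidelity,star_fidelity numeric vectors (same length,
#'   same locus order), or a list of `isomir_profile` pairs via
#'   `mature_fidelity` with `star_fidelity = NULL`.
#' @param ids optional locus ids.
#' @return list with `table` (data.frame id, mature, star) and
#'   `p_value` (sign test; 1 when all pairs tie).
#' @export
fidelity_contrast <- function(mature_fidelity, star_fidelity = NULL, ids = NULL) {
  if (is.list(mature_fidelity) && is.null(star_fidelity)) {
    prof <- mature_fidelity
    mature_fidelity <- vapply(prof, function(p) p$mature$fidelity, numeric(1))
    star_fidelity <- vapply(prof, function(p) p$star$fidelity, numeric(1))
    if (is.null(ids)) ids <- vapply(prof, function(p) p$mature$id, character(1))
  }
  stopifnot(length(mature_fidelity) == length(star_fidelity))
  if (is.null(ids)) ids <- sprintf("locus%03d", seq_along(mature_fidelity))
  tab <- data.frame(id = ids, mature = mature_fidelity, star = star_fidelity,
                    stringsAsFactors = FALSE)
  non_tied <- tab$mature != tab$star
  p <- if (!any(non_tied)) 1 else
    binom.test(sum(tab$mature > tab$star & non_tied), sum(non_tied),
               p = 0.5)$p.value
  list(table = tab, p_value = p)
}
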
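#' Fold an RNA sequence by weighted base-pair maximisation
#'
#' Predicts a nested (pseudoknot-free) secondary structure with a
#' Nussinov-style dynamic program that maximises a weighted pair count
#' (G:C = 3, A:U = 2, G:U wobble = 1 by default) subject to a minimum
#' hairpin loop of `min_loop` unpaired bases. This captures what the
#' downstream analyses need from a precursor fold — hairpin presence and
#' the geometry of the mature/star duplex — with an exactly testable
#' optimum. `fold_engine` allows swapping in an external thermodynamic
#' folder returning the same pairing representation for cross-checks.
#'
#' @param seq RNA sequence (A/C/G/U; T is accepted and read as U).
#'   At most 400 nt (precursor scale).
#' @param min_loop minimum unpaired bases enclosed by any pair (>= 3).
#' @param weights named numeric pair weights `c(GC=, AU=, GU=)`.
#' @param fold_engine optional function(seq, min_loop) returning
#'   `list(score=, pairing=)` with a 0-based pairing vector, used in
#'   place of the built-in dynamic program.
#' @return object of class `fold_result`: list with `sequence`, `score`,
#'   `n_pairs`, `pairing` (1-based partner index per position, NA when
#'   unpaired), `structure` (dot-bracket), and `loop`, `arm5`, `arm3` —
#'   0-based half-open intervals of the dominant hairpin's terminal loop
#'   and its two arms (all NULL when the structure has no pair).
#' @export
fold <- function(seq, min_loop = 3L, weights = c(GC = 3, AU = 2, GU = 1),
                 fold_engine = NULL) {
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- dna2rna(seq)
  if (nchar(seq) > 400)
    stop("fold() is intended for precursor-scale sequences (<= 400 nt)")
  bad <- which(!strsplit(seq, "")[[1]] %in% c("A", "C", "G", "U"))
  if (length(bad))
    stop("invalid base at position ", bad[1], " of sequence")
  if (min_loop < 3) stop("min_loop must be >= 3")

  res <- if (is.null(fold_engine)) {
    nussinov_fold(seq, min_loop = as.integer(min_loop),
                  wGC = as.integer(weights[["GC"]]),
                  wAU = as.integer(weights[["AU"]]),
                  wGU = as.integer(weights[["GU"]]))
  } else {
    fold_engine(seq, min_loop)
  }

  pairing0 <- as.integer(res$pairing)          # 0-based partner, -1 unpaired
  pairing <- ifelse(pairing0 < 0, NA_integer_, pairing0 + 1L)
  n <- nchar(seq)
  db <- rep(".", n)
  paired <- which(!is.na(pairing))
  db[paired[pairing[paired] > paired]] <- "("
  db[paired[pairing[paired] < paired]] <- ")"

  anatomy <- hairpin_anatomy(pairing)
  structure(list(
    sequence = seq,
    score = res$score,
    n_pairs = length(paired) / 2,
    pairing = pairing,
    structure = paste(db, collapse = ""),
    loop = anatomy$loop,
    arm5 = anatomy$arm5,
    arm3 = anatomy$arm3
  ), class = "fold_result")
}

## Locate the dominant hairpin: among terminal loops (pairs enclosing no
## other pair), pick the one whose closing pair has the most enclosing
## ancestors (the deepest stem); arms span the ancestors' outer limits.
hairpin_anatomy <- function(pairing) {
  paired <- which(!is.na(pairing))
  if (!length(paired)) return(list(loop = NULL, arm5 = NULL, arm3 = NULL))
  op <- paired[pairing[paired] > paired]       # opening positions (1-based)
  cl <- pairing[op]
  # terminal loops: opening pairs with no paired position strictly inside
  is_term <- vapply(seq_along(op), function(t) {
    i <- op[t]; j <- cl[t]
    !any(paired > i & paired < j)
  }, logical(1))
  if (!any(is_term)) return(list(loop = NULL, arm5 = NULL, arm3 = NULL))
  topen <- op[is_term]; tclose <- cl[is_term]
  depth <- vapply(seq_along(topen), function(t) {
    sum(op <= topen[t] & cl >= tclose[t])
  }, integer(1))
  best <- which.max(depth)
  i <- topen[best]; j <- tclose[best]
  anc <- op <= i & cl >= j
  outer_i <- min(op[anc]); outer_j <- max(cl[anc])
  list(
    loop = iv(i, j - 1),                       # 0-based half-open, between i and j
    arm5 = iv(outer_i - 1, i),
    arm3 = iv(j - 1, outer_j)
  )
}

#' @export
print.fold_result <- function(x, ...) {
  cat("RNA fold (", nchar(x$sequence), " nt, score ", x$score,
      ", ", x$n_pairs, " pairs)\n", sep = "")
  cat(x$sequence, "\n", x$structure, "\n", sep = "")
  invisible(x)
}

#' Geometry of the mature/star duplex within a folded precursor
#'
#' Measures the two quantities used to validate a candidate pre-miRNA
#' duplex: `space`, the number of nucleotides strictly between the
#' loop-proximal ends of the mature and star intervals, and `max_bulge`,
#' the longest contiguous run of positions unpaired to the opposite arm
#' within the duplex region on either strand. Also reports
#' `paired_fraction`, the fraction of mature positions paired into the
#' star interval.
#'
#' @param fold a [fold()] result for the precursor.
#' @param mature,star 0-based half-open intervals of the two arms on the
#'   precursor; they must not overlap.
#' @return list with `space`, `max_bulge`, `paired_fraction`.
#' @export
duplex_geometry <- function(fold, mature, star) {
  stopifnot(inherits(fold, "fold_result"))
  if (iv_overlaps(mature, star)) stop("mature and star intervals overlap")
  five <- if (mature[1] < star[1]) mature else star
  three <- if (mature[1] < star[1]) star else mature
  space <- unname(three[1] - five[2])

  pairing <- fold$pairing
  mpos <- (mature[1] + 1):mature[2]            # 1-based positions
  spos <- (star[1] + 1):star[2]
  m_partner <- pairing[mpos]
  s_partner <- pairing[spos]
  m_cross <- !is.na(m_partner) & m_partner %in% spos
  s_cross <- !is.na(s_partner) & s_partner %in% mpos
  paired_fraction <- mean(m_cross)

  max_run <- function(cross) {
    hit <- which(cross)
    if (length(hit) < 2) return(if (length(hit)) sum(!cross) else length(cross))
    inner <- cross[min(hit):max(hit)]
    r <- rle(!inner)
    runs <- r$lengths[r$values]
    if (length(runs)) max(runs) else 0L
  }
  max_bulge <- max(max_run(m_cross), max_run(s_cross))
  list(space = as.integer(space),
       max_bulge = as.integer(max_bulge),
       paired_fraction = paired_fraction)
}
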
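## Internal sequence / interval helpers.
## Intervals throughout the package are 0-based half-open c(start, end).

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement DNA sequences
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
rc_dna <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Convert between DNA and RNA alphabets
#'
#' `dna2rna()` replaces T with U; `rna2dna()` replaces U with T. Both
#' uppercase their input.
#'
#' @param x character vector.
#' @return character vector in the other alphabet.
#' @export
dna2rna <- function(x) chartr("Tt", "UU", toupper(x))

#' @rdname dna2rna
#' @export
rna2dna <- function(x) chartr("Uu", "TT", toupper(x))

## Random DNA string of length n using the session RNG.
random_dna <- function(n, bases = DNA_BASES) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

## 0-based half-open interval constructor with sanity checks.
iv <- function(start, end) {
  stopifnot(length(start) == 1, length(end) == 1, end >= start, start >= 0)
  c(start = as.integer(start), end = as.integer(end))
}

iv_len <- function(x) unname(x[2] - x[1])

iv_overlaps <- function(a, b) a[1] < b[2] && b[1] < a[2]

## Extract a 0-based half-open substring from a sequence string.
subseq0 <- function(seq, start, end) substr(seq, start + 1, end)

#' Convert 0-based half-open intervals to a GFF3-style GRanges
#'
#' The package works in 0-based half-open coordinates; GFF3 is 1-based
#' and closed, so starts shift by +1 and ends are unchanged.
#'
#' @param df data.frame with columns `seqname`, `start`, `end`, `strand`
#'   (0-based half-open) and any metadata columns.
#' @return a [GenomicRanges::GRanges] suitable for GFF3 export via
#'   rtracklayer.
#' @export
intervals_to_granges <- function(df) {
  meta <- df[, setdiff(names(df), c("seqname", "start", "end", "strand")),
             drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqname,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = ifelse(is.na(df$strand) | df$strand == "", "*", df$strand)
  )
  if (ncol(meta)) S4Vectors::mcols(gr) <- meta
  gr
}

#' Convert a GRanges back to 0-based half-open intervals
#'
#' Inverse of [intervals_to_granges()].
#'
#' @param gr a [GenomicRanges::GRanges].
#' @return data.frame with `seqname`, `start`, `end`, `strand` columns
#'   (0-based half-open) plus metadata columns.
#' @export
granges_to_intervals <- function(gr) {
  out <- data.frame(
    seqname = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  meta <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(meta)) out <- cbind(out, meta)
  out
}

## Pair weight of RNA base pairs: G:C = 3, A:U = 2, G:U wobble = 1,
## otherwise 0 (mirrors the folding weights). Vectorised.
pair_weight <- function(a, b) {
  k <- paste0(a, b)
  ifelse(k %in% c("GC", "CG"), 3,
         ifelse(k %in% c("AU", "UA"), 2,
                ifelse(k %in% c("GU", "UG"), 1, 0)))
}

## Deterministic TSV writer (no quoting surprises, no row names).
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
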
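#' Build a genome index for exact read mapping and word-seeded search
#'
#' Wraps one or more genome sequences as a [Biostrings::DNAStringSet]
#' together with the word length used for seeded homology search.
#' Read mapping is full-length exact matching (zero mismatches) on both
#' strands; homology search seeds on `k`-mer words.
#'
#' @param sequences named character vector of DNA sequences, a
#'   `DNAStringSet`, or the path to a FASTA file.
#' @param k word length for seeded homology search (default 7).
#' @return object of class `genome_index`.
#' @export
genome_index <- function(sequences, k = 7L) {
  if (is.character(sequences) && length(sequences) == 1 &&
      file.exists(sequences) && is.null(names(sequences))) {
    sequences <- Biostrings::readDNAStringSet(sequences)
    names(sequences) <- sub("\\s.*$", "", names(sequences))
  }
  if (is.character(sequences)) {
    if (is.null(names(sequences)) && length(sequences))
      names(sequences) <- paste0("seq", seq_along(sequences))
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  }
  stopifnot(methods::is(sequences, "DNAStringSet"))
  structure(list(sequences = sequences, k = as.integer(k)),
            class = "genome_index")
}

#' @export
print.genome_index <- function(x, ...) {
  cat("genome_index: ", length(x$sequences), " sequence(s), ",
      sum(Biostrings::width(x$sequences)), " nt total, word size k=",
      x$k, "\n", sep = "")
  invisible(x)
}

#' Map reads to a genome with zero mismatches
#'
#' Reports every full-length exact occurrence of each read on both
#' strands of the indexed genome. Reads containing N (or any non-ACGT
#' character) map nowhere. Hits are ordered deterministically by
#' sequence name, then start, then strand (`+` before `-`).
#'
#' @param reads character vector of DNA reads (18-30 nt).
#' @param index a [genome_index()].
#' @return data.frame with columns `read` (index into `reads`),
#'   `sequence` (read string), `seqname`, `start`, `end` (0-based
#'   half-open, forward-strand coordinates), `strand`.
#' @export
map_exact <- function(reads, index) {
  stopifnot(inherits(index, "genome_index"))
  reads <- toupper(reads)
  empty <- data.frame(read = integer(0), sequence = character(0),
                      seqname = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
  if (!length(reads) || !length(index$sequences)) return(empty)
  w <- nchar(reads)
  if (any(w < 18 | w > 30))
    stop("reads must be 18-30 nt (got length ", w[which(w < 18 | w > 30)[1]], ")")
  mappable <- grepl("^[ACGT]+$", reads)

  out <- list()
  seqnames <- names(index$sequences)
  for (width in sort(unique(w[mappable]))) {
    idx <- which(mappable & w == width)
    pats <- Biostrings::DNAStringSet(reads[idx])
    pd_fwd <- Biostrings::PDict(pats)
    pd_rev <- Biostrings::PDict(Biostrings::reverseComplement(pats))
    for (s in seq_along(index$sequences)) {
      subject <- index$sequences[[s]]
      gather <- function(pd, strand) {
        si <- Biostrings::startIndex(Biostrings::matchPDict(pd, subject))
        n_per <- vapply(si, length, integer(1))
        if (!sum(n_per)) return(NULL)
        starts <- unlist(si[n_per > 0], use.names = FALSE)
        rid <- rep(idx[n_per > 0], n_per[n_per > 0])
        data.frame(read = rid, sequence = reads[rid], seqname = seqnames[s],
                   start = starts - 1L, end = starts - 1L + width,
                   strand = strand, stringsAsFactors = FALSE)
      }
      fwd <- gather(pd_fwd, "+")
      if (!is.null(fwd)) out[[length(out) + 1]] <- fwd
      # revcomp(read) matching forward means the read lies on '-'
      rev <- gather(pd_rev, "-")
      if (!is.null(rev)) out[[length(out) + 1]] <- rev
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$seqname, res$start, res$strand, res$read), ]
  rownames(res) <- NULL
  res
}

#' Locations of a k-mer word on both strands of an indexed genome
#'
#' Used as the seeding step of homology search.
#'
#' @param index a [genome_index()].
#' @param word DNA word of length `index$k` (any length is accepted).
#' @return data.frame `seqname`, `start` (0-based), `strand`.
#' @keywords internal
word_hits <- function(index, word) {
  word <- toupper(word)
  out <- list()
  pat <- Biostrings::DNAString(word)
  rcp <- Biostrings::reverseComplement(pat)
  for (s in seq_along(index$sequences)) {
    subject <- index$sequences[[s]]
    fw <- Biostrings::start(Biostrings::matchPattern(pat, subject))
    rv <- Biostrings::start(Biostrings::matchPattern(rcp, subject))
    if (length(fw))
      out[[length(out) + 1]] <- data.frame(
        seqname = names(index$sequences)[s], start = fw - 1L, strand = "+",
        stringsAsFactors = FALSE)
    if (length(rv))
      out[[length(out) + 1]] <- data.frame(
        seqname = names(index$sequences)[s], start = rv - 1L, strand = "-",
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(seqname = character(0), start = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
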
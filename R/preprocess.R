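## Read cleaning: adapter trimming, length filtering, collapsing to
## unique tags with per-library counts, and removal of tags matching
## known ncRNA / known-miRNA reference sets.

#' Read small-RNA reads from FASTA or FASTQ
#'
#' @param path file path; format is taken from the extension
#'   (`.fq`/`.fastq` vs anything else) unless given.
#' @param format `"auto"`, `"fasta"` or `"fastq"`.
#' @return character vector of read sequences.
#' @export
read_reads <- function(path, format = "auto") {
  if (format == "auto")
    format <- if (grepl("\\.f(ast)?q(\\.gz)?$", path)) "fastq" else "fasta"
  as.character(Biostrings::readDNAStringSet(path, format = format))
}

#' Trim a 3' adapter from reads
#'
#' Removes the adapter at the first full occurrence in the read, or a
#' terminal partial match of at least `min_overlap` bases at the read's
#' 3' end. Reads with no adapter evidence pass through unchanged.
#'
#' @param reads character vector of read sequences.
#' @param adapter adapter sequence (non-empty).
#' @param min_overlap minimum terminal overlap for a partial match.
#' @return character vector of trimmed reads (same length as input).
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 4L) {
  if (!nzchar(adapter)) stop("adapter must be non-empty")
  adapter <- toupper(adapter)
  vapply(toupper(reads), function(r) {
    hit <- regexpr(adapter, r, fixed = TRUE)
    if (hit > 0) return(substr(r, 1, hit - 1))
    n <- nchar(r)
    kmax <- min(nchar(adapter) - 1, n)
    if (kmax >= min_overlap) {
      for (k in seq(kmax, min_overlap, by = -1)) {
        if (substr(r, n - k + 1, n) == substr(adapter, 1, k))
          return(substr(r, 1, n - k))
      }
    }
    r
  }, character(1), USE.NAMES = FALSE)
}

#' Filter reads or tags by length
#'
#' Boundary-inclusive: sequences with `min_len <= length <= max_len`
#' are kept.
#'
#' @param x character vector of sequences, or a tag data.frame with a
#'   `sequence` column.
#' @param min_len,max_len inclusive length bounds (defaults 18 and 30).
#' @return filtered object of the same shape.
#' @export
length_filter <- function(x, min_len = 18L, max_len = 30L) {
  if (is.data.frame(x)) {
    keep <- nchar(x$sequence) >= min_len & nchar(x$sequence) <= max_len
    out <- x[keep, , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  x[nchar(x) >= min_len & nchar(x) <= max_len]
}

#' Collapse reads to unique tags with per-library counts
#'
#' @param reads_by_library named list of character vectors (one per
#'   library), or a single character vector (treated as one library).
#' @return data.frame with `sequence`, one `count_<library>` column per
#'   library, and `total`; sorted by total descending, then sequence.
#'   The per-library count sums equal the input read numbers.
#' @export
collapse_tags <- function(reads_by_library) {
  if (!is.list(reads_by_library)) reads_by_library <- list(lib1 = reads_by_library)
  libs <- names(reads_by_library)
  all_seq <- sort(unique(unlist(reads_by_library, use.names = FALSE)))
  counts <- vapply(reads_by_library, function(r) {
    tab <- table(factor(r, levels = all_seq))
    as.integer(tab)
  }, integer(length(all_seq)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = length(all_seq))
  colnames(counts) <- paste0("count_", libs)
  out <- data.frame(sequence = all_seq, counts, stringsAsFactors = FALSE,
                    check.names = FALSE)
  out$total <- as.integer(rowSums(counts))
  out <- out[order(-out$total, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## classes in precedence order for multi-hit annotation
KNOWN_CLASSES <- c("known_miRNA", "rRNA", "tRNA", "snRNA", "snoRNA")

#' Annotate tags against known ncRNA / miRNA reference sets
#'
#' A tag is annotated with a reference class when its sequence (or its
#' reverse complement) is an exact substring of any reference sequence
#' of that class — consistent with zero-mismatch mapping. Tags hitting
#' multiple classes take the highest-precedence one
#' (known_miRNA > rRNA > tRNA > snRNA > snoRNA); tags hitting none are
#' `clean`. Non-clean tags are excluded from discovery via
#' [clean_tags()].
#'
#' @param tags tag data.frame from [collapse_tags()].
#' @param references named list; names are reference classes (any
#'   subset of `known_miRNA`, `rRNA`, `tRNA`, `snRNA`, `snoRNA`),
#'   values are character vectors of reference sequences or FASTA paths.
#' @return `tags` with an `annotation` column added.
#' @export
annotate_known <- function(tags, references) {
  bad <- setdiff(names(references), KNOWN_CLASSES)
  if (length(bad))
    stop("unknown reference class(es): ", paste(bad, collapse = ", "))
  refs <- lapply(names(references), function(cl) {
    r <- references[[cl]]
    if (is.character(r) && length(r) == 1 && file.exists(r) &&
        grepl("\\.(fa|fasta|fna)$", r))
      r <- as.character(Biostrings::readDNAStringSet(r))
    if (!length(r)) stop("empty reference set for class '", cl, "'")
    Biostrings::DNAStringSet(toupper(rna2dna(r)))
  })
  names(refs) <- names(references)

  ann <- rep("clean", nrow(tags))
  if (nrow(tags)) {
    for (cl in intersect(KNOWN_CLASSES, names(refs))) {
      todo <- which(ann == "clean")
      if (!length(todo)) break
      hit <- vapply(tags$sequence[todo], function(s) {
        pat <- Biostrings::DNAString(rna2dna(s))
        any(Biostrings::vcountPattern(pat, refs[[cl]]) > 0) ||
          any(Biostrings::vcountPattern(Biostrings::reverseComplement(pat),
                                        refs[[cl]]) > 0)
      }, logical(1), USE.NAMES = FALSE)
      ann[todo[hit]] <- cl
    }
  }
  tags$annotation <- ann
  tags
}

#' Keep only clean (unannotated) tags
#'
#' @param tags annotated tag data.frame.
#' @return tags with `annotation == "clean"` (tags without an
#'   annotation column are returned unchanged).
#' @export
clean_tags <- function(tags) {
  if (is.null(tags$annotation)) return(tags)
  out <- tags[tags$annotation == "clean", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write collapsed tags to FASTA and/or a TSV count table
#'
#' FASTA headers follow the conventional `tag{i}_x{count}` form, with
#' the total read count after the `x`.
#'
#' @param tags tag data.frame from [collapse_tags()].
#' @param fasta,tsv output paths (either may be NULL).
#' @return invisibly, the tag data.frame.
#' @export
write_tags <- function(tags, fasta = NULL, tsv = NULL) {
  if (!is.null(fasta)) {
    ds <- Biostrings::DNAStringSet(tags$sequence)
    names(ds) <- sprintf("tag%d_x%d", seq_len(nrow(tags)), tags$total)
    Biostrings::writeXStringSet(ds, fasta)
  }
  if (!is.null(tsv)) write_tsv(tags, tsv)
  invisible(tags)
}

#' Run the full preprocessing stage
#'
#' Adapter trimming (optional), length filtering, collapsing and
#' known-class annotation, with a per-library audit of reads kept and
#' removed.
#'
#' @param reads_by_library named list of read vectors.
#' @param adapter optional 3' adapter to trim.
#' @param min_len,max_len length filter bounds.
#' @param references optional reference sets for [annotate_known()].
#' @param min_overlap adapter trimming overlap.
#' @return list with `tags` (annotated), `clean` (clean tags only) and
#'   `stats` (per-library input/kept counts).
#' @export
preprocess_reads <- function(reads_by_library, adapter = NULL,
                             min_len = 18L, max_len = 30L,
                             references = NULL, min_overlap = 4L) {
  if (!is.list(reads_by_library)) reads_by_library <- list(lib1 = reads_by_library)
  input_n <- vapply(reads_by_library, length, integer(1))
  if (!is.null(adapter))
    reads_by_library <- lapply(reads_by_library, trim_adapter, adapter = adapter,
                               min_overlap = min_overlap)
  filtered <- lapply(reads_by_library, length_filter, min_len = min_len,
                     max_len = max_len)
  kept_n <- vapply(filtered, length, integer(1))
  tags <- collapse_tags(filtered)
  if (!is.null(references)) tags <- annotate_known(tags, references)
  else tags$annotation <- rep("clean", nrow(tags))
  list(tags = tags, clean = clean_tags(tags),
       stats = data.frame(library = names(input_n), input = input_n,
                          length_kept = kept_n,
                          length_dropped = input_n - kept_n,
                          row.names = NULL, stringsAsFactors = FALSE))
}
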
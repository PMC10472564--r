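#' Genome assembly container
#'
#' A `genome_assembly` holds uppercase DNA sequences together with a
#' per-position soft-mask flag (positions that were lowercase in the input
#' FASTA, i.e. repeat-masked). Internally all coordinates in this package are
#' 0-based half-open; conversion to the 1-based inclusive convention of
#' GFF/GTF/GenBank happens only in the readers and writers.
#'
#' @param sequences named character vector of DNA sequences (A/C/G/T/N,
#'   lowercase allowed and interpreted as soft-masking).
#' @return an object of class `genome_assembly`: a list with elements
#'   `seq` (named uppercase character vector) and `mask` (named list of
#'   logical vectors, `TRUE` where the input was soft-masked).
#' @export
genome_assembly <- function(sequences) {
  ids <- names(sequences)
  if (is.null(ids) || any(ids == "")) stopf("all sequences must be named")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stopf("duplicate seq_id %s", dup[[1L]])
  empty <- ids[nchar(sequences) == 0L]
  if (length(empty)) stopf("empty sequence for record %s", empty[[1L]])
  mask <- lapply(sequences, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    ch %in% c("a", "c", "g", "t", "n")
  })
  seqs <- toupper(sequences)
  bad <- vapply(seqs, function(s) grepl("[^ACGTN]", s), logical(1L))
  if (any(bad)) stopf("non-DNA characters in sequence %s", ids[bad][[1L]])
  structure(list(seq = seqs, mask = mask), class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf("genome_assembly: %d sequence(s), %s bp total\n",
              length(x$seq), format(sum(nchar(x$seq)), big.mark = ",")))
  invisible(x)
}

#' Sequence lengths of an assembly
#' @param assembly a `genome_assembly`
#' @return named integer vector of sequence lengths (bp)
#' @export
seq_lengths <- function(assembly) {
  stopifnot(inherits(assembly, "genome_assembly"))
  vapply(assembly$seq, nchar, integer(1L))
}

#' Read a (soft-masked) FASTA assembly
#'
#' Lowercase residues are folded to uppercase with the mask retained per
#' position. Duplicate record ids and empty records are hard errors.
#'
#' @param path path to a FASTA file
#' @return a [genome_assembly()]
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  # BStringSet preserves case so the soft-mask can be recovered
  raw <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(raw))
  seqs <- as.character(raw)
  names(seqs) <- ids
  genome_assembly(seqs)
}

#' Write an assembly to FASTA
#'
#' Soft-masked positions are written back as lowercase.
#'
#' @param assembly a [genome_assembly()]
#' @param path output path
#' @param width line width
#' @export
write_genome_fasta <- function(assembly, path, width = 60L) {
  stopifnot(inherits(assembly, "genome_assembly"))
  out <- vapply(names(assembly$seq), function(id) {
    ch <- strsplit(assembly$seq[[id]], "", fixed = TRUE)[[1L]]
    m <- assembly$mask[[id]]
    ch[m] <- tolower(ch[m])
    paste0(ch, collapse = "")
  }, character(1L))
  Biostrings::writeXStringSet(Biostrings::BStringSet(out), path, width = width)
  invisible(path)
}

#' Extract a window of an assembly sequence
#'
#' @param assembly a [genome_assembly()]
#' @param seq_id sequence id
#' @param start,end 0-based half-open window
#' @return character scalar (uppercase)
#' @export
subseq_window <- function(assembly, seq_id, start, end) {
  stopifnot(inherits(assembly, "genome_assembly"))
  s <- assembly$seq[[seq_id]]
  if (is.null(s)) stopf("unknown seq_id %s", seq_id)
  if (start < 0 || end > nchar(s) || start >= end)
    stopf("window [%d,%d) out of bounds for %s (length %d)", start, end, seq_id, nchar(s))
  substr(s, start + 1L, end)
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

translate_dna <- function(s) {
  suppressWarnings(as.character(Biostrings::translate(Biostrings::DNAString(s))))
}
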
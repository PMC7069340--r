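#' Load a reference genome from FASTA
#'
#' Reads every record of a FASTA file into an in-memory reference object.
#' Soft-masked (lowercase) bases are uppercased; any character outside
#' `A,C,G,T,N` is rejected with its position.
#'
#' @param path path to a FASTA file.
#' @return an object of class `genome_ref` with elements `sequences`
#'   (named character vector, one uppercase string per chromosome) and
#'   `lengths` (named integer vector).
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop2("genome FASTA not found: %s", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop2("no records in FASTA: %s", path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) stop2("duplicate record names in FASTA: %s",
                               paste(unique(nm[duplicated(nm)]), collapse = ", "))
  seqs <- toupper(as.character(ss))
  names(seqs) <- nm
  bad <- gregexpr("[^ACGTN]", seqs)
  for (i in seq_along(bad)) {
    if (bad[[i]][1] != -1L)
      stop2("non-nucleotide character in record '%s' at position %d",
            nm[i], bad[[i]][1])
  }
  genome_ref(seqs)
}

#' Construct a genome reference from named sequences
#' @param sequences named character vector of uppercase nucleotide strings.
#' @return a `genome_ref` object.
#' @export
genome_ref <- function(sequences) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  sequences <- toupper(sequences)
  structure(list(sequences = sequences,
                 lengths = setNames(nchar(sequences), names(sequences))),
            class = "genome_ref")
}

#' @export
print.genome_ref <- function(x, ...) {
  cat(sprintf("<genome_ref> %d sequence(s), %d bp total\n",
              length(x$sequences), sum(x$lengths)))
  invisible(x)
}

#' Fetch genome bases over a 0-based half-open interval
#'
#' @param genome a `genome_ref`.
#' @param chrom chromosome name.
#' @param start0 0-based start.
#' @param end0 half-open end; `end0 - start0` bases are returned.
#' @return a single character string of length `end0 - start0`.
#' @export
genome_fetch <- function(genome, chrom, start0, end0) {
  if (!chrom %in% names(genome$sequences)) stop2("unknown chromosome: %s", chrom)
  if (start0 < 0 || end0 > genome$lengths[[chrom]] || start0 > end0)
    stop2("interval [%d,%d) out of range for %s (length %d)",
          start0, end0, chrom, genome$lengths[[chrom]])
  substr(genome$sequences[[chrom]], start0 + 1L, end0)
}

#' Write a genome reference to FASTA
#' @param genome a `genome_ref`.
#' @param path output file.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(genome$sequences)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}
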
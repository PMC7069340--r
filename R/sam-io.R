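#' Read alignments from a SAM file
#'
#' Parses a coordinate-sorted SAM file (through Rsamtools) into a data frame
#' of reads. Mapped reads are returned in coordinate order; unmapped reads
#' (flag 0x4) are returned only when `unmapped = TRUE`.
#'
#' @param path path to a SAM (or BAM) file with an `@SQ` header.
#' @param genome optional `genome_ref`; when given, header chromosomes are
#'   checked against it.
#' @param region optional list `list(chrom=, start0=, end0=)` restricting the
#'   query to reads overlapping the 0-based half-open interval.
#' @param unmapped if `TRUE`, return unmapped reads instead of mapped ones.
#' @return a data frame with one row per read: `name, flag, chrom, pos`
#'   (0-based leftmost), `mapq, cigar, seq, qual` (phred string),
#'   `n_hits` (NH tag, 1 when absent), `is_reverse`, `is_unmapped`.
#' @export
read_alignments <- function(path, genome = NULL, region = NULL, unmapped = FALSE) {
  if (!file.exists(path)) stop2("alignment file not found: %s", path)
  is_bam <- grepl("\\.bam$", path, ignore.case = TRUE)
  bam <- if (is_bam) path else sam_as_bam(path)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (length(hdr) == 0L) stop2("SAM header has no @SQ lines: %s", path)
  if (!is.null(genome)) {
    missing <- setdiff(names(hdr), names(genome$sequences))
    if (length(missing))
      stop2("SAM header chromosomes absent from genome: %s",
            paste(missing, collapse = ", "))
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = unmapped)
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual")
  param <- if (!unmapped && !is.null(region)) {
    if (!region$chrom %in% names(hdr)) stop2("region chromosome not in header: %s", region$chrom)
    gr <- GenomicRanges::GRanges(region$chrom,
                                 IRanges::IRanges(region$start0 + 1L, region$end0))
    Rsamtools::ScanBamParam(flag = flag, what = what, tag = "NH", which = gr)
  } else {
    Rsamtools::ScanBamParam(flag = flag, what = what, tag = "NH")
  }
  res <- Rsamtools::scanBam(bam, param = param)
  res <- do.call(Map, c(list(f = c), lapply(res, function(r) {
    r$seq <- as.character(r$seq); r$qual <- as.character(r$qual)
    r$rname <- as.character(r$rname)
    r$tag <- r$tag$NH %||% rep(NA_integer_, length(r$qname))
    r
  })))
  out <- data.frame(
    name = res$qname,
    flag = res$flag,
    chrom = res$rname,
    pos = res$pos - 1L,
    mapq = res$mapq,
    cigar = res$cigar,
    seq = res$seq,
    qual = res$qual,
    n_hits = ifelse(is.na(res$tag), 1L, res$tag),
    is_reverse = bitwAnd(res$flag, 16L) > 0L,
    is_unmapped = bitwAnd(res$flag, 4L) > 0L,
    stringsAsFactors = FALSE
  )
  if (!unmapped) {
    qlen <- cigar_query_length(out$cigar)
    bad <- which(qlen != nchar(out$seq))
    if (length(bad))
      stop2("CIGAR/sequence length mismatch for read '%s' (%s vs %d bases)",
            out$name[bad[1]], out$cigar[bad[1]], nchar(out$seq[bad[1]]))
    out <- out[order(match(out$chrom, names(hdr)), out$pos), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

# convert a plain SAM to a temporary sorted+indexed BAM, validating records
# first (htslib silently drops malformed lines)
sam_as_bam <- function(path) {
  dest <- file.path(tempdir(), paste0("rnaeditr_", basename(tools::file_path_sans_ext(path)),
                                      "_", substr(tools::md5sum(path), 1, 8)))
  bam <- paste0(dest, ".bam")
  if (!file.exists(bam)) {
    validate_sam_text(path)
    Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = TRUE)
  }
  bam
}

validate_sam_text <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (!length(body)) return(invisible(TRUE))
  f <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(f) < 11L))
    stop2("malformed SAM record (fewer than 11 fields): %s",
          body[which(lengths(f) < 11L)[1]])
  cigar <- vapply(f, `[[`, "", 6L)
  seq <- vapply(f, `[[`, "", 10L)
  mapped <- cigar != "*"
  mlen <- suppressWarnings(as.integer(sub("^([0-9]+)M$", "\\1", cigar)))
  simple_ok <- !is.na(mlen) & mlen == nchar(seq)
  check <- which(mapped & !simple_ok)
  for (i in check) {
    if (cigar_query_length(cigar[i]) != nchar(seq[i]))
      stop2("CIGAR/sequence length mismatch for read '%s' (%s vs %d bases)",
            f[[i]][1], cigar[i], nchar(seq[i]))
  }
  invisible(TRUE)
}

#' Parse a CIGAR string into operations
#' @param cigar a single CIGAR string.
#' @return data frame with columns `op` and `len`.
#' @keywords internal
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*") return(data.frame(op = character(), len = integer()))
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (length(ops) != length(lens) || !length(ops)) stop2("malformed CIGAR: %s", cigar)
  data.frame(op = ops, len = lens, stringsAsFactors = FALSE)
}

cigar_query_length <- function(cigar) {
  vapply(cigar, function(cg) {
    co <- parse_cigar(cg)
    sum(co$len[co$op %in% c("M", "I", "S", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Write reads to a SAM file
#'
#' Emits a minimal valid SAM with an `@SQ` header drawn from `genome`.
#' Mapped reads are coordinate-sorted before writing.
#'
#' @param reads data frame in the layout produced by [read_alignments()].
#' @param genome a `genome_ref` supplying `@SQ` lines.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome$lengths), genome$lengths))
  mapped <- reads[!reads$is_unmapped, , drop = FALSE]
  un <- reads[reads$is_unmapped, , drop = FALSE]
  if (nrow(mapped))
    mapped <- mapped[order(match(mapped$chrom, names(genome$lengths)), mapped$pos), , drop = FALSE]
  fmt <- function(r) {
    if (nrow(r) == 0L) return(character())
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tNH:i:%d",
            r$name, r$flag,
            ifelse(r$is_unmapped, "*", r$chrom),
            ifelse(r$is_unmapped, 0L, r$pos + 1L),
            ifelse(r$is_unmapped, 0L, r$mapq),
            ifelse(r$is_unmapped, "*", r$cigar),
            r$seq, r$qual, r$n_hits)
  }
  writeLines(c(hdr, fmt(mapped), fmt(un)), path)
  invisible(path)
}
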
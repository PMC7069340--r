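#' Read a known-site catalog
#'
#' Loads a REDIportal-style TSV of known A-to-I editing positions. Required
#' columns: `chrom`, `position` (1-based), `strand` (`+`/`-`). Optional:
#' `recoding` (yes/no or TRUE/FALSE, default no), `aa_change`, `gene`.
#' Every entry must have reference base A on its annotated strand; when a
#' `genome` is supplied this is verified against the sequence.
#'
#' @param path TSV file with a header line.
#' @param genome optional `genome_ref` used to validate the reference base.
#' @return data frame of class `site_catalog`: `chrom, pos` (0-based
#'   internal), `strand, recoding, aa_change, gene`.
#' @export
read_site_catalog <- function(path, genome = NULL) {
  if (!file.exists(path)) stop2("site catalog not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom", "position", "strand")
  if (!all(need %in% names(df)))
    stop2("site catalog must have columns %s", paste(need, collapse = ", "))
  site_catalog(
    chrom = as.character(df$chrom),
    pos1 = as.integer(df$position),
    strand = as.character(df$strand),
    recoding = parse_flag(df$recoding %||% rep(FALSE, nrow(df))),
    aa_change = as.character(df$aa_change %||% rep(NA_character_, nrow(df))),
    gene = as.character(df$gene %||% rep(NA_character_, nrow(df))),
    genome = genome
  )
}

parse_flag <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  tolower(as.character(x)) %in% c("yes", "true", "1", "y")
}

#' Construct a site catalog
#' @param chrom,pos1,strand vectors of chromosome, 1-based position, strand.
#' @param recoding logical recoding flag (default all `FALSE`).
#' @param aa_change,gene optional annotation labels.
#' @param genome optional `genome_ref`; entries whose annotated-strand
#'   reference base is not A are rejected.
#' @return a `site_catalog` data frame (0-based `pos`).
#' @export
site_catalog <- function(chrom, pos1, strand, recoding = NULL,
                         aa_change = NULL, gene = NULL, genome = NULL) {
  n <- length(chrom)
  df <- data.frame(chrom = chrom, pos = as.integer(pos1) - 1L, strand = strand,
                   recoding = recoding %||% rep(FALSE, n),
                   aa_change = aa_change %||% rep(NA_character_, n),
                   gene = gene %||% rep(NA_character_, n),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (!all(df$strand %in% c("+", "-")))
      stop2("catalog strand must be '+' or '-'")
    key <- paste(df$chrom, df$pos)
    if (anyDuplicated(key))
      stop2("duplicate catalog position: %s", key[duplicated(key)][1])
    if (!is.null(genome)) {
      ref <- mapply(function(ch, p) genome_fetch(genome, ch, p, p + 1L),
                    df$chrom, df$pos)
      ref_on_strand <- ifelse(df$strand == "+", ref, comp_base(ref))
      bad <- which(ref_on_strand != "A")
      if (length(bad))
        stop2("catalog entry %s:%d has reference '%s' on strand %s (A required)",
              df$chrom[bad[1]], df$pos[bad[1]] + 1L, ref[bad[1]], df$strand[bad[1]])
    }
  }
  class(df) <- c("site_catalog", "data.frame")
  df
}

#' Read a SNP exclusion set
#'
#' Accepts either a VCF (positions taken from CHROM/POS of every record,
#' regardless of variant class) or a two-column TSV `chrom<TAB>position`.
#' With `snv_only = TRUE`, VCF records whose REF or ALT is longer than one
#' base are skipped.
#'
#' @param path VCF (`.vcf`) or TSV file.
#' @param snv_only restrict VCF input to single-nucleotide records.
#' @return data frame of class `snp_set` with `chrom` and `pos` (0-based).
#' @export
read_snp_sites <- function(path, snv_only = FALSE) {
  if (!file.exists(path)) stop2("SNP file not found: %s", path)
  lines <- readLines(path)
  is_vcf <- any(startsWith(lines, "##fileformat=VCF")) || grepl("\\.vcf$", path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) == 0L) return(snp_set(character(), integer()))
  fields <- strsplit(body, "\t", fixed = TRUE)
  if (is_vcf) {
    nf <- lengths(fields)
    if (any(nf < 5L))
      stop2("malformed VCF line %d: fewer than 5 fields",
            which(!startsWith(lines, "#") & nzchar(lines))[which(nf < 5L)[1]])
    chrom <- vapply(fields, `[[`, "", 1L)
    pos1 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
    if (anyNA(pos1))
      stop2("malformed VCF line %d: non-numeric POS",
            which(!startsWith(lines, "#") & nzchar(lines))[which(is.na(pos1))[1]])
    if (snv_only) {
      ref <- vapply(fields, `[[`, "", 4L)
      alt <- vapply(fields, `[[`, "", 5L)
      keep <- nchar(ref) == 1L &
        vapply(strsplit(alt, ",", fixed = TRUE),
               function(a) all(nchar(a) == 1L & a != "*"), logical(1))
      chrom <- chrom[keep]; pos1 <- pos1[keep]
    }
  } else {
    if (any(lengths(fields) < 2L)) stop2("SNP TSV needs two columns: chrom, position")
    chrom <- vapply(fields, `[[`, "", 1L)
    pos1 <- as.integer(vapply(fields, `[[`, "", 2L))
    # tolerate a header row
    if (is.na(pos1[1]) && length(pos1) >= 1L) { chrom <- chrom[-1]; pos1 <- pos1[-1] }
    if (anyNA(pos1)) stop2("non-numeric position in SNP TSV")
  }
  snp_set(chrom, pos1)
}

#' Construct a SNP set
#' @param chrom chromosome names.
#' @param pos1 1-based positions.
#' @return a `snp_set` data frame (0-based `pos`, unique positions).
#' @export
snp_set <- function(chrom, pos1) {
  df <- unique(data.frame(chrom = as.character(chrom),
                          pos = as.integer(pos1) - 1L,
                          stringsAsFactors = FALSE))
  rownames(df) <- NULL
  class(df) <- c("snp_set", "data.frame")
  df
}

#' Test membership in a SNP set
#' @param snps a `snp_set`.
#' @param chrom,pos chromosome and 0-based position vectors.
#' @return logical vector.
#' @export
snp_member <- function(snps, chrom, pos) {
  paste(chrom, pos) %in% paste(snps$chrom, snps$pos)
}

#' Read stranded intervals from BED
#'
#' Reads BED3+ (0-based half-open) into a `GRanges`. A 6th column supplies
#' the strand; absent strand defaults to `+`.
#'
#' @param path BED file.
#' @return a [GenomicRanges::GRanges] object.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop2("BED file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
  if (!length(lines))
    return(GenomicRanges::GRanges())
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 3L)) stop2("BED needs at least 3 columns")
  chrom <- vapply(f, `[[`, "", 1L)
  start0 <- as.integer(vapply(f, `[[`, "", 2L))
  end0 <- as.integer(vapply(f, `[[`, "", 3L))
  if (any(start0 >= end0)) stop2("BED interval with start >= end")
  strand <- vapply(f, function(x) if (length(x) >= 6L) x[[6]] else "+", "")
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0), strand = strand)
}

#' Write stranded intervals to BED
#' @param gr a `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start0 = GenomicRanges::start(gr) - 1L,
                   end0 = GenomicRanges::end(gr),
                   name = ".", score = 0L,
                   strand = as.character(GenomicRanges::strand(gr)))
  df$strand[df$strand == "*"] <- "+"
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

SITE_TABLE_VERSION <- "rnaeditr-site-table-v1"

#' Write a site-call table
#'
#' Emits calls as TSV (1-based positions) with a version comment line.
#' The table round-trips losslessly through [read_site_table()].
#'
#' @param calls a `site_calls` data frame (see [call_stage_A()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(calls, path) {
  cols <- c("chrom", "pos", "ref", "strand", "coverage",
            "A", "C", "G", "T", "freq", "stages")
  out <- as.data.frame(calls)[, cols, drop = FALSE]
  out$pos <- out$pos + 1L
  names(out)[names(out) == "pos"] <- "position"
  out$freq <- sprintf("%.4f", out$freq)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", SITE_TABLE_VERSION), con)
  suppressWarnings(write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE))
  invisible(path)
}

#' Read a site-call table written by [write_site_table()]
#' @param path TSV path.
#' @return a `site_calls` data frame (0-based `pos`).
#' @export
read_site_table <- function(path) {
  if (!file.exists(path)) stop2("site table not found: %s", path)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  df$pos <- as.integer(df$position) - 1L
  df$position <- NULL
  df$freq <- as.numeric(df$freq)
  df$stages <- as.character(df$stages)
  df <- df[, c("chrom", "pos", "ref", "strand", "coverage",
               "A", "C", "G", "T", "freq", "stages")]
  class(df) <- c("site_calls", "data.frame")
  df
}
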
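#' Per-base filter configuration
#'
#' Filters applied to every base before it is counted in a pileup: minimum
#' base quality (phred 30 by default, ~0.1% error), exclusion of the first
#' and last `read_end_trim` bases of each read (measured on the query, so
#' soft-clipped bases count toward the end distance), and a minimum mapping
#' quality below which a read is tallied but not counted.
#'
#' @param min_base_qual minimum phred base quality (default 30).
#' @param read_end_trim bases excluded at each read end (default 6: query
#'   offsets 1..6 and the last 6 are never counted).
#' @param min_mapq minimum mapping quality for a read to contribute (default 20).
#' @return a `base_filter_config` list.
#' @export
base_filter_config <- function(min_base_qual = 30L, read_end_trim = 6L, min_mapq = 20L) {
  stopifnot(is_count(min_base_qual), is_count(read_end_trim), is_count(min_mapq))
  structure(list(min_base_qual = as.integer(min_base_qual),
                 read_end_trim = as.integer(read_end_trim),
                 min_mapq = as.integer(min_mapq)),
            class = "base_filter_config")
}

# walk one CIGAR: (1-based query offset, 0-based ref position) aligned pairs
aligned_pairs <- function(pos, cigar) {
  co <- parse_cigar(cigar)
  qoff <- 0L; roff <- pos
  qp <- vector("list", nrow(co)); rp <- vector("list", nrow(co))
  for (k in seq_len(nrow(co))) {
    op <- co$op[k]; len <- co$len[k]
    if (op %in% c("M", "=", "X")) {
      qp[[k]] <- qoff + seq_len(len); rp[[k]] <- roff + seq_len(len) - 1L
      qoff <- qoff + len; roff <- roff + len
    } else if (op %in% c("I", "S")) {
      qoff <- qoff + len
    } else if (op %in% c("D", "N")) {
      roff <- roff + len
    } # H, P: consume nothing
  }
  list(qpos = unlist(qp) %||% integer(), rpos = unlist(rp) %||% integer())
}

#' Strand-aware pileup with per-base filters
#'
#' Converts aligned reads into per-position nucleotide tallies. A base is
#' counted only if its phred quality is at least `cfg$min_base_qual` and its
#' query offset is more than `cfg$read_end_trim` positions from both read
#' ends. Reads with mapping quality below `cfg$min_mapq` contribute to the
#' `low_mapq` tally only. Deletions, reference skips and insertions
#' contribute nothing. Only positions with at least one surviving base are
#' emitted (use [count_at_sites()] for a fixed site list including
#' zero-coverage sites).
#'
#' @param reads data frame from [read_alignments()], coordinate-sorted.
#' @param genome a `genome_ref`.
#' @param region optional `list(chrom=, start0=, end0=)` restriction.
#' @param cfg a [base_filter_config()].
#' @param unique_only drop reads with `n_hits > 1` before counting.
#' @return data frame of class `base_counts`, one row per position:
#'   `chrom, pos` (0-based), `ref`, counts `A_fwd..T_fwd`, `A_rev..T_rev`,
#'   `counted` (surviving bases), `excluded` (aligned bases removed by
#'   quality/trim/mapq), `low_mapq` (reads below `min_mapq`), `lowconf`
#'   (reads below `min_mapq` or multi-mapped), `n_reads` (all reads whose
#'   alignment covers the position), `mean_qual` (over counted bases).
#' @export
pileup <- function(reads, genome, region = NULL, cfg = base_filter_config(),
                   unique_only = FALSE) {
  reads <- reads[!reads$is_unmapped, , drop = FALSE]
  if (nrow(reads)) {
    key <- match(reads$chrom, names(genome$sequences)) *
      (max(genome$lengths) + 1) + reads$pos
    if (is.unsorted(key)) stop2("reads are not coordinate-sorted")
  }
  if (unique_only) reads <- reads[reads$n_hits == 1L, , drop = FALSE]
  # fast path: plain full-match reads expand with vectorized arithmetic;
  # reads with indels/clips go through the per-read CIGAR walk
  mlen <- suppressWarnings(as.integer(sub("^([0-9]+)M$", "\\1", reads$cigar)))
  simple <- !is.na(mlen) & mlen == nchar(reads$seq)
  fast <- reads[simple, , drop = FALSE]
  reads <- reads[!simple, , drop = FALSE]
  fast_dt <- NULL
  if (nrow(fast)) {
    lens <- nchar(fast$seq)
    qpos <- sequence(lens)
    rpos <- rep(fast$pos, lens) + qpos - 1L
    bases <- strsplit(paste(fast$seq, collapse = ""), "", fixed = TRUE)[[1]]
    quals <- utf8ToInt(paste(fast$qual, collapse = "")) - 33L
    codes <- match(bases, BASES)
    low_mapq <- rep(fast$mapq < cfg$min_mapq, lens)
    keep <- !low_mapq &
      quals >= cfg$min_base_qual &
      qpos > cfg$read_end_trim &
      qpos <= rep(lens, lens) - cfg$read_end_trim &
      !is.na(codes)
    fast_dt <- data.table::data.table(
      chrom = rep(fast$chrom, lens), pos = rpos,
      code = codes + 4L * rep(fast$is_reverse, lens), qual = quals,
      counted = keep, low_mapq = low_mapq,
      lowconf = rep(fast$mapq < cfg$min_mapq | fast$n_hits > 1L, lens))
  }
  n_reads_in <- nrow(reads)
  Lchrom <- Lpos <- Lcode <- Lqual <- Lkeep <- Llm <- Llc <-
    vector("list", n_reads_in)
  for (i in seq_len(n_reads_in)) {
    ap <- aligned_pairs(reads$pos[i], reads$cigar[i])
    if (!length(ap$qpos)) next
    quals <- utf8ToInt(reads$qual[i]) - 33L
    bases <- strsplit(reads$seq[i], "", fixed = TRUE)[[1]]
    qlen <- length(bases)
    codes <- match(bases[ap$qpos], BASES)
    low_mapq <- reads$mapq[i] < cfg$min_mapq
    keep <- !low_mapq &
      quals[ap$qpos] >= cfg$min_base_qual &
      ap$qpos > cfg$read_end_trim &
      ap$qpos <= qlen - cfg$read_end_trim &
      !is.na(codes)
    k <- length(ap$qpos)
    Lchrom[[i]] <- rep.int(reads$chrom[i], k)
    Lpos[[i]] <- ap$rpos
    Lcode[[i]] <- codes + 4L * rep.int(reads$is_reverse[i], k)
    Lqual[[i]] <- quals[ap$qpos]
    Lkeep[[i]] <- keep
    Llm[[i]] <- rep.int(low_mapq, k)
    Llc[[i]] <- rep.int(low_mapq || reads$n_hits[i] > 1L, k)
  }
  slow_dt <- NULL
  if (!all(vapply(Lpos, is.null, logical(1)))) {
    slow_dt <- data.table::data.table(
      chrom = unlist(Lchrom), pos = unlist(Lpos), code = unlist(Lcode),
      qual = unlist(Lqual), counted = unlist(Lkeep),
      low_mapq = unlist(Llm), lowconf = unlist(Llc))
  }
  dt <- if (is.null(fast_dt)) slow_dt
        else if (is.null(slow_dt)) fast_dt
        else data.table::rbindlist(list(fast_dt, slow_dt))
  if (is.null(dt) || !nrow(dt)) return(empty_base_counts())
  if (!is.null(region)) {
    dt <- dt[dt$chrom == region$chrom & dt$pos >= region$start0 & dt$pos < region$end0]
    if (!nrow(dt)) return(empty_base_counts())
  }
  # plain per-position sums (GForce-able), then the 8-way base/strand counts
  counted <- qual <- code <- qsum <- NULL # data.table NSE
  dt[, qsum := qual * counted]
  agg <- dt[, list(counted = sum(counted), n_reads = .N,
                   low_mapq = sum(low_mapq), lowconf = sum(lowconf),
                   qsum = sum(qsum)),
            by = c("chrom", "pos")]
  cnt <- dt[counted & !is.na(code),
            list(N = .N), by = c("chrom", "pos", "code")]
  wide <- data.table::dcast(cnt, chrom + pos ~ code, value.var = "N", fill = 0L)
  code_cols <- c("A_fwd", "C_fwd", "G_fwd", "T_fwd",
                 "A_rev", "C_rev", "G_rev", "T_rev")
  for (k in 1:8) {
    kc <- as.character(k)
    if (!kc %in% names(wide)) wide[[kc]] <- 0L
  }
  data.table::setnames(wide, as.character(1:8), code_cols)
  agg <- merge(agg, wide, by = c("chrom", "pos"), all.x = TRUE)
  for (cc in code_cols) agg[[cc]][is.na(agg[[cc]])] <- 0L
  agg <- agg[agg$counted > 0L]
  data.table::setorderv(agg, c("chrom", "pos"))
  out <- as.data.frame(agg)
  out$excluded <- out$n_reads - out$counted
  out$mean_qual <- ifelse(out$counted > 0, out$qsum / out$counted, NA_real_)
  out$ref <- NA_character_
  for (ch in unique(out$chrom)) {
    idx <- out$chrom == ch
    out$ref[idx] <- substring(genome$sequences[[ch]], out$pos[idx] + 1L,
                              out$pos[idx] + 1L)
  }
  out <- out[, c("chrom", "pos", "ref", "A_fwd", "C_fwd", "G_fwd", "T_fwd",
                 "A_rev", "C_rev", "G_rev", "T_rev", "counted", "excluded",
                 "low_mapq", "lowconf", "n_reads", "mean_qual")]
  rownames(out) <- NULL
  class(out) <- c("base_counts", "data.frame")
  out
}

empty_base_counts <- function() {
  out <- data.frame(chrom = character(), pos = integer(), ref = character(),
                    A_fwd = integer(), C_fwd = integer(), G_fwd = integer(),
                    T_fwd = integer(), A_rev = integer(), C_rev = integer(),
                    G_rev = integer(), T_rev = integer(), counted = integer(),
                    excluded = integer(), low_mapq = integer(),
                    lowconf = integer(), n_reads = integer(),
                    mean_qual = numeric(), stringsAsFactors = FALSE)
  class(out) <- c("base_counts", "data.frame")
  out
}

#' Combined (forward + reverse) base counts
#' @param counts a `base_counts` data frame.
#' @return integer matrix with columns A, C, G, T.
#' @export
base_count_matrix <- function(counts) {
  m <- cbind(A = counts$A_fwd + counts$A_rev,
             C = counts$C_fwd + counts$C_rev,
             G = counts$G_fwd + counts$G_rev,
             T = counts$T_fwd + counts$T_rev)
  m
}

#' Base counts at catalog sites
#'
#' Runs the same counting rules as [pileup()] but reports exactly the
#' positions of a site catalog, including zero-coverage sites (all-zero
#' count rows).
#'
#' @param reads data frame from [read_alignments()].
#' @param genome a `genome_ref`.
#' @param catalog a `site_catalog`.
#' @param cfg a [base_filter_config()].
#' @param unique_only drop multi-mapped reads before counting.
#' @return a `base_counts` data frame with one row per catalog site, in
#'   catalog order, with the catalog `strand` column attached.
#' @export
count_at_sites <- function(reads, genome, catalog, cfg = base_filter_config(),
                           unique_only = FALSE) {
  missing <- setdiff(unique(catalog$chrom), names(genome$sequences))
  if (length(missing))
    stop2("catalog chromosomes absent from genome: %s", paste(missing, collapse = ", "))
  pu <- pileup(reads, genome, region = NULL, cfg = cfg, unique_only = unique_only)
  if (nrow(pu) == 0L) {
    idx <- rep(NA_integer_, nrow(catalog))
  } else {
    idx <- match(paste(catalog$chrom, catalog$pos), paste(pu$chrom, pu$pos))
  }
  proto <- empty_base_counts()
  proto[seq_len(nrow(catalog)), ] <- NA
  out <- if (nrow(pu)) pu[ifelse(is.na(idx), NA_integer_, idx), , drop = FALSE] else proto
  zero <- is.na(idx)
  if (any(zero)) {
    out$chrom[zero] <- catalog$chrom[zero]
    out$pos[zero] <- catalog$pos[zero]
    for (cn in c("A_fwd", "C_fwd", "G_fwd", "T_fwd", "A_rev", "C_rev",
                 "G_rev", "T_rev", "counted", "excluded", "low_mapq",
                 "lowconf", "n_reads"))
      out[[cn]][zero] <- 0L
    out$mean_qual[zero] <- NA_real_
    out$ref[zero] <- mapply(function(ch, p) genome_fetch(genome, ch, p, p + 1L),
                            catalog$chrom[zero], catalog$pos[zero], USE.NAMES = FALSE)
  }
  out$strand <- catalog$strand
  rownames(out) <- NULL
  class(out) <- c("base_counts", "data.frame")
  out
}
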
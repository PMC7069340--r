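# shared fixture builders: everything generated in code, nothing on disk

tiny_genome <- function(seqs = c(chr1 = "ACGTACGTACGTACGTACGTACGTACGTACGT")) {
  genome_ref(seqs)
}

# build one read row in the read_alignments() layout
mk_read <- function(name, chrom, pos, seq, qual = NULL, mapq = 60L,
                    cigar = NULL, n_hits = 1L, is_reverse = FALSE,
                    is_unmapped = FALSE) {
  qual <- qual %||% strrep("I", nchar(seq))   # phred 40
  cigar <- cigar %||% sprintf("%dM", nchar(seq))
  data.frame(name = name, flag = (if (is_unmapped) 4L else 0L) +
               (if (is_reverse) 16L else 0L),
             chrom = chrom, pos = as.integer(pos), mapq = as.integer(mapq),
             cigar = cigar, seq = seq, qual = qual,
             n_hits = as.integer(n_hits), is_reverse = is_reverse,
             is_unmapped = is_unmapped, stringsAsFactors = FALSE)
}

mk_reads <- function(...) {
  out <- do.call(rbind, list(...))
  out[order(out$is_unmapped, out$chrom, out$pos), , drop = FALSE]
}

# write a SAM file by hand (kept independent of write_sam for I/O tests)
write_sam_text <- function(reads, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome$lengths), genome$lengths))
  rows <- vapply(seq_len(nrow(reads)), function(i) {
    r <- reads[i, ]
    if (r$is_unmapped)
      sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t%s", r$name, r$seq, r$qual)
    else
      sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tNH:i:%d",
              r$name, r$flag, r$chrom, r$pos + 1L, r$mapq, r$cigar,
              r$seq, r$qual, r$n_hits)
  }, character(1))
  writeLines(c(hdr, rows), path)
  path
}

# a base_counts row built directly (for index arithmetic tests)
mk_counts <- function(chrom, pos, ref, A = 0L, C = 0L, G = 0L, T = 0L,
                      strand = "+") {
  df <- data.frame(chrom = chrom, pos = as.integer(pos), ref = ref,
                   A_fwd = as.integer(A), C_fwd = as.integer(C),
                   G_fwd = as.integer(G), T_fwd = as.integer(T),
                   A_rev = 0L, C_rev = 0L, G_rev = 0L, T_rev = 0L,
                   counted = as.integer(A + C + G + T), excluded = 0L,
                   low_mapq = 0L, lowconf = 0L,
                   n_reads = as.integer(A + C + G + T),
                   mean_qual = 40, strand = strand, stringsAsFactors = FALSE)
  class(df) <- c("base_counts", "data.frame")
  df
}

mk_counts_tbl <- function(...) {
  out <- do.call(rbind, list(...))
  class(out) <- c("base_counts", "data.frame")
  out
}

# small default simulation reused across tests (built once per test run)
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(genome_length = 4000L, n_alu_pairs = 2L,
                        n_editing_sites = 60L, n_recoding_sites = 6L,
                        n_het_snps = 10L, depth = 40, wgs_depth = 20,
                        n_hyper_reads = 10L, n_multimap_reads = 12L,
                        seed = 20260921L)
      dir <- file.path(tempdir(), "rnaeditr_shared_sim")
      cache <<- simulate_dataset(cfg, dir)
    }
    cache
  }
})

# independent per-read recount of base counts at given positions from a SAM
# text file: the brute-force oracle used against the pileup engine
brute_force_counts <- function(sam_path, positions, min_qual = 30L,
                               trim = 6L, min_mapq = 20L) {
  lines <- readLines(sam_path)
  body <- lines[!startsWith(lines, "@")]
  acc <- matrix(0L, nrow = length(positions), ncol = 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (bitwAnd(as.integer(f[2]), 4L) > 0L) next
    if (as.integer(f[5]) < min_mapq) next
    st <- as.integer(f[4]) - 1L
    seq <- f[10]; qual <- f[11]
    n <- nchar(seq)
    if (f[6] != paste0(n, "M")) next
    for (k in seq_along(positions)) {
      p <- positions[k]
      off <- p - st + 1L
      if (off < 1L || off > n) next
      if (off <= trim || off > n - trim) next
      if (utf8ToInt(substr(qual, off, off)) - 33L < min_qual) next
      b <- substr(seq, off, off)
      if (b %in% c("A", "C", "G", "T")) acc[k, b] <- acc[k, b] + 1L
    }
  }
  acc
}
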
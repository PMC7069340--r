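#' Filter-cascade configuration
#'
#' Thresholds for the five-stage candidate filter cascade:
#' \describe{
#'   \item{A}{all mismatches surviving the per-base filters (phred >= 30).}
#'   \item{B}{genomic evidence: at least `min_wgs_cov` WGS reads, WGS
#'     non-reference fraction below `max_wgs_alt_frac` (homozygosity test),
#'     and position absent from the SNP set.}
#'   \item{C}{RNA coverage >= `min_rna_cov` and position not inside a
#'     reference homopolymer run longer than `max_homopolymer`.}
#'   \item{D}{editing frequency >= `min_freq`.}
#'   \item{E}{mapping confidence: position farther than `splice_window` nt
#'     from any splice junction and fraction of covering reads that are
#'     multi-mapped or low-MAPQ at most `max_lowmapq_frac`.}
#' }
#'
#' @param min_wgs_cov minimum WGS coverage at stage B (default 10).
#' @param max_wgs_alt_frac maximum WGS non-reference fraction regarded as
#'   homozygous reference (default 0.1).
#' @param min_rna_cov minimum RNA coverage at stage C (default 10).
#' @param max_homopolymer longest tolerated reference homopolymer run
#'   containing the site (default 5; runs of 6+ are removed).
#' @param min_freq minimum editing frequency at stage D (default 0.1).
#' @param splice_window distance (nt) to a splice junction below which a
#'   site is removed at stage E (default 4).
#' @param max_lowmapq_frac maximum tolerated fraction of low-confidence
#'   (multi-mapped or MAPQ below the pileup threshold) covering reads
#'   (default 0.1).
#' @return a `cascade_config` list.
#' @export
cascade_config <- function(min_wgs_cov = 10L, max_wgs_alt_frac = 0.1,
                           min_rna_cov = 10L, max_homopolymer = 5L,
                           min_freq = 0.1, splice_window = 4L,
                           max_lowmapq_frac = 0.1) {
  structure(list(min_wgs_cov = as.integer(min_wgs_cov),
                 max_wgs_alt_frac = max_wgs_alt_frac,
                 min_rna_cov = as.integer(min_rna_cov),
                 max_homopolymer = as.integer(max_homopolymer),
                 min_freq = min_freq,
                 splice_window = as.integer(splice_window),
                 max_lowmapq_frac = max_lowmapq_frac),
            class = "cascade_config")
}

#' Stage A: candidate sites from surviving mismatches
#'
#' Every pileup position whose surviving (quality- and trim-filtered) counts
#' contain at least one non-reference base becomes a candidate. The variant
#' base is the most frequent non-reference base; the substitution class is
#' `ref` followed by the variant base; strand is inferred for the A-to-G
#' classes (`AG` on `+`, `TC` reported as the reverse-strand signal).
#'
#' @param counts a `base_counts` data frame from [pileup()].
#' @return data frame of class `site_calls`: `chrom, pos, ref, strand,
#'   coverage` (ref + variant reads), `A, C, G, T` combined counts, `alt`,
#'   `alt_count, ref_count, freq, class, lowconf_frac, stages`.
#' @export
call_stage_A <- function(counts) {
  if (nrow(counts) == 0L) return(empty_site_calls())
  m <- base_count_matrix(counts)
  ref <- counts$ref
  keep <- ref %in% BASES
  counts <- counts[keep, , drop = FALSE]; m <- m[keep, , drop = FALSE]; ref <- ref[keep]
  if (!nrow(counts)) return(empty_site_calls())
  ref_idx <- match(ref, BASES)
  alt_m <- m
  alt_m[cbind(seq_len(nrow(m)), ref_idx)] <- -1L
  alt_idx <- max.col(alt_m, ties.method = "first")
  alt_count <- m[cbind(seq_len(nrow(m)), alt_idx)]
  has_alt <- alt_count > 0L
  counts <- counts[has_alt, , drop = FALSE]
  if (!nrow(counts)) return(empty_site_calls())
  m <- m[has_alt, , drop = FALSE]; ref <- ref[has_alt]
  ref_idx <- ref_idx[has_alt]; alt_idx <- alt_idx[has_alt]; alt_count <- alt_count[has_alt]
  ref_count <- m[cbind(seq_len(nrow(m)), ref_idx)]
  alt <- BASES[alt_idx]
  cls <- paste0(ref, alt)
  strand <- ifelse(cls == "AG", "+", ifelse(cls == "TC", "-", "?"))
  out <- data.frame(chrom = counts$chrom, pos = counts$pos, ref = ref,
                    strand = strand,
                    coverage = ref_count + alt_count,
                    A = m[, "A"], C = m[, "C"], G = m[, "G"], T = m[, "T"],
                    alt = alt, alt_count = alt_count, ref_count = ref_count,
                    freq = alt_count / (ref_count + alt_count),
                    class = cls,
                    lowconf_frac = ifelse(counts$n_reads > 0,
                                          counts$lowconf / counts$n_reads, 0),
                    stages = "A",
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("site_calls", "data.frame")
  out
}

empty_site_calls <- function() {
  out <- data.frame(chrom = character(), pos = integer(), ref = character(),
                    strand = character(), coverage = integer(),
                    A = integer(), C = integer(), G = integer(), T = integer(),
                    alt = character(), alt_count = integer(),
                    ref_count = integer(), freq = numeric(), class = character(),
                    lowconf_frac = numeric(), stages = character(),
                    stringsAsFactors = FALSE)
  class(out) <- c("site_calls", "data.frame")
  out
}

mark_stage <- function(calls, keep, letter) {
  out <- calls[keep, , drop = FALSE]
  out$stages <- paste0(out$stages, letter)
  rownames(out) <- NULL
  class(out) <- c("site_calls", "data.frame")
  out
}

#' Stage B: genomic evidence filter
#'
#' Keeps candidates supported by homozygous-reference genomic DNA: WGS
#' coverage at least `cfg$min_wgs_cov`, WGS non-reference fraction below
#' `cfg$max_wgs_alt_frac`, and position not in the SNP exclusion set.
#'
#' @param calls `site_calls` from [call_stage_A()].
#' @param wgs_counts `base_counts` from a pileup of the matched WGS reads
#'   (same per-base filters), or `NULL` to disable the WGS test.
#' @param snps a `snp_set`, or `NULL` to skip SNP removal.
#' @param cfg a [cascade_config()].
#' @return filtered `site_calls` with stage flag `B` appended.
#' @export
apply_stage_B <- function(calls, wgs_counts, snps, cfg = cascade_config()) {
  if (nrow(calls) == 0L) return(calls)
  keep <- rep(TRUE, nrow(calls))
  if (!is.null(snps) && nrow(snps))
    keep <- keep & !snp_member(snps, calls$chrom, calls$pos)
  if (!is.null(wgs_counts)) {
    cov <- rep(0, nrow(calls)); ref_cnt <- rep(0, nrow(calls))
    if (nrow(wgs_counts)) {
      m <- base_count_matrix(wgs_counts)
      idx <- match(paste(calls$chrom, calls$pos),
                   paste(wgs_counts$chrom, wgs_counts$pos))
      hit <- !is.na(idx)
      cov[hit] <- rowSums(m)[idx[hit]]
      ref_cnt[hit] <- m[cbind(idx[hit], match(calls$ref[hit], BASES))]
    }
    alt_frac <- ifelse(cov > 0, 1 - ref_cnt / cov, 1)
    keep <- keep & cov >= cfg$min_wgs_cov & alt_frac < cfg$max_wgs_alt_frac
  }
  mark_stage(calls, keep, "B")
}

#' Length of the reference homopolymer run containing a position
#' @param genome a `genome_ref`.
#' @param chrom,pos chromosome and 0-based position.
#' @return integer run length.
#' @export
homopolymer_run <- function(genome, chrom, pos) {
  seq <- genome$sequences[[chrom]]
  b <- substr(seq, pos + 1L, pos + 1L)
  n <- nchar(seq)
  left <- pos
  while (left > 0L && substr(seq, left, left) == b) left <- left - 1L
  right <- pos + 2L
  while (right <= n && substr(seq, right, right) == b) right <- right + 1L
  right - left - 1L
}

#' Stage C: coverage and homopolymer filter
#'
#' Keeps candidates with RNA coverage at least `cfg$min_rna_cov` whose
#' position does not fall inside a reference homopolymer run longer than
#' `cfg$max_homopolymer` residues. (Read-end exclusion is already enforced
#' per base in the pileup.)
#'
#' @param calls `site_calls`.
#' @param genome a `genome_ref`.
#' @param cfg a [cascade_config()].
#' @return filtered `site_calls` with stage flag `C` appended.
#' @export
apply_stage_C <- function(calls, genome, cfg = cascade_config()) {
  if (nrow(calls) == 0L) return(calls)
  runs <- mapply(homopolymer_run, chrom = calls$chrom, pos = calls$pos,
                 MoreArgs = list(genome = genome), USE.NAMES = FALSE)
  keep <- calls$coverage >= cfg$min_rna_cov & runs <= cfg$max_homopolymer
  mark_stage(calls, keep, "C")
}

#' Stage D: editing-frequency filter
#'
#' Keeps candidates with editing frequency at least `cfg$min_freq`.
#'
#' @param calls `site_calls`.
#' @param cfg a [cascade_config()].
#' @return filtered `site_calls` with stage flag `D` appended.
#' @export
apply_stage_D <- function(calls, cfg = cascade_config()) {
  if (nrow(calls) == 0L) return(calls)
  mark_stage(calls, calls$freq >= cfg$min_freq, "D")
}

#' Stage E: mapping-confidence and splice-proximity filter
#'
#' Removes candidates within `cfg$splice_window` nt of a splice junction
#' and candidates where the fraction of covering reads that are
#' multi-mapped or below the MAPQ threshold exceeds
#' `cfg$max_lowmapq_frac` (a mapping-confidence proxy for re-alignment
#' checks; an external per-read concordance annotation can be supplied by
#' pre-filtering the read stream).
#'
#' @param calls `site_calls` (carrying `lowconf_frac` from the pileup).
#' @param junctions a `GRanges` of splice-junction positions, or `NULL`.
#' @param cfg a [cascade_config()].
#' @return filtered `site_calls` with stage flag `E` appended.
#' @export
apply_stage_E <- function(calls, junctions = NULL, cfg = cascade_config()) {
  if (nrow(calls) == 0L) return(calls)
  keep <- calls$lowconf_frac <= cfg$max_lowmapq_frac
  if (!is.null(junctions) && length(junctions)) {
    sites <- GenomicRanges::GRanges(calls$chrom,
                                    IRanges::IRanges(calls$pos + 1L, calls$pos + 1L))
    d <- GenomicRanges::distanceToNearest(sites, junctions, ignore.strand = TRUE)
    dist <- rep(Inf, nrow(calls))
    dist[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance
    keep <- keep & dist > cfg$splice_window
  }
  mark_stage(calls, keep, "E")
}

#' Run the full candidate-calling cascade
#'
#' Convenience wrapper chaining stages A through E and recording per-stage
#' survivor counts.
#'
#' @param counts RNA `base_counts` (pileup built with `min_base_qual` 30).
#' @param genome a `genome_ref`.
#' @param wgs_counts WGS `base_counts` or `NULL` (disables the WGS test).
#' @param snps a `snp_set` or `NULL`.
#' @param junctions a `GRanges` of splice junctions or `NULL`.
#' @param cfg a [cascade_config()].
#' @return list with `calls` (stage-E survivors), `per_stage` (named
#'   survivor counts A..E) and `stages` (list of intermediate `site_calls`).
#' @export
call_editing <- function(counts, genome, wgs_counts = NULL, snps = NULL,
                         junctions = NULL, cfg = cascade_config()) {
  a <- call_stage_A(counts)
  b <- apply_stage_B(a, wgs_counts, snps, cfg)
  cc <- apply_stage_C(b, genome, cfg)
  d <- apply_stage_D(cc, cfg)
  e <- apply_stage_E(d, junctions, cfg)
  list(calls = e,
       per_stage = c(A = nrow(a), B = nrow(b), C = nrow(cc), D = nrow(d), E = nrow(e)),
       stages = list(A = a, B = b, C = cc, D = d, E = e))
}

#' Mismatch-spectrum summary and spectrum-based FDR estimate
#'
#' Tallies calls over the 12 substitution classes. The A-to-G fraction pools
#' `AG` with `TC` (the reverse-strand appearance of A-to-G in unstranded
#' data). The false-discovery estimate takes the mean count of the 10
#' classes not expected to be edited as the per-class noise floor and
#' divides it by the pooled `AG`+`TC` count.
#'
#' @param calls a `site_calls` data frame.
#' @return object of class `spectrum_summary`: `counts` (named, 12
#'   classes), `ag_tc_fraction`, `fdr_estimate` (both `NA` when no calls).
#' @export
mismatch_spectrum <- function(calls) {
  cnt <- setNames(integer(length(SUB_CLASSES)), SUB_CLASSES)
  tab <- table(calls$class)
  cnt[names(tab)] <- as.integer(tab)
  total <- sum(cnt)
  ag_tc <- cnt[["AG"]] + cnt[["TC"]]
  other <- cnt[setdiff(SUB_CLASSES, c("AG", "TC"))]
  out <- list(
    counts = cnt,
    ag_tc_fraction = if (total > 0) ag_tc / total else NA_real_,
    fdr_estimate = if (total > 0 && ag_tc > 0) mean(other) / ag_tc
                   else if (total > 0) NA_real_ else NA_real_
  )
  structure(out, class = "spectrum_summary")
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat("<spectrum_summary>\n")
  print(x$counts)
  cat(sprintf("AG+TC fraction: %s   estimated FDR: %s\n",
              format(x$ag_tc_fraction, digits = 4),
              format(x$fdr_estimate, digits = 4)))
  invisible(x)
}
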
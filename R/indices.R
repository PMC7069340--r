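#' Site-level editing from base counts
#'
#' For a site annotated on the `+` strand, editing is `G / (A + G)` in
#' genome space; on the `-` strand it is `C / (T + C)`. Other bases are
#' ignored. Returns `NA` when the informative denominator is zero.
#'
#' @param counts a `base_counts` data frame (one or more rows).
#' @param strand catalog strand per row (`+`/`-`); defaults to the `strand`
#'   column attached by [count_at_sites()].
#' @return numeric vector of editing levels in `[0, 1]` (NA where undefined).
#' @export
site_level <- function(counts, strand = counts$strand) {
  m <- base_count_matrix(counts)
  ed <- ifelse(strand == "+", m[, "G"], m[, "C"])
  un <- ifelse(strand == "+", m[, "A"], m[, "T"])
  den <- ed + un
  ifelse(den > 0, ed / den, NA_real_)
}

index_result <- function(kind, num, den, n) {
  structure(list(kind = kind, numerator = num, denominator = den,
                 value = if (den > 0) 100 * num / den else NA_real_,
                 n_sites = n),
            class = "index_result")
}

#' @export
print.index_result <- function(x, ...) {
  cat(sprintf("<index_result> %s: %s%% (%d / %d over %d site(s)/position(s))\n",
              x$kind,
              if (is.na(x$value)) "NA" else format(x$value, digits = 4),
              x$numerator, x$denominator, x$n_sites))
  invisible(x)
}

#' Overall editing index
#'
#' Total edited reads over total informative reads across all catalog
#' sites, with no per-site coverage cutoff; reported as a percentage.
#' Zero-coverage sites contribute nothing. With
#' `denominator = "all"`, every counted read at a site (including
#' non-ref/non-edited bases) enters the denominator.
#'
#' @param counts `base_counts` from [count_at_sites()] (must carry `strand`).
#' @param denominator `"informative"` (ref + edited reads, default) or
#'   `"all"` (all counted reads).
#' @return an `index_result` of kind `overall` (`value` is `NA` when the
#'   denominator is zero).
#' @export
overall_index <- function(counts, denominator = c("informative", "all")) {
  denominator <- match.arg(denominator)
  m <- base_count_matrix(counts)
  ed <- ifelse(counts$strand == "+", m[, "G"], m[, "C"])
  un <- ifelse(counts$strand == "+", m[, "A"], m[, "T"])
  den <- if (denominator == "informative") sum(ed + un) else sum(m)
  index_result("overall", sum(ed), den, nrow(counts))
}

#' Alu editing index (AEI)
#'
#' The coverage-weighted average editing over every adenosine inside the
#' supplied repeat intervals: the ratio (as a percentage) of A-to-G
#' mismatched reads to the total adenosine coverage (A matches plus A-to-G
#' mismatches). On `-` intervals reference-T positions are used with the
#' `C` mismatch, mirroring the genome-space representation. By default only
#' uniquely mapped reads contribute.
#'
#' @param reads data frame from [read_alignments()].
#' @param genome a `genome_ref`.
#' @param regions a stranded `GRanges` of repeat (Alu-like) intervals.
#' @param cfg a [base_filter_config()].
#' @param unique_only restrict to uniquely mapped reads (default `TRUE`).
#' @return an `index_result` of kind `AEI`; `n_sites` is the number of
#'   covered adenosine positions.
#' @export
alu_index <- function(reads, genome, regions, cfg = base_filter_config(),
                      unique_only = TRUE) {
  pu <- pileup(reads, genome, cfg = cfg, unique_only = unique_only)
  if (nrow(pu) == 0L) return(index_result("AEI", 0L, 0L, 0L))
  gr_pos <- GenomicRanges::GRanges(pu$chrom, IRanges::IRanges(pu$pos + 1L, pu$pos + 1L))
  ov <- GenomicRanges::findOverlaps(gr_pos, regions, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov)
  strand <- as.character(GenomicRanges::strand(regions))[S4Vectors::subjectHits(ov)]
  strand[strand == "*"] <- "+"
  keep <- !duplicated(qh) # a position in two overlapping intervals counts once
  qh <- qh[keep]; strand <- strand[keep]
  sub <- pu[qh, , drop = FALSE]
  m <- base_count_matrix(sub)
  isA <- (strand == "+" & sub$ref == "A") | (strand == "-" & sub$ref == "T")
  ed <- ifelse(strand == "+", m[, "G"], m[, "C"])[isA]
  un <- ifelse(strand == "+", m[, "A"], m[, "T"])[isA]
  index_result("AEI", sum(ed), sum(ed + un), sum(isA))
}

#' Recoding editing index (REI)
#'
#' The overall-index arithmetic restricted to recoding (nonsynonymous)
#' catalog sites: edited reads over informative reads at recoding
#' positions, in percent.
#'
#' @param counts `base_counts` from [count_at_sites()] on a catalog whose
#'   `recoding` flags are attached via `catalog`.
#' @param catalog the `site_catalog` matching `counts` row-for-row; only
#'   rows with `recoding = TRUE` are used.
#' @return an `index_result` of kind `REI`.
#' @export
recoding_index <- function(counts, catalog) {
  stopifnot(nrow(counts) == nrow(catalog))
  sub <- counts[catalog$recoding, , drop = FALSE]
  r <- overall_index(sub)
  index_result("REI", r$numerator, r$denominator, nrow(sub))
}

#' Subsampling robustness of the overall editing index
#'
#' Draws growing random subsets of catalog sites, recomputes the per-sample
#' overall index on each subset, and correlates (Pearson) the subset values
#' with the full-catalog values across samples.
#'
#' @param counts_per_sample named list of `base_counts` from
#'   [count_at_sites()] on the same catalog (>= 3 samples).
#' @param sizes integer vector of subset sizes (each <= catalog size).
#' @param n_reps random subsets per size (default 5).
#' @param seed RNG seed (mandatory for reproducibility).
#' @return object of class `subsample_report`: data frame `samples` of
#'   per-size/rep/sample index values and data frame `correlations`
#'   (`size, rep, r`); `r` is `NA` when a vector is constant.
#' @export
subsample_robustness <- function(counts_per_sample, sizes, n_reps = 5L, seed) {
  stopifnot(length(counts_per_sample) >= 3L, !missing(seed))
  n_sites <- nrow(counts_per_sample[[1]])
  if (any(sizes > n_sites))
    stop2("subset size %d exceeds catalog size %d", max(sizes), n_sites)
  full <- vapply(counts_per_sample, function(x) overall_index(x)$value, numeric(1))
  set.seed(seed)
  rows <- list(); vals <- list()
  for (s in sizes) {
    for (r in seq_len(n_reps)) {
      idx <- sample.int(n_sites, s)
      v <- vapply(counts_per_sample,
                  function(x) overall_index(x[idx, , drop = FALSE])$value,
                  numeric(1))
      rr <- if (stats::sd(v) == 0 || stats::sd(full) == 0 || anyNA(v)) NA_real_
            else cor(v, full)
      rows[[length(rows) + 1L]] <- data.frame(size = s, rep = r, r = rr)
      vals[[length(vals) + 1L]] <-
        data.frame(size = s, rep = r, sample = names(counts_per_sample) %||%
                     as.character(seq_along(v)), value = unname(v))
    }
  }
  structure(list(samples = do.call(rbind, vals),
                 correlations = do.call(rbind, rows),
                 full_values = full),
            class = "subsample_report")
}

#' @export
print.subsample_report <- function(x, ...) {
  cat("<subsample_report>\n")
  agg <- stats::aggregate(r ~ size, data = x$correlations, FUN = mean)
  print(agg, row.names = FALSE)
  invisible(x)
}
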
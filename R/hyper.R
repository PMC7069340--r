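#' Hyper-editing configuration
#'
#' Thresholds for calling a rescued read hyper-edited. This toolkit's
#' defaults: at least 4 A-to-G mismatches per read, A-to-G purity at least
#' 60% of all mismatches, and non-A-to-G mismatches at most 10% of the read
#' length; both the A-to-G and T-to-C transformed passes run by default
#' (unstranded data).
#'
#' @param min_ag_per_read minimum A-to-G mismatches per read (default 4).
#' @param min_ag_purity minimum fraction of mismatches that are A-to-G
#'   (default 0.6).
#' @param max_other_mismatch_frac maximum non-A-to-G mismatches as a
#'   fraction of read length (default 0.1).
#' @param passes `"AG"`, `"TC"`, or `"both"` (default): which transformed
#'   passes to run.
#' @param seed_length seed length used by the built-in rescue aligner
#'   (default 20).
#' @return a `hyper_config` list.
#' @export
hyper_config <- function(min_ag_per_read = 4L, min_ag_purity = 0.6,
                         max_other_mismatch_frac = 0.1,
                         passes = c("both", "AG", "TC"), seed_length = 20L) {
  passes <- match.arg(passes)
  stopifnot(min_ag_purity >= 0, min_ag_purity <= 1,
            max_other_mismatch_frac >= 0, max_other_mismatch_frac <= 1)
  structure(list(min_ag_per_read = as.integer(min_ag_per_read),
                 min_ag_purity = min_ag_purity,
                 max_other_mismatch_frac = max_other_mismatch_frac,
                 passes = passes, seed_length = as.integer(seed_length)),
            class = "hyper_config")
}

#' Replace one base with another throughout a sequence
#'
#' The base transformation underlying hyper-editing rescue: replacing every
#' A with G (or T with C) collapses editing mismatches so that heavily
#' edited reads align cleanly to an equally transformed genome.
#'
#' @param seq character vector of nucleotide strings.
#' @param from,to single bases.
#' @return transformed strings (same lengths).
#' @export
transform_bases <- function(seq, from = "A", to = "G") {
  stopifnot(nchar(from) == 1L, nchar(to) == 1L)
  chartr(from, to, seq)
}

# exact/1-mismatch seed search + full-read extension on transformed space
toy_align_one <- function(tread, tseqs, max_mm, seed_len) {
  n <- nchar(tread)
  seed_len <- min(seed_len, n)
  seed <- substr(tread, 1, seed_len)
  best <- NULL
  pat <- Biostrings::DNAString(seed)
  for (chrom in names(tseqs)) {
    subj <- tseqs[[chrom]]
    hits <- Biostrings::matchPattern(pat, subj, max.mismatch = 1L)
    for (st in Biostrings::start(hits)) {
      if (st + n - 1L > length(subj)) next
      window <- as.character(Biostrings::subseq(subj, st, st + n - 1L))
      mm <- sum(strsplit(window, "")[[1]] != strsplit(tread, "")[[1]])
      if (mm <= max_mm && (is.null(best) || mm < best$mm))
        best <- list(chrom = chrom, start0 = st - 1L, mm = mm)
    }
  }
  best
}

#' Rescue unmapped reads on a base-transformed genome
#'
#' Transforms reads and genome (A to G for the forward-strand editing
#' signal; T to C for the reverse-strand signal) and places each read with
#' the built-in seed-and-extend aligner (exact/1-mismatch seed, full-read
#' extension, at most 10% mismatches in transformed space). Placements are
#' reported in original genome coordinates. A custom aligner can be
#' supplied through `aligner`, a function
#' `(transformed_read, transformed_genome_DNAStringList, max_mm, seed_len)`
#' returning `list(chrom, start0, mm)` or `NULL`.
#'
#' @param reads data frame with at least `name` and `seq` columns (e.g. the
#'   unmapped reads from [read_alignments()] or parsed FASTQ via
#'   [read_fastq()]).
#' @param genome a `genome_ref`.
#' @param cfg a [hyper_config()].
#' @param aligner optional replacement for the built-in adapter.
#' @return data frame of placements: `name, seq, chrom, pos` (0-based),
#'   `pass` (`AG`/`TC`), `tmm` (mismatches in transformed space), and
#'   `rescued` flag (unplaced reads are retained with `rescued = FALSE`).
#' @export
rescue_align <- function(reads, genome, cfg = hyper_config(), aligner = NULL) {
  passes <- switch(cfg$passes, both = c("AG", "TC"), AG = "AG", TC = "TC")
  tgenomes <- lapply(passes, function(p) {
    from <- if (p == "AG") "A" else "T"; to <- if (p == "AG") "G" else "C"
    lapply(genome$sequences, function(s) Biostrings::DNAString(transform_bases(s, from, to)))
  })
  names(tgenomes) <- passes
  align <- aligner %||% toy_align_one
  out <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    s <- reads$seq[i]
    max_mm <- floor(0.1 * nchar(s))
    best <- NULL; best_pass <- NA_character_
    for (p in passes) {
      from <- if (p == "AG") "A" else "T"; to <- if (p == "AG") "G" else "C"
      tread <- transform_bases(s, from, to)
      hit <- align(tread, tgenomes[[p]], max_mm, cfg$seed_length)
      if (!is.null(hit) && (is.null(best) || hit$mm < best$mm)) {
        best <- hit; best_pass <- p
      }
    }
    out[[i]] <- if (is.null(best)) {
      data.frame(name = reads$name[i], seq = s, chrom = NA_character_,
                 pos = NA_integer_, pass = NA_character_, tmm = NA_integer_,
                 rescued = FALSE, stringsAsFactors = FALSE)
    } else {
      data.frame(name = reads$name[i], seq = s, chrom = best$chrom,
                 pos = best$start0, pass = best_pass, tmm = best$mm,
                 rescued = TRUE, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(name = character(), seq = character(), chrom = character(),
               pos = integer(), pass = character(), tmm = integer(),
               rescued = logical(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Detect A-to-G clusters in rescued reads
#'
#' Compares each rescued read to the original (untransformed) genome at its
#' placement, counts editing-type mismatches (A-to-G for the `AG` pass,
#' T-to-C genome-space for the `TC` pass) and all other mismatches, and
#' flags the read as a passing hyper-edited cluster when the count, purity
#' and other-mismatch thresholds in `cfg` are met.
#'
#' @param placements data frame from [rescue_align()].
#' @param genome a `genome_ref`.
#' @param cfg a [hyper_config()].
#' @return data frame of class `hyper_clusters`: one row per rescued read
#'   with `name, chrom, start` (0-based), `end` (half-open), `pass, n_ag,
#'   n_other, positions` (comma-separated 0-based A-to-G genome positions)
#'   and `pass_filter`.
#' @export
detect_clusters <- function(placements, genome, cfg = hyper_config()) {
  pl <- placements[placements$rescued, , drop = FALSE]
  out <- vector("list", nrow(pl))
  for (i in seq_len(nrow(pl))) {
    s <- strsplit(pl$seq[i], "")[[1]]
    n <- length(s)
    ref <- strsplit(genome_fetch(genome, pl$chrom[i], pl$pos[i], pl$pos[i] + n), "")[[1]]
    ed_from <- if (pl$pass[i] == "AG") "A" else "T"
    ed_to <- if (pl$pass[i] == "AG") "G" else "C"
    is_ed <- ref == ed_from & s == ed_to
    is_other <- ref != s & !is_ed
    pos_ed <- pl$pos[i] + which(is_ed) - 1L
    n_ag <- sum(is_ed); n_other <- sum(is_other)
    purity <- if (n_ag + n_other > 0) n_ag / (n_ag + n_other) else 0
    out[[i]] <- data.frame(
      name = pl$name[i], chrom = pl$chrom[i], start = pl$pos[i],
      end = pl$pos[i] + n, pass = pl$pass[i], n_ag = n_ag, n_other = n_other,
      positions = paste(pos_ed, collapse = ","),
      pass_filter = n_ag >= cfg$min_ag_per_read &&
        purity >= cfg$min_ag_purity &&
        n_other <= cfg$max_other_mismatch_frac * n,
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(name = character(), chrom = character(), start = integer(),
               end = integer(), pass = character(), n_ag = integer(),
               n_other = integer(), positions = character(),
               pass_filter = logical(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("hyper_clusters", "data.frame")
  res
}

#' Editing positions from passing clusters
#' @param clusters a `hyper_clusters` data frame.
#' @return data frame `chrom, pos` (0-based, unique) of A-to-G positions in
#'   passing clusters.
#' @export
cluster_sites <- function(clusters) {
  cl <- clusters[clusters$pass_filter & nzchar(clusters$positions), , drop = FALSE]
  if (!nrow(cl)) return(data.frame(chrom = character(), pos = integer()))
  pos <- strsplit(cl$positions, ",", fixed = TRUE)
  df <- data.frame(chrom = rep(cl$chrom, lengths(pos)),
                   pos = as.integer(unlist(pos)), stringsAsFactors = FALSE)
  df <- unique(df)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Merge standard candidate calls with hyper-editing cluster sites
#'
#' @param calls a `site_calls` data frame (standard caller output).
#' @param clusters a `hyper_clusters` data frame.
#' @return list with `sites` (data frame `chrom, pos, source` where source
#'   is `standard`, `hyper` or `both`) and `counts` (named: standard,
#'   hyper, both, union).
#' @export
merge_calls <- function(calls, clusters) {
  std <- unique(data.frame(chrom = calls$chrom, pos = calls$pos,
                           stringsAsFactors = FALSE))
  hyp <- cluster_sites(clusters)
  key_s <- paste(std$chrom, std$pos); key_h <- paste(hyp$chrom, hyp$pos)
  all_sites <- unique(rbind(std, hyp))
  key_a <- paste(all_sites$chrom, all_sites$pos)
  src <- ifelse(key_a %in% key_s & key_a %in% key_h, "both",
                ifelse(key_a %in% key_s, "standard", "hyper"))
  all_sites$source <- src
  all_sites <- all_sites[order(all_sites$chrom, all_sites$pos), , drop = FALSE]
  rownames(all_sites) <- NULL
  list(sites = all_sites,
       counts = c(standard = nrow(std), hyper = nrow(hyp),
                  both = sum(src == "both"), union = nrow(all_sites)))
}

#' Read sequences from FASTQ
#' @param path FASTQ file (plain text).
#' @return data frame `name, seq, qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop2("FASTQ not found: %s", path)
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stop2("truncated FASTQ: %s", path)
  idx <- seq(1L, length(lines), by = 4L)
  data.frame(name = sub("^@", "", sub("\\s.*$", "", lines[idx])),
             seq = toupper(lines[idx + 1L]),
             qual = lines[idx + 3L], stringsAsFactors = FALSE)
}
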
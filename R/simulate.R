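#' Simulation configuration
#'
#' Defines the synthetic study conditions: a random genome carrying
#' inverted pairs of A-rich Alu-like repeats, programmed editing sites
#' (inside repeats, plus recoding sites outside), heterozygous SNPs,
#' uniformly sampled RNA and WGS reads with independent base-call errors,
#' and heavily edited (hyper) reads emitted unmapped.
#'
#' @param genome_length genome size in bp (single chromosome, default 10000).
#' @param n_alu_pairs inverted repeat pairs (default 3).
#' @param alu_length repeat length in bp (default 300).
#' @param n_editing_sites programmed sites inside repeats (default 150);
#'   ignored when `edit_all_alu = TRUE`.
#' @param edit_all_alu program every repeat-strand adenosine inside the
#'   repeats (the regime the Alu editing index integrates over).
#' @param level_type `"fixed"` or `"beta"`: per-site editing level model.
#' @param level fixed editing level (default 0.15).
#' @param beta_a,beta_b Beta parameters when `level_type = "beta"`
#'   (default Beta(1, 9), mean 0.1).
#' @param n_recoding_sites recoding sites outside repeats (default 10).
#' @param n_het_snps heterozygous SNPs, outside repeats and disjoint from
#'   editing sites (default 20).
#' @param read_length RNA/WGS read length (default 100).
#' @param depth mean RNA coverage (default 60).
#' @param wgs_depth mean WGS coverage (default 30).
#' @param error_rate per-base sequencing error probability (default 0.001).
#' @param low_qual_frac fraction of bases assigned phred 20 instead of 40
#'   (default 0.02); these are removed by the default base filters.
#' @param n_hyper_reads heavily edited reads emitted unmapped (default 30).
#' @param hyper_fraction fraction of each hyper read's adenosines edited
#'   (default 0.8).
#' @param n_multimap_reads reads emitted with `NH = 2` at a fixed locus, to
#'   exercise the mapping-confidence filter (default 0).
#' @param seed RNG seed (mandatory).
#' @return a `sim_config` list.
#' @export
sim_config <- function(genome_length = 10000L, n_alu_pairs = 3L,
                       alu_length = 300L, n_editing_sites = 150L,
                       edit_all_alu = FALSE,
                       level_type = c("fixed", "beta"), level = 0.15,
                       beta_a = 1, beta_b = 9, n_recoding_sites = 10L,
                       n_het_snps = 20L, read_length = 100L, depth = 60,
                       wgs_depth = 30, error_rate = 0.001,
                       low_qual_frac = 0.02, n_hyper_reads = 30L,
                       hyper_fraction = 0.8, n_multimap_reads = 0L, seed) {
  if (missing(seed)) stop2("sim_config requires a seed")
  level_type <- match.arg(level_type)
  stopifnot(error_rate >= 0, error_rate <= 1, low_qual_frac >= 0,
            low_qual_frac <= 1, hyper_fraction >= 0, hyper_fraction <= 1)
  structure(as.list(environment()), class = "sim_config")
}

# deterministic substream seeds so adding a stage never perturbs earlier ones
substream <- function(seed, k) (as.numeric(seed) * 48271 + k * 16807) %% 2147483647

#' Build the synthetic genome, repeats, catalogs and SNP set
#'
#' Deterministic under `cfg$seed`. Repeats are placed as inverted pairs
#' (`+` copy and its reverse complement on `-`). Editing sites are
#' repeat-strand adenosines inside repeats (genome A in `+` copies, genome
#' T in `-` copies) plus `n_recoding_sites` genome-A positions outside
#' repeats flagged as recoding. SNP positions are disjoint from editing
#' sites and repeats.
#'
#' @param cfg a [sim_config()].
#' @return list: `genome` (`genome_ref`), `repeats` (`GRanges`), `catalog`
#'   (`site_catalog`), `snps` (data frame `chrom, pos`, 0-based, with `ref`
#'   and `alt`), `truth_sites` (catalog plus programmed `level` and
#'   `class`).
#' @export
make_genome <- function(cfg) {
  set.seed(substream(cfg$seed, 1L))
  L <- cfg$genome_length
  chrom <- "chr1"
  bg <- sample(BASES, L, replace = TRUE)
  n_rep <- 2L * cfg$n_alu_pairs
  slot <- floor(L / (n_rep + 1))
  if (slot <= cfg$alu_length + 20L)
    stop2("genome too small for %d repeats of length %d", n_rep, cfg$alu_length)
  starts <- (seq_len(n_rep)) * slot - floor(cfg$alu_length / 2)
  strands <- rep(c("+", "-"), cfg$n_alu_pairs)
  rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  # one A-rich element per inverted pair: '+' copy plus its reverse
  # complement elsewhere, so the pair can form the dsRNA ADAR substrate
  for (p in seq_len(cfg$n_alu_pairs)) {
    cons_str <- paste(sample(BASES, cfg$alu_length, replace = TRUE,
                             prob = c(0.35, 0.2, 0.2, 0.25)), collapse = "")
    i_fwd <- 2L * p - 1L; i_rev <- 2L * p
    bg[starts[i_fwd] + seq_len(cfg$alu_length)] <- strsplit(cons_str, "")[[1]]
    bg[starts[i_rev] + seq_len(cfg$alu_length)] <- strsplit(rc(cons_str), "")[[1]]
  }
  genome <- genome_ref(setNames(paste(bg, collapse = ""), chrom))
  repeats <- GenomicRanges::GRanges(chrom,
                                    IRanges::IRanges(starts + 1L, starts + cfg$alu_length),
                                    strand = strands)
  # candidate editing positions: repeat-strand adenosines
  ed_pos <- integer(); ed_strand <- character()
  for (i in seq_len(n_rep)) {
    span <- starts[i] + seq_len(cfg$alu_length) - 1L  # 0-based
    b <- bg[span + 1L]
    want <- if (strands[i] == "+") "A" else "T"
    hit <- span[b == want]
    ed_pos <- c(ed_pos, hit)
    ed_strand <- c(ed_strand, rep(strands[i], length(hit)))
  }
  if (!cfg$edit_all_alu) {
    if (cfg$n_editing_sites > length(ed_pos))
      stop2("requested %d editing sites but only %d repeat adenosines available",
            cfg$n_editing_sites, length(ed_pos))
    pick <- sort(sample.int(length(ed_pos), cfg$n_editing_sites))
    ed_pos <- ed_pos[pick]; ed_strand <- ed_strand[pick]
  }
  in_repeat <- rep(FALSE, L)
  for (i in seq_len(n_rep)) in_repeat[starts[i] + seq_len(cfg$alu_length)] <- TRUE
  # recoding sites: genome-A positions outside repeats
  outside_A <- which(bg == "A" & !in_repeat) - 1L
  rec_pos <- sort(sample(outside_A, cfg$n_recoding_sites))
  all_pos <- c(ed_pos, rec_pos)
  all_strand <- c(ed_strand, rep("+", length(rec_pos)))
  recoding <- c(rep(FALSE, length(ed_pos)), rep(TRUE, length(rec_pos)))
  ord <- order(all_pos)
  catalog <- site_catalog(chrom = rep(chrom, length(all_pos)),
                          pos1 = all_pos[ord] + 1L,
                          strand = all_strand[ord],
                          recoding = recoding[ord],
                          genome = genome)
  # programmed levels
  set.seed(substream(cfg$seed, 2L))
  n_sites <- nrow(catalog)
  lev <- if (cfg$level_type == "fixed") rep(cfg$level, n_sites)
         else rbeta(n_sites, cfg$beta_a, cfg$beta_b)
  truth_sites <- as.data.frame(catalog)
  truth_sites$level <- lev
  truth_sites$class <- ifelse(truth_sites$recoding, "recoding", "alu")
  # het SNPs outside repeats, disjoint from catalog
  set.seed(substream(cfg$seed, 3L))
  cand <- setdiff(which(!in_repeat) - 1L, c(all_pos, 0:(cfg$read_length), (L - cfg$read_length):(L - 1L)))
  snp_pos <- sort(sample(cand, cfg$n_het_snps))
  snp_ref <- bg[snp_pos + 1L]
  snp_alt <- vapply(snp_ref, function(r) sample(setdiff(BASES, r), 1L), "")
  snps <- data.frame(chrom = rep(chrom, length(snp_pos)), pos = snp_pos,
                     ref = snp_ref, alt = unname(snp_alt),
                     stringsAsFactors = FALSE)
  list(genome = genome, repeats = repeats, catalog = catalog,
       snps = snps, truth_sites = truth_sites)
}

qual_string <- function(quals) intToUtf8(quals + 33L)

simulate_read_batch <- function(world, cfg, n_reads, carry_editing, seed) {
  set.seed(seed)
  genome <- world$genome; chrom <- "chr1"
  L <- cfg$genome_length; rl <- cfg$read_length
  bgc <- strsplit(genome$sequences[[chrom]], "")[[1]]
  starts <- sort(sample.int(L - rl + 1L, n_reads, replace = TRUE)) - 1L
  site_pos <- world$truth_sites$pos
  site_lev <- world$truth_sites$level
  site_strand <- world$truth_sites$strand
  snp_pos <- world$snps$pos; snp_alt <- world$snps$alt
  ed_tally_ed <- integer(length(site_pos))
  ed_tally_un <- integer(length(site_pos))
  seqs <- character(n_reads); quals <- character(n_reads)
  edited_at <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    st <- starts[i]
    idxs <- st + seq_len(rl) - 1L
    b <- bgc[idxs + 1L]
    # heterozygous SNPs: alt with probability 0.5 in every read
    sh <- which(snp_pos >= st & snp_pos < st + rl)
    for (j in sh) if (runif(1) < 0.5) b[snp_pos[j] - st + 1L] <- snp_alt[j]
    ed_here <- integer()
    if (carry_editing) {
      eh <- which(site_pos >= st & site_pos < st + rl)
      for (j in eh) {
        edited <- runif(1) < site_lev[j]
        off <- site_pos[j] - st + 1L
        if (edited) {
          b[off] <- if (site_strand[j] == "+") "G" else "C"
          ed_here <- c(ed_here, site_pos[j])
        }
      }
    }
    # independent base-call errors
    if (cfg$error_rate > 0) {
      err <- which(runif(rl) < cfg$error_rate)
      for (j in err) b[j] <- sample(setdiff(BASES, b[j]), 1L)
    }
    q <- rep(40L, rl)
    if (cfg$low_qual_frac > 0) {
      lowq <- which(runif(rl) < cfg$low_qual_frac)
      q[lowq] <- 20L
    }
    # truth tally of emitted bases at catalog sites (post error, pre filter)
    if (length(site_pos)) {
      ah <- which(site_pos >= st & site_pos < st + rl)
      for (j in ah) {
        off <- site_pos[j] - st + 1L
        ed_base <- if (site_strand[j] == "+") "G" else "C"
        un_base <- if (site_strand[j] == "+") "A" else "T"
        if (b[off] == ed_base) ed_tally_ed[j] <- ed_tally_ed[j] + 1L
        else if (b[off] == un_base) ed_tally_un[j] <- ed_tally_un[j] + 1L
      }
    }
    seqs[i] <- paste(b, collapse = "")
    quals[i] <- qual_string(q)
    edited_at[[i]] <- ed_here
  }
  rev_flag <- runif(n_reads) < 0.5
  reads <- data.frame(
    name = sprintf("r%08d", seq_len(n_reads)),
    flag = ifelse(rev_flag, 16L, 0L),
    chrom = chrom, pos = starts, mapq = 60L,
    cigar = sprintf("%dM", rl), seq = seqs, qual = quals,
    n_hits = 1L, is_reverse = rev_flag, is_unmapped = FALSE,
    stringsAsFactors = FALSE)
  list(reads = reads, edited_at = edited_at,
       tally = data.frame(chrom = chrom, pos = site_pos,
                          edited = ed_tally_ed, unedited = ed_tally_un))
}

simulate_hyper_reads <- function(world, cfg, seed) {
  set.seed(seed)
  if (cfg$n_hyper_reads == 0L)
    return(list(reads = data.frame(), truth = data.frame(
      name = character(), chrom = character(), pos = integer(),
      pass = character(), positions = character(), stringsAsFactors = FALSE)))
  genome <- world$genome; chrom <- "chr1"; rl <- cfg$read_length
  bgc <- strsplit(genome$sequences[[chrom]], "")[[1]]
  reps <- world$repeats
  rows <- vector("list", cfg$n_hyper_reads)
  truth <- vector("list", cfg$n_hyper_reads)
  for (i in seq_len(cfg$n_hyper_reads)) {
    k <- sample.int(length(reps), 1L)
    r_start <- GenomicRanges::start(reps)[k] - 1L
    r_end <- GenomicRanges::end(reps)[k]
    strand <- as.character(GenomicRanges::strand(reps))[k]
    lo <- max(0L, r_start - (rl - 50L)); hi <- min(cfg$genome_length - rl, r_end - 50L)
    st <- sample(seq(lo, hi), 1L)
    b <- bgc[st + seq_len(rl)]
    from <- if (strand == "+") "A" else "T"
    to <- if (strand == "+") "G" else "C"
    cand <- which(b == from)
    n_ed <- max(cfg$min_hyper_sites %||% 4L, ceiling(cfg$hyper_fraction * length(cand)))
    n_ed <- min(n_ed, length(cand))
    pick <- sort(sample(cand, n_ed))
    b[pick] <- to
    rows[[i]] <- data.frame(
      name = sprintf("h%05d", i), flag = 4L, chrom = "*", pos = NA_integer_,
      mapq = 0L, cigar = "*", seq = paste(b, collapse = ""),
      qual = qual_string(rep(40L, rl)), n_hits = 1L, is_reverse = FALSE,
      is_unmapped = TRUE, stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(
      name = sprintf("h%05d", i), chrom = chrom, pos = st,
      pass = if (strand == "+") "AG" else "TC",
      positions = paste(st + pick - 1L, collapse = ","),
      stringsAsFactors = FALSE)
  }
  list(reads = do.call(rbind, rows), truth = do.call(rbind, truth))
}

#' Simulate a full synthetic dataset with truth
#'
#' Builds the genome and annotations ([make_genome()]), samples RNA reads
#' carrying the programmed per-site editing levels, WGS reads carrying the
#' heterozygous SNPs but never editing, multi-mapped reads when configured,
#' and hyper-edited unmapped reads; optionally writes everything to `dir`
#' (FASTA, SAM, FASTQ, BED, TSV, truth JSON).
#'
#' @param cfg a [sim_config()].
#' @param dir output directory, or `NULL` to skip file output.
#' @return list of class `sim_dataset`: `genome, repeats, catalog, snps,
#'   truth_sites` (with realized `edited`/`unedited` read tallies),
#'   `rna_reads, wgs_reads, hyper_reads, hyper_truth, files` (paths when
#'   `dir` given).
#' @export
simulate_dataset <- function(cfg, dir = NULL) {
  world <- make_genome(cfg)
  n_rna <- ceiling(cfg$depth * cfg$genome_length / cfg$read_length)
  n_wgs <- ceiling(cfg$wgs_depth * cfg$genome_length / cfg$read_length)
  rna <- simulate_read_batch(world, cfg, n_rna, carry_editing = TRUE,
                             seed = substream(cfg$seed, 4L))
  wgs <- simulate_read_batch(world, cfg, n_wgs, carry_editing = FALSE,
                             seed = substream(cfg$seed, 5L))
  wgs$reads$name <- sub("^r", "w", wgs$reads$name)
  hyper <- simulate_hyper_reads(world, cfg, seed = substream(cfg$seed, 6L))
  rna_reads <- rna$reads
  if (cfg$n_multimap_reads > 0L) {
    set.seed(substream(cfg$seed, 7L))
    st <- GenomicRanges::start(world$repeats)[1] - 1L + 10L
    mm <- rna_reads[rep(1L, cfg$n_multimap_reads), , drop = FALSE]
    mm$name <- sprintf("m%05d", seq_len(cfg$n_multimap_reads))
    mm$pos <- st
    seqv <- strsplit(genome_fetch(world$genome, "chr1", st, st + cfg$read_length), "")[[1]]
    # plant a variant so the locus is called, then removed by stage E
    alt_off <- which(seqv == "A")[5]
    seqv[alt_off] <- "G"
    mm$seq <- paste(seqv, collapse = "")
    mm$qual <- qual_string(rep(40L, cfg$read_length))
    mm$n_hits <- 2L
    mm$flag <- 0L; mm$is_reverse <- FALSE
    rna_reads <- rbind(rna_reads, mm)
    rna_reads <- rna_reads[order(rna_reads$pos), , drop = FALSE]
    attr(rna_reads, "multimap_site") <- st + alt_off - 1L
  }
  truth_sites <- world$truth_sites
  truth_sites$edited <- rna$tally$edited
  truth_sites$unedited <- rna$tally$unedited
  out <- list(genome = world$genome, repeats = world$repeats,
              catalog = world$catalog, snps = world$snps,
              truth_sites = truth_sites, rna_reads = rna_reads,
              wgs_reads = wgs$reads, hyper_reads = hyper$reads,
              hyper_truth = hyper$truth,
              multimap_site = attr(rna_reads, "multimap_site"),
              config = cfg, files = NULL)
  class(out) <- "sim_dataset"
  if (!is.null(dir)) out <- write_sim_dataset(out, dir)
  out
}

#' Write a simulated dataset to files
#' @param sim a `sim_dataset`.
#' @param dir output directory (created if needed).
#' @return the `sim_dataset` with `files` filled in.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- list(genome = file.path(dir, "genome.fa"),
            repeats = file.path(dir, "repeats.bed"),
            catalog = file.path(dir, "catalog.tsv"),
            snps = file.path(dir, "snps.tsv"),
            rna = file.path(dir, "rna.sam"),
            wgs = file.path(dir, "wgs.sam"),
            hyper_fastq = file.path(dir, "hyper.fastq"),
            truth = file.path(dir, "truth.json"))
  write_genome(sim$genome, f$genome)
  write_regions(sim$repeats, f$repeats)
  cat_df <- as.data.frame(sim$catalog)
  write.table(data.frame(chrom = cat_df$chrom, position = cat_df$pos + 1L,
                         strand = cat_df$strand,
                         recoding = ifelse(cat_df$recoding, "yes", "no"),
                         aa_change = cat_df$aa_change, gene = cat_df$gene),
              f$catalog, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(chrom = sim$snps$chrom, position = sim$snps$pos + 1L),
              f$snps, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  rna_all <- rbind(sim$rna_reads,
                   if (nrow(sim$hyper_reads)) sim$hyper_reads else NULL)
  write_sam(rna_all, sim$genome, f$rna)
  write_sam(sim$wgs_reads, sim$genome, f$wgs)
  if (nrow(sim$hyper_reads)) {
    writeLines(as.vector(rbind(paste0("@", sim$hyper_reads$name),
                               sim$hyper_reads$seq, "+",
                               sim$hyper_reads$qual)), f$hyper_fastq)
  } else writeLines(character(), f$hyper_fastq)
  jsonlite::write_json(
    list(seed = sim$config$seed,
         sites = sim$truth_sites,
         snps = sim$snps,
         hyper = sim$hyper_truth),
    f$truth, auto_unbox = TRUE, digits = NA)
  sim$files <- f
  sim
}

#' Independent truth verification by SAM recount
#'
#' Re-parses the emitted RNA SAM with its own minimal text parser (no
#' shared code with the pileup engine), tallies the edited/unedited base at
#' every truth site over all mapped reads, and compares with the truth-side
#' bookkeeping recorded during simulation.
#'
#' @param sam_path path to the RNA SAM written by [write_sim_dataset()].
#' @param truth_sites the `truth_sites` data frame of a `sim_dataset`.
#' @return list: `consistent` flag, `recount` data frame, and
#'   `first_mismatch` (row index or `NA`).
#' @export
verify_truth <- function(sam_path, truth_sites) {
  lines <- readLines(sam_path)
  body <- lines[!startsWith(lines, "@")]
  ed <- integer(nrow(truth_sites)); un <- integer(nrow(truth_sites))
  site_pos <- truth_sites$pos
  ed_base <- ifelse(truth_sites$strand == "+", "G", "C")
  un_base <- ifelse(truth_sites$strand == "+", "A", "T")
  for (ln in body) {
    fld <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(fld[2])
    if (bitwAnd(flag, 4L) > 0L) next
    nh <- grep("^NH:i:", fld[-(1:11)], value = TRUE)
    if (length(nh) && as.integer(sub("NH:i:", "", nh[1])) > 1L) next
    if (fld[6] != paste0(nchar(fld[10]), "M")) next  # toy recount: full-M reads
    st <- as.integer(fld[4]) - 1L
    len <- nchar(fld[10])
    hit <- which(site_pos >= st & site_pos < st + len &
                   truth_sites$chrom == fld[3])
    for (j in hit) {
      b <- substr(fld[10], site_pos[j] - st + 1L, site_pos[j] - st + 1L)
      if (b == ed_base[j]) ed[j] <- ed[j] + 1L
      else if (b == un_base[j]) un[j] <- un[j] + 1L
    }
  }
  recount <- data.frame(chrom = truth_sites$chrom, pos = site_pos,
                        edited = ed, unedited = un)
  ok <- ed == truth_sites$edited & un == truth_sites$unedited
  list(consistent = all(ok), recount = recount,
       first_mismatch = if (all(ok)) NA_integer_ else which(!ok)[1])
}

#' Simulate per-sample editing levels for differential testing
#'
#' Site-level cohort simulator: per-site true editing levels are drawn from
#' Beta distributions (null sites share one distribution across groups;
#' shifted sites have their group-2 mean displaced by `delta`), and
#' observed levels are binomial read draws at the given coverage, the same
#' noise model that read-level simulation induces at a site.
#'
#' @param n_null number of null (no-difference) sites (default 100).
#' @param n_shifted number of truly shifted sites (default 10).
#' @param delta group-2 minus group-1 mean editing at shifted sites
#'   (default 0.3).
#' @param n_per_group samples per group (default 12).
#' @param base_mean mean editing at null sites and at shifted sites in
#'   group 1 (default 0.2).
#' @param concentration Beta concentration (a + b) of the per-sample level
#'   distribution (default 50).
#' @param coverage per-sample read coverage (default 50).
#' @param seed RNG seed (mandatory).
#' @return list: `group1`, `group2` (`sample_levels` objects) and `truth`
#'   (data frame with `shifted` flag per site).
#' @export
simulate_level_cohort <- function(n_null = 100L, n_shifted = 10L, delta = 0.3,
                                  n_per_group = 12L, base_mean = 0.2,
                                  concentration = 50, coverage = 50L, seed) {
  if (missing(seed)) stop2("simulate_level_cohort requires a seed")
  set.seed(seed)
  n_sites <- n_null + n_shifted
  shifted <- c(rep(FALSE, n_null), rep(TRUE, n_shifted))
  draw <- function(mu, n) {
    a <- mu * concentration; b <- (1 - mu) * concentration
    rbeta(n, a, b)
  }
  lv1 <- t(vapply(seq_len(n_sites), function(i)
    draw(base_mean, n_per_group), numeric(n_per_group)))
  mu2 <- ifelse(shifted, base_mean + delta, base_mean)
  lv2 <- t(vapply(seq_len(n_sites), function(i)
    draw(mu2[i], n_per_group), numeric(n_per_group)))
  obs <- function(lv) {
    m <- matrix(rbinom(length(lv), coverage, as.vector(lv)) / coverage,
                nrow = nrow(lv))
    m
  }
  cov_m <- matrix(coverage, n_sites, n_per_group)
  sites <- data.frame(chrom = "sim", pos = seq_len(n_sites) - 1L,
                      shifted = shifted)
  list(group1 = sample_levels_from_matrices(obs(lv1), cov_m, sites),
       group2 = sample_levels_from_matrices(obs(lv2), cov_m, sites),
       truth = sites)
}
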
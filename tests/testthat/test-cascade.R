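test_that("stage A calls mismatch-bearing positions with class and frequency", {
  counts <- mk_counts_tbl(
    mk_counts("chr1", 10, "A", A = 9L, G = 1L),
    mk_counts("chr1", 20, "A", A = 12L),          # pure reference: no call
    mk_counts("chr1", 30, "T", T = 7L, C = 3L),
    mk_counts("chr1", 40, "C", C = 5L, A = 2L))
  calls <- call_stage_A(counts)
  expect_equal(nrow(calls), 3L)
  ag <- calls[calls$pos == 10L, ]
  expect_equal(ag$class, "AG")
  expect_equal(ag$freq, 0.1)
  expect_equal(ag$strand, "+")
  tc <- calls[calls$pos == 30L, ]
  expect_equal(tc$class, "TC")
  expect_equal(tc$strand, "-")
  expect_equal(calls[calls$pos == 40L, ]$strand, "?")
  expect_equal(nrow(call_stage_A(mk_counts("chr1", 1, "A", A = 1L)[0, ])), 0L)
})

test_that("stage A call count equals a brute-force mismatch scan on simulation", {
  sim <- shared_sim()
  pu <- pileup(sim$rna_reads, sim$genome)
  calls <- call_stage_A(pu)
  # oracle: positions where surviving counts contain a non-reference base
  m <- base_count_matrix(pu)
  ref_idx <- match(pu$ref, c("A", "C", "G", "T"))
  nonref <- rowSums(m) - m[cbind(seq_len(nrow(m)), ref_idx)]
  expect_equal(nrow(calls), sum(nonref > 0 & !is.na(ref_idx)))
})

test_that("stage B removes SNPs, low WGS coverage and heterozygous evidence", {
  calls <- call_stage_A(mk_counts_tbl(
    mk_counts("chr1", 10, "A", A = 8L, G = 4L),
    mk_counts("chr1", 20, "A", A = 8L, G = 4L),
    mk_counts("chr1", 30, "A", A = 8L, G = 4L),
    mk_counts("chr1", 40, "A", A = 8L, G = 4L)))
  wgs <- mk_counts_tbl(
    mk_counts("chr1", 10, "A", A = 12L),            # clean homozygous ref
    mk_counts("chr1", 20, "A", A = 9L),             # coverage 9 < 10
    mk_counts("chr1", 30, "A", A = 6L, G = 6L),     # het: alt fraction 0.5
    mk_counts("chr1", 40, "A", A = 15L))            # clean but in SNP set
  snps <- snp_set("chr1", 41L)                       # 1-based 41 == 0-based 40
  out <- apply_stage_B(calls, wgs, snps)
  expect_equal(out$pos, 10L)
  expect_equal(out$stages, "AB")
})

test_that("stage C enforces coverage and homopolymer bounds", {
  g <- genome_ref(c(chr1 = paste0(strrep("C", 9), "AAAAAA", strrep("C", 5),
                                  "AAAAA", strrep("G", 20))))
  # run of 6 at pos 9..14; run of 5 at pos 20..24
  expect_equal(homopolymer_run(g, "chr1", 10L), 6L)
  expect_equal(homopolymer_run(g, "chr1", 22L), 5L)
  calls <- call_stage_A(mk_counts_tbl(
    mk_counts("chr1", 10, "A", A = 9L, G = 3L),     # inside run of 6: removed
    mk_counts("chr1", 22, "A", A = 7L, G = 3L),     # inside run of 5: kept
    mk_counts("chr1", 30, "G", G = 6L, A = 3L)))    # coverage 9 < 10: removed
  out <- apply_stage_C(calls, g)
  expect_equal(out$pos, 22L)
})

test_that("stage D keeps frequency at or above 0.1 exactly", {
  calls <- call_stage_A(mk_counts_tbl(
    mk_counts("chr1", 10, "A", A = 9L, G = 1L),      # 0.1000: kept
    mk_counts("chr1", 20, "A", A = 9010L, G = 999L), # 0.0999: removed
    mk_counts("chr1", 30, "A", A = 5L, G = 5L)))
  out <- apply_stage_D(calls)
  expect_setequal(out$pos, c(10L, 30L))
})

test_that("stage E removes junction-proximal and low-confidence-supported calls", {
  calls <- call_stage_A(mk_counts_tbl(
    mk_counts("chr1", 10, "A", A = 8L, G = 4L),
    mk_counts("chr1", 100, "A", A = 8L, G = 4L)))
  junctions <- GenomicRanges::GRanges("chr1", IRanges::IRanges(13, 13))
  out <- apply_stage_E(calls, junctions)  # pos 10 is 2 nt away, window 4
  expect_equal(out$pos, 100L)

  lowconf <- calls
  lowconf$lowconf_frac <- c(0.5, 0)
  out2 <- apply_stage_E(lowconf, NULL)
  expect_equal(out2$pos, 100L)
  expect_equal(nrow(apply_stage_E(calls, NULL)), 2L)
})

test_that("cascade is monotone and recalls all eligible programmed sites", {
  sim <- shared_sim()
  pu <- pileup(sim$rna_reads, sim$genome)
  wgs_pu <- pileup(sim$wgs_reads, sim$genome)
  snps <- snp_set(sim$snps$chrom, sim$snps$pos + 1L)
  res <- call_editing(pu, sim$genome, wgs_pu, snps)
  expect_true(all(diff(res$per_stage) <= 0))

  # every programmed site that is eligible (covered >= 10, freq >= 0.1,
  # outside homopolymers; no junctions simulated) survives to stage E
  cs <- count_at_sites(sim$rna_reads, sim$genome, sim$catalog)
  lev <- site_level(cs)
  m <- base_count_matrix(cs)
  informative <- ifelse(cs$strand == "+", m[, "A"] + m[, "G"], m[, "T"] + m[, "C"])
  runs <- mapply(homopolymer_run, pos = cs$pos,
                 MoreArgs = list(genome = sim$genome, chrom = "chr1"))
  # stage-B eligibility: homozygous-reference WGS support at depth >= 10
  mw <- base_count_matrix(wgs_pu)
  idxw <- match(paste(cs$chrom, cs$pos), paste(wgs_pu$chrom, wgs_pu$pos))
  wcov <- ifelse(is.na(idxw), 0, rowSums(mw)[idxw])
  wref <- ifelse(is.na(idxw), 0,
                 mw[cbind(ifelse(is.na(idxw), 1L, idxw), match(cs$ref, c("A", "C", "G", "T")))])
  # stage-E eligibility: high-confidence read support
  idxp <- match(paste(cs$chrom, cs$pos), paste(pu$chrom, pu$pos))
  lc <- ifelse(is.na(idxp), 1, pu$lowconf[idxp] / pu$n_reads[idxp])
  eligible <- !is.na(lev) & lev >= 0.1 & informative >= 10 & runs <= 5 &
    wcov >= 10 & (wcov - wref) / pmax(wcov, 1) < 0.1 & lc <= 0.1
  called <- paste(res$calls$chrom, res$calls$pos)
  expect_true(all(paste(cs$chrom, cs$pos)[eligible] %in% called))

  # every programmed het SNP with WGS coverage >= 10 is gone by stage B
  wgs_cov <- rowSums(base_count_matrix(wgs_pu))
  idx <- match(sim$snps$pos, wgs_pu$pos)
  snp_elig <- !is.na(idx) & wgs_cov[idx] >= 10
  called_b <- paste(res$stages$B$chrom, res$stages$B$pos)
  expect_false(any(paste(sim$snps$chrom, sim$snps$pos)[snp_elig] %in% called_b))

  # the planted multi-mapped locus is removed at stage E
  expect_true(sim$multimap_site %in% res$stages$D$pos)
  expect_false(sim$multimap_site %in% res$calls$pos)
})

test_that("mismatch spectrum arithmetic and FDR estimate follow their definitions", {
  mk_calls <- function(classes) {
    data.frame(chrom = rep("chr1", length(classes)), pos = seq_along(classes), class = classes,
               stringsAsFactors = FALSE)
  }
  classes <- c(rep("AG", 100), rep("TC", 10),
               c("AC", "AT", "CA", "CG", "CT", "GA", "GC", "GT", "TA", "TG"))
  sp <- mismatch_spectrum(mk_calls(classes))
  expect_equal(sum(sp$counts), 120L)
  expect_equal(sp$ag_tc_fraction, 110 / 120)
  expect_equal(sp$fdr_estimate, 1 / 110)

  sp_pure <- mismatch_spectrum(mk_calls(rep("AG", 50)))
  expect_equal(sp_pure$ag_tc_fraction, 1)
  expect_equal(sp_pure$fdr_estimate, 0)

  sp_none <- mismatch_spectrum(mk_calls(character()))
  expect_true(is.na(sp_none$ag_tc_fraction))
})

test_that("error-free simulation yields a pure spectrum and zero estimated FDR", {
  cfg <- sim_config(genome_length = 3000L, n_alu_pairs = 1L,
                    n_editing_sites = 40L, n_recoding_sites = 4L,
                    n_het_snps = 0L, depth = 40, error_rate = 0,
                    low_qual_frac = 0, n_hyper_reads = 0L, seed = 11L)
  sim <- simulate_dataset(cfg)
  pu <- pileup(sim$rna_reads, sim$genome)
  res <- call_editing(pu, sim$genome, wgs_counts = NULL, snps = NULL)
  sp <- mismatch_spectrum(res$calls)
  expect_equal(sp$fdr_estimate, 0)
  expect_equal(sp$ag_tc_fraction, 1)
})
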
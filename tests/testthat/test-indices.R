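test_that("site-level editing follows strand-aware informative counts", {
  counts <- mk_counts_tbl(
    mk_counts("chr1", 1, "A", A = 8L, G = 2L, strand = "+"),
    mk_counts("chr1", 2, "T", T = 7L, C = 3L, strand = "-"),
    mk_counts("chr1", 3, "A", C = 5L, strand = "+"))
  lev <- site_level(counts)
  expect_equal(lev[1], 0.2)
  expect_equal(lev[2], 0.3)
  expect_true(is.na(lev[3]))
})

test_that("overall index pools edited over informative reads with no cutoff", {
  counts <- mk_counts_tbl(
    mk_counts("chr1", 1, "A", A = 8L, G = 2L),
    mk_counts("chr1", 2, "A", A = 5L),
    mk_counts("chr1", 3, "A", A = 7L, G = 3L))
  r <- overall_index(counts)
  expect_equal(r$value, 100 * 5 / 25)
  expect_equal(r$numerator, 5L)
  expect_equal(r$denominator, 25L)

  none <- overall_index(mk_counts_tbl(mk_counts("chr1", 1, "A", A = 9L)))
  expect_equal(none$value, 0)

  undef <- overall_index(mk_counts("chr1", 1, "A", C = 4L))
  expect_true(is.na(undef$value))

  # non-informative bases enter the denominator only on request
  mixed <- mk_counts_tbl(mk_counts("chr1", 1, "A", A = 6L, G = 2L, C = 2L))
  expect_equal(overall_index(mixed)$denominator, 8L)
  expect_equal(overall_index(mixed, denominator = "all")$denominator, 10L)
})

test_that("overall index equals the coverage-weighted mean of site levels", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    counts <- do.call(mk_counts_tbl, lapply(seq_len(n), function(i) {
      strand <- sample(c("+", "-"), 1)
      if (strand == "+")
        mk_counts("chr1", i, "A", A = sample(0:30, 1), G = sample(0:10, 1),
                  strand = "+")
      else
        mk_counts("chr1", i, "T", T = sample(0:30, 1), C = sample(0:10, 1),
                  strand = "-")
    }))
    lev <- site_level(counts)
    m <- base_count_matrix(counts)
    w <- ifelse(counts$strand == "+", m[, "A"] + m[, "G"], m[, "T"] + m[, "C"])
    ok <- !is.na(lev)
    if (!any(ok)) next
    expect_equal(overall_index(counts)$value,
                 100 * sum(lev[ok] * w[ok]) / sum(w[ok]))
  }
})

test_that("recoding index restricts the same arithmetic to recoding sites", {
  counts <- mk_counts_tbl(
    mk_counts("chr1", 1, "A", A = 1L, G = 9L),
    mk_counts("chr1", 2, "A", A = 10L, G = 0L))
  catalog <- site_catalog("chr1", c(2, 3), c("+", "+"),
                          recoding = c(TRUE, FALSE))
  r <- recoding_index(counts, catalog)
  expect_equal(r$kind, "REI")
  expect_equal(r$value, 90)

  all_rec <- site_catalog("chr1", c(2, 3), c("+", "+"),
                          recoding = c(TRUE, TRUE))
  expect_equal(recoding_index(counts, all_rec)$value,
               overall_index(counts)$value)
  none <- site_catalog("chr1", c(2, 3), c("+", "+"))
  expect_true(is.na(recoding_index(counts, none)$value))
})

test_that("AEI counts adenosine coverage inside stranded repeat intervals", {
  # genome: 20 A's then 20 T's; reads place G mismatches on some A's
  g <- genome_ref(c(chr1 = paste0(strrep("A", 40), strrep("T", 40))))
  seq1 <- paste0(strrep("A", 10), "G", strrep("A", 19))  # G at pos 10
  reads <- mk_reads(mk_read("r1", "chr1", 0, seq1),
                    mk_read("r2", "chr1", 0, strrep("A", 30)),
                    mk_read("r3", "chr1", 40, strrep("T", 30)),
                    mk_read("r4", "chr1", 40, paste0(strrep("T", 12), "C", strrep("T", 17))))
  regions <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(c(1, 41), c(40, 80)),
                                    strand = c("+", "-"))
  r <- alu_index(reads, g, regions)
  # '+' interval: A positions 6..23 covered (trim), 1 G among them;
  # '-' interval: genome-T positions, 1 C among them
  expect_equal(r$numerator, 2L)
  expect_gt(r$value, 0)

  # splitting one interval in two leaves the index unchanged
  split <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(c(1, 21, 41), c(20, 40, 80)),
                                  strand = c("+", "+", "-"))
  expect_equal(alu_index(reads, g, split)$value, r$value)

  # multi-mapped reads are excluded by default
  mm <- mk_read("m", "chr1", 0, seq1, n_hits = 2L)
  expect_equal(alu_index(mk_reads(mm), g, regions)$numerator, 0L)
  expect_equal(alu_index(mk_reads(mm), g, regions, unique_only = FALSE)$numerator, 1L)
})

test_that("subsampling the catalog reproduces the full index at full size", {
  sim <- shared_sim()
  counts <- count_at_sites(sim$rna_reads, sim$genome, sim$catalog)
  # three pseudo-samples: resampled read subsets of the one simulation
  set.seed(5)
  samples <- lapply(1:3, function(i) {
    keep <- runif(nrow(sim$rna_reads)) < 0.7
    count_at_sites(sim$rna_reads[keep, , drop = FALSE], sim$genome, sim$catalog)
  })
  names(samples) <- paste0("s", 1:3)
  rep_full <- subsample_robustness(samples, sizes = nrow(sim$catalog),
                                   n_reps = 2L, seed = 1L)
  expect_true(all(abs(rep_full$correlations$r - 1) < 1e-12))
  rep_small <- subsample_robustness(samples, sizes = c(5L, 20L), n_reps = 3L,
                                    seed = 2L)
  expect_true(all(rep_small$correlations$r >= -1 & rep_small$correlations$r <= 1,
                  na.rm = TRUE))
  # reproducible under the same seed
  rep_small2 <- subsample_robustness(samples, sizes = c(5L, 20L), n_reps = 3L,
                                     seed = 2L)
  expect_equal(rep_small$correlations, rep_small2$correlations)
  expect_error(subsample_robustness(samples, sizes = 10000L, n_reps = 1L,
                                    seed = 1L), "exceeds")
})

test_that("doubling read depth shrinks the recovery error of the overall index", {
  errs <- sapply(1:6, function(s) {
    sapply(c(15, 60), function(d) {
      cfg <- sim_config(genome_length = 3000L, n_alu_pairs = 1L,
                        n_editing_sites = 40L, n_recoding_sites = 0L,
                        n_het_snps = 0L, depth = d, n_hyper_reads = 0L,
                        error_rate = 0, seed = 100L + s)
      sim <- simulate_dataset(cfg)
      counts <- count_at_sites(sim$rna_reads, sim$genome, sim$catalog)
      abs(overall_index(counts)$value - 15)
    })
  })
  expect_lt(mean(errs[2, ]), mean(errs[1, ]))
})
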
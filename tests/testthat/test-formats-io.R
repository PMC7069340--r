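test_that("load_genome uppercases, validates and indexes FASTA records", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "acgtACGT", ">chr2", "GGGGCCCC"), fa)
  g <- load_genome(fa)
  expect_equal(unname(g$sequences["chr1"]), "ACGTACGT")
  expect_equal(unname(g$lengths), c(8L, 8L))
  expect_length(g$lengths, 2L)
  expect_equal(genome_fetch(g, "chr1", 2, 5), "GTA")
  expect_equal(nchar(genome_fetch(g, "chr2", 0, 8)), 8L)

  empty <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(), empty)
  expect_error(load_genome(empty), "no records")

  dup <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ACGT", ">chr1", "ACGT"), dup)
  expect_error(load_genome(dup), "duplicate")

  bad <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ACXT"), bad)
  expect_error(load_genome(bad), "position 3")
})

test_that("read_alignments separates mapped/unmapped and honors regions", {
  g <- tiny_genome(c(chr1 = strrep("ACGT", 25), chr2 = strrep("ACGT", 25)))
  reads <- mk_reads(
    mk_read("a", "chr1", 0, "ACGTACGTAC"),
    mk_read("b", "chr1", 4, "ACGTACGTAC"),
    mk_read("c", "chr1", 8, "ACGTACGTAC"),
    mk_read("u", "*", NA, "ACGTACGTAC", is_unmapped = TRUE))
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam_text(reads, g, sam)

  mapped <- read_alignments(sam, g)
  expect_equal(nrow(mapped), 3L)
  expect_equal(mapped$pos, c(0L, 4L, 8L))
  expect_false(any(mapped$is_unmapped))

  un <- read_alignments(sam, g, unmapped = TRUE)
  expect_equal(un$name, "u")

  none <- read_alignments(sam, g,
                          region = list(chrom = "chr2", start0 = 0, end0 = 100))
  expect_equal(nrow(none), 0L)
})

test_that("reads with inconsistent CIGAR/sequence length are rejected", {
  g <- tiny_genome(c(chr1 = strrep("ACGT", 25)))
  sam_ok <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:chr1\tLN:100",
               sprintf("r1\t0\tchr1\t1\t60\t10M2I10M\t*\t0\t0\t%s\t%s",
                       strrep("A", 22), strrep("I", 22))), sam_ok)
  expect_equal(nrow(read_alignments(sam_ok, g)), 1L)

  sam_bad <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:chr1\tLN:100",
               sprintf("r1\t0\tchr1\t1\t60\t10M\t*\t0\t0\t%s\t%s",
                       strrep("A", 22), strrep("I", 22))), sam_bad)
  expect_error(read_alignments(sam_bad, g))
})

test_that("site catalog parsing validates strand, reference base and duplicates", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tposition\tstrand\trecoding\taa_change\tgene",
               "chr1\t100\t+\tyes\tK95R\tIGFBP7"), tsv)
  cat <- read_site_catalog(tsv)
  expect_equal(cat$pos, 99L)  # 0-based internally
  expect_true(cat$recoding)
  expect_equal(cat$aa_change, "K95R")
  expect_equal(cat$gene, "IGFBP7")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chrom\tposition\tstrand", empty)
  expect_equal(nrow(read_site_catalog(empty)), 0L)

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tposition\tstrand", "chr1\t100\t+", "chr1\t100\t-"), dup)
  expect_error(read_site_catalog(dup), "duplicate")

  # reference-base validation against the genome, on both strands
  g <- tiny_genome(c(chr1 = "AATTCCGG"))
  expect_silent(site_catalog("chr1", 1, "+", genome = g))  # ref A
  expect_silent(site_catalog("chr1", 3, "-", genome = g))  # ref T == A on '-'
  expect_error(site_catalog("chr1", 5, "+", genome = g), "A required")
})

test_that("SNP sets load from VCF and TSV; indels kept unless snv_only", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2", "#CHROM\tPOS\tID\tREF\tALT",
               "chr1\t5\t.\tA\tG", "chr1\t9\t.\tC\tT",
               "chr2\t3\t.\tAT\tA"), vcf)
  s <- read_snp_sites(vcf)
  expect_equal(nrow(s), 3L)  # indel position included by default
  expect_true(snp_member(s, "chr1", 4L))   # 0-based internal
  expect_false(snp_member(s, "chr1", 5L))

  s2 <- read_snp_sites(vcf, snv_only = TRUE)
  expect_equal(nrow(s2), 2L)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chr1\t5", tsv)
  expect_true(snp_member(read_snp_sites(tsv), "chr1", 4L))

  bad <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2", "chr1\tnope\t.\tA\tG\t.\t.\t."), bad)
  expect_error(read_snp_sites(bad), "line 2")
})

test_that("site tables round-trip losslessly", {
  g <- tiny_genome()
  counts <- mk_counts_tbl(mk_counts("chr1", 10, "A", A = 8L, G = 2L),
                          mk_counts("chr1", 20, "T", T = 5L, C = 5L))
  calls <- call_stage_A(counts)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_site_table(calls, path)
  back <- read_site_table(path)
  expect_equal(back$pos, calls$pos)
  expect_equal(as.data.frame(back)[, c("A", "C", "G", "T")],
               as.data.frame(calls)[, c("A", "C", "G", "T")])
  expect_equal(back$freq, round(calls$freq, 4))
  expect_equal(back$coverage, calls$coverage)

  # header-only file for an empty call set
  write_site_table(call_stage_A(empty_counts <- mk_counts_tbl(mk_counts("chr1", 1, "A", A = 1L))[0, ]),
                   path)
  expect_equal(nrow(read_site_table(path)), 0L)
})

test_that("region overlap queries agree with a brute-force interval scan", {
  set.seed(7)
  bed <- withr::local_tempfile(fileext = ".bed")
  n <- 60L
  start0 <- sample.int(5000L, n)
  end0 <- start0 + sample.int(300L, n)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  writeLines(sprintf("chr1\t%d\t%d\tr%d\t0\t%s", start0, end0, seq_len(n), strand), bed)
  gr <- read_regions(bed)
  expect_equal(length(gr), n)
  expect_equal(as.character(GenomicRanges::strand(gr)), strand)

  for (rep in 1:1000) {
    q <- sample.int(5500L, 1L) - 1L  # 0-based point query
    hits_gr <- S4Vectors::subjectHits(GenomicRanges::findOverlaps(
      GenomicRanges::GRanges("chr1", IRanges::IRanges(q + 1L, q + 1L)), gr,
      ignore.strand = TRUE))
    hits_bf <- which(start0 <= q & q < end0)
    expect_equal(sort(hits_gr), sort(hits_bf))
  }
})
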
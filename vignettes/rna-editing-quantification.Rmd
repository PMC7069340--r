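---
title: "Detecting and quantifying A-to-I RNA editing with rnaeditr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying A-to-I RNA editing with rnaeditr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaeditr)
```

## The problem

Adenosine-to-inosine (A-to-I) editing is the most common RNA modification in
mammals: ADAR enzymes deaminate adenosines in double-stranded RNA, and since
sequencers read inosine as guanosine, editing appears in RNA-seq alignments
as A→G mismatches against the reference genome (or T→C on the opposite
strand of unstranded libraries). The analytical difficulty is that A→G
mismatches also arise from sequencing errors, alignment artifacts and
genomic SNPs, and that editing levels are mostly low — so naive mismatch
counting is dominated by noise. `rnaeditr` implements the standard defensive
pipeline for this problem: a heavily filtered pileup-based caller, global
editing indices that aggregate over many sites rather than trusting any one
of them, a rescue path for reads too heavily edited to align at all, and
rank-based differential testing between sample groups.

## Candidate calling: the filter cascade

Reads are converted to strand-aware per-position base tallies by a pileup
that applies two per-base filters before anything is counted: a minimum
phred base quality of 30 (≈0.1% error probability) and exclusion of the
first and last six bases of every read, where library-preparation and
alignment artifacts concentrate. The end exclusion is measured on the query
sequence, so soft-clipped bases count toward the end distance; the boundary
is exact — query offsets 1–6 and the symmetric tail are excluded, offset 7
is counted. Reads below MAPQ 20 are tallied but never counted.

Candidates then pass through five cumulative stages:

* **A** — every position whose surviving counts contain a non-reference
  base, classified into the twelve substitution classes by the most
  frequent alternative base.
* **B** — genomic evidence: at least 10 WGS reads, a WGS non-reference
  fraction below 0.1 (a homozygosity test that removes heterozygous SNPs
  invisible to public catalogs), and absence from the SNP exclusion set.
  The 0.1 homozygosity bound is a toolkit default; the source material for
  this stage specifies only the coverage requirement, so the threshold is
  configurable and echoed in every run report.
* **C** — at least 10 covering RNA reads, and no reference homopolymer run
  longer than five residues containing the site (runs of exactly five are
  kept; six or more are removed).
* **D** — editing frequency (variant reads over reference-plus-variant
  reads) of at least 0.1, boundary included.
* **E** — mapping confidence: sites within 4 nt of a splice junction are
  removed, as are sites where more than 10% of covering reads are
  multi-mapped (`NH > 1`) or below the MAPQ threshold. This stage replaces
  an external re-alignment check with a mapping-confidence proxy computed
  from the alignment itself; a pre-filtered read stream can be supplied
  where a true re-alignment pass is available. The 4 nt window and 10%
  fraction are declared toolkit defaults — the quantities they bound are
  described only qualitatively in the literature ("near splice sites",
  "poorly aligned") — and both are configurable.

The mismatch spectrum of any call set summarises the twelve substitution
classes. Because genuine editing is almost exclusively A→G (plus its T→C
mirror), the pooled AG+TC fraction measures signal purity, and the mean
count of the ten other classes divided by the AG+TC count estimates the
false discovery rate of the call set — exactly zero on error-free
simulations, by construction.

## Editing indices

Three global activity measures are implemented, all as ratios of edited to
informative read counts (reported as percentages), never as unweighted
means of per-site levels:

* the **overall editing index** over a catalog of known sites, with no
  per-site coverage cutoff — zero-coverage sites simply contribute nothing;
* the **Alu editing index (AEI)** over every adenosine inside annotated
  repeat intervals (reference A in `+` intervals, reference T with C
  mismatches in `-` intervals), using uniquely mapped reads only;
* the **recoding editing index (REI)**, the same arithmetic restricted to
  nonsynonymous sites.

The denominator counts informative reads (reference plus edited base);
reads carrying any other base at the site are excluded by default, with
`denominator = "all"` available for the literal all-covering-reads
convention. A subsampling analysis (`subsample_robustness()`) draws growing
random subsets of the catalog and reports the Pearson correlation between
subset-based and full-catalog per-sample indices; a constant vector has no
defined correlation and is reported as missing rather than zero.

## Hyper-editing rescue

Reads with many edited adenosines fail normal alignment — too many
mismatches — and silently vanish from all of the above. The rescue path
transforms both the unaligned reads and the genome by collapsing the edited
base (A→G for the forward signal, T→C for the reverse; both passes run by
default), so that editing becomes invisible and the reads place cleanly.
Placements are mapped back to original coordinates and each read is
re-compared to the untransformed genome: a read passes as a hyper-editing
cluster when it shows at least 4 A→G mismatches, at least 60% of all its
mismatches are A→G, and other mismatches are at most 10% of the read
length. These thresholds are toolkit defaults (the protocol this step
follows is cited, not restated, by the source literature) and are fully
configurable. The built-in aligner is a seed-and-extend toy — a 20-mer
seed with at most one mismatch, full-read extension, at most 10% mismatches
in transformed space — sufficient for the synthetic genomes this package
ships with; the `aligner` argument of `rescue_align()` accepts an adapter
to any external aligner for real genomes. Rescued sites are kept out of the
AEI by default, matching how the index is normally computed.

## Differential editing

Between two groups of samples, testing is restricted to sites covered by at
least 10 reads in at least 50% of the samples of *each* group (an absolute
per-group count is available via `min_samples`; both conventions appear in
the field). Group levels are compared with the two-tailed Mann–Whitney U
test, U = #{x&lt;y} + ½·ties: the p-value is exact (full enumeration) when
n₁+n₂ ≤ 12 with no ties, and a tie- and continuity-corrected normal
approximation otherwise. Benjamini–Hochberg adjustment runs over exactly
the tested sites. Δ editing is mean(group 2) − mean(group 1) in the order
the groups are supplied, so with (artery, cerebellum) an artery-high site
prints a negative Δ — the convention of the bundled differential table.
Missing levels (insufficient coverage) are dropped, never imputed. The
coverage-ranked variant (`ranked_wilcoxon()`) orders sites by total read
coverage and tests only those with at least five sufficiently covered
samples per group.

## The synthetic-data generator

Every statement above is testable offline because `simulate_dataset()`
produces a complete dataset with known truth: a random genome carrying
inverted pairs of A-rich repeat elements (each pair is one random element
and its reverse complement, the double-stranded-RNA geometry that makes
such repeats the dominant editing substrate); programmed editing sites on
the repeat-strand adenosines plus recoding sites outside repeats;
heterozygous SNPs carried by both RNA and WGS reads with probability 0.5
per read; independent per-base errors; and heavily edited reads emitted
unmapped (and as FASTQ). Each read carries the edited base at a programmed
site with probability equal to the site's level — fixed (0.15 by default)
or Beta(1, 9) (mean 0.1), the regime used for the index-recovery analyses.
Because editing is binomial by construction, an index estimate should fall
within ~3 binomial standard errors of the programmed value, and the
recovery tests assert exactly that. `verify_truth()` recounts the emitted
SAM with an independent minimal parser and confirms the generator's own
bookkeeping; it is the anchor for all generator-derived oracles.

What the generator does *not* emulate: real repeat sequence content and
genome-wide repeat density, splicing (the junction filter is tested against
synthetic junction lists directly), indel alignment around editing sites,
coverage biases, strand-specific library protocols, and correlated error
modes of real sequencers. Passing tests therefore demonstrate the
correctness of the arithmetic and the filter logic under the stated noise
model, not performance on any particular real dataset.

Determinism: one seed drives everything through fixed per-stage substreams,
so identical configurations produce byte-identical outputs and adding a
downstream stage never perturbs an upstream one.

## Problem sizes and numerical choices

The test and acceptance analyses use 4 kb single-chromosome genomes with
two repeat pairs, read length 100, depth 200 for index recovery (60 for
cascade checks), 20 simulation seeds for the recovery and differential
power analyses, and the power design of 100 null + 10 shifted sites
(Δ = 0.3, 12 samples per group, coverage 50). These sizes give binomial
standard errors a few tenths of a percentage point wide — tight enough to
detect real arithmetic errors — while keeping a full run in the minutes
range on one CPU. Threshold boundaries are inclusive wherever the rule
says "at least"; frequency comparisons use exact arithmetic on counts, so
no floating-point tolerance is needed at stage boundaries. Pearson
correlations on zero-variance vectors, indices with empty denominators and
sites with no informative reads all return `NA` markers rather than zeros.

## A worked example

```{r example}
cfg <- sim_config(genome_length = 4000, n_alu_pairs = 2, depth = 60,
                  n_editing_sites = 80, seed = 20260921)
sim <- simulate_dataset(cfg)

pu <- pileup(sim$rna_reads, sim$genome)
res <- call_editing(pu, sim$genome,
                    wgs_counts = pileup(sim$wgs_reads, sim$genome),
                    snps = snp_set(sim$snps$chrom, sim$snps$pos + 1))
res$per_stage
mismatch_spectrum(res$calls)

counts <- count_at_sites(sim$rna_reads, sim$genome, sim$catalog)
overall_index(counts)
alu_index(sim$rna_reads, sim$genome, sim$repeats)
```

## Known limitations

* The built-in rescue aligner is deliberately minimal; real-genome
  hyper-editing analysis requires plugging in an external aligner through
  the adapter interface.
* Overlapping mate pairs double-count by default (a per-position
  mate-aware collapse is not implemented); pre-collapse the stream if this
  matters for your protocol.
* Duplicate reads are not detected; deduplicate upstream if required.
* The differential module tests level shifts only; population-frequency
  differences and model-based (e.g. beta-regression) approaches are out of
  scope.
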
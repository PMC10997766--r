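# linkphase

Simulation, processing and evaluation of **targeted linked-read
(microbead co-barcoded) phasing experiments** in R.

## The problem

Short reads cannot tell which of the two chromosome copies an allele sits
on. Linked-read library preparations recover that information by capturing
long DNA molecules on barcoded microbeads: every short read inherits its
bead's 18-base barcode, so reads sharing a barcode derive from one molecule
and therefore one haplotype. For *targeted* applications — a single
enriched locus, an amplicon, or a small panel (2–200 kb targets) — the
sample's low fragment diversity makes **DNA collisions** (two distinct
molecules on one bead, often the maternal and paternal copy of the same
locus) the central failure mode, alongside insufficient coverage and low
heterozygosity density.

`linkphase` is for method developers and analysts who want to study this
regime quantitatively. It provides:

* a **synthetic-data generator** with full ground truth: diploid loci with
  heterozygous SNVs every ~1–2 kb (or at pinned positions), picogram mass →
  molecule-count conversion (650 g/mol/bp), Poisson bead loading with an
  explicit mean load λ, equimolar lambda-digest filling DNA (fourteen
  BstP I fragments summing to 48.5 kb), off-target background, haplotype
  amplification bias / dropout, 2×145 bp barcoded read pairs with
  substitution, barcode-error and PCR-duplicate artifacts;
* the **processing chain**: exact-overlap adapter trimming, bead-barcode
  error correction (singletons one mismatch from a multi-read barcode),
  lite k-mer read mapping, within-barcode duplicate marking, pileup
  genotyping with an allele-frequency cutoff (AF ≥ 0.1, diploid), and
  barcode-linked phasing;
* the **evaluation suite**: collision-free fractions and linked-read
  efficiency, on-target recovery and coverage, allele burden,
  switch/flip error decomposition, phase-block accounting, de novo site
  confirmation across replicates, quality groups 1–4 and the
  coverage-titration experiment (50% … 0.78% subsampling ladder).

## The core computation

Per-barcode allele observations over heterozygous sites form a fragment
matrix *M* with rows *R* (barcodes) and entries in {0, 1}. Phasing seeks a
haplotype assignment *h* minimising the **minimum error correction**
objective

```
MEC(h) = sum over rows r of min( d(r, h), d(r, complement(h)) )
```

where *d* counts mismatches at the sites the row covers. Sites are linked
into **phase blocks** only where the log-odds of co-phasing,
`(agree − disagree) · log((1−e)/e)` with symmetric observation error
`e = 0.02`, reaches a prune threshold requiring at least two independent
consistent barcodes; pairs farther apart than 40 kb contribute no direct
link. Blocks of ≤ 10 sites are solved exhaustively (guaranteed optimum),
larger blocks by maximum-spanning-tree construction plus single-site
flips. Accuracy against a benchmark decomposes disagreements into **flip**
errors (one site inverted) and **switch** errors (all downstream sites
inverted), minimised over each block's orientation.

## A worked example

Simulate a 13 kb amplicon carrying seven heterozygous sites spaced
288, 4299, 23, 69, 5560 and 2505 bp apart, at ~185× coverage, and phase it:

```r
library(linkphase)

cfg <- pipeline_config(
  seed = 7,
  loci = list(list(length_bp = 13000L,
                   het_positions = cumsum(c(100L, 288L, 4299L, 23L,
                                            69L, 5560L, 2505L)),
                   locus_id = "amp13k")),
  target_mass_pg = molecules_to_mass(200, 13000),  # 200 molecules
  n_beads = 20000L, reads_per_kb = 3.2)

sim <- simulate_experiment(cfg)
res <- run_pipeline_reads(sim$reads, sim$refs, sim$targets, cfg)
res$phase
#> <phase_result> 7/7 sites phased in 1 block(s); MEC = 0

res$phased_vcf
#>     chrom   pos    ref    alt     gt    ps phased
#>  1: amp13k   101      A      T    0|1   101   TRUE
#>  2: amp13k   389      A      G    1|0   101   TRUE
#>  3: amp13k  4688      T      A    1|0   101   TRUE
#>  ...

compare_phasing(sim$truth_vcf, res$phased_vcf, target = "amp13k")
#> <eval_report> amp13k: 7/7 recalled, 7 phased (7 correct, 100.00% of
#> annotated), 0 flip(s), 0 switch(es), 1 block(s)
```

All seven sites are recalled and phased into a single block with zero
flip/switch errors (quality group 1); on-target recovery is 100% at a mean
coverage of 187×. Lower `reads_per_kb`, raise `dropout_fraction`, or raise
λ (molecules per bead) to watch recall, allele burden and block continuity
degrade; `coverage_titration()` automates the depth scan.

File-based workflows mirror the in-memory one: `run_simulation()` writes a
FASTQ trio (R1/R2/I1), reference FASTA, target BED, truth phased VCF and a
bead-truth table; `run_pipeline()` consumes them and writes a phased VCF
(GT with `|`, `PS` phase sets) and a SAM-like alignment table with `BX`
barcode tags.

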
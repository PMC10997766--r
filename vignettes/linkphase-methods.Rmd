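---
title: "Simulating and phasing targeted linked-read experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and phasing targeted linked-read experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linkphase)
```

## The problem

Short-read sequencing loses the association between alleles on the same
chromosome copy. Microbead co-barcoding recovers it: long DNA molecules are
captured on barcoded beads, amplified, and sequenced as short paired reads
that all carry their bead's barcode. Reads sharing a barcode then derive —
barring *collisions* — from one molecule, hence one haplotype, and the
per-barcode allele observations over heterozygous sites can be assembled
into phased haplotypes.

For *targeted* applications (one locus or a small panel, enriched by
Cas9-based capture, exonuclease protection, or PCR), the sample has very low
fragment diversity, so two molecules landing on the same bead are likely to
be the maternal and paternal copy of the *same* locus, which directly
corrupts the phasing signal. The experimental levers are the target input
mass (which sets the mean bead load) and non-target "filling" DNA (an
equimolar restriction digest of the 48.5 kb lambda phage genome added to
stabilise yields and dilute same-locus collisions). `linkphase` provides a
generator for such experiments with known truth, the processing chain from
raw barcoded reads to phased variants, and the evaluation machinery to
quantify the result.

## The generator

`simulate_experiment()` composes five stages, all driven by one seed:

* **Loci.** `make_diploid_locus()` draws a random reference segment and
  places biallelic heterozygous SNVs by a renewal process with geometric
  inter-site gaps (mean spacing 1.5 kb by default — the typical human
  regime of one heterozygous site every 1–2 kb). Positions can instead be
  pinned exactly (we use the 13 kb / 7-site configuration with spacings
  288, 4299, 23, 69, 5560 and 2505 bp as a standard benchmark of both
  tightly clustered and multi-kb-separated sites). One allele always equals
  the reference base; which haplotype carries it is randomised per site.
* **Masses to molecules.** Experiments are specified in picograms.
  `mass_to_molecules()` converts with 650 g/mol per base pair: 20 pg of an
  8.5 kb target is ~2.2 million molecules. The constant is a convention;
  nothing downstream depends on its exact value, only on relative
  molarities.
* **Composition.** `sample_composition()` mixes per-locus target mass
  (split between haplotypes by `hap_bias`, thinned by `dropout_fraction` to
  model enrichment dropout such as an inversion breaking one haplotype's
  capture, possibly mosaic), off-target background drawn from a separate
  random genome absent from the mapping reference, and filling DNA. The
  digest is *equimolar*: every genome equivalent contributes one copy of
  each of the fourteen fragments (117–8453 bp), so per-fragment counts are
  identical and mass share is proportional to length.
* **Bead loading.** `assign_beads()` places each molecule on a bead
  uniformly at random, making molecules-per-bead Poisson with mean
  `lambda = molecules / beads`. This is the minimal exchangeable model of
  collisions; the real assay's effective load is not derivable from
  published bead counts, so `lambda` is exposed directly. Only a
  configurable subsample of beads emits reads (the assay indexes ~1/40th
  of the bead solution).
* **Reads.** `generate_reads()` emits 2×145 bp pairs (Poisson per molecule
  at `reads_per_kb`), i.i.d. substitution errors, single-base barcode
  errors (matching the reach of the downstream corrector; barcode indels
  are out of scope), and PCR duplicates as *exact* re-emissions so that
  within-barcode deduplication is exactly testable. Base qualities are
  constant because no downstream step uses them. Molecules shorter than one
  insert (290 bp) yield no reads — notably the 117 and 224 bp digest
  fragments at default settings.

What the generator does *not* emulate: indels (SNV-only throughout),
sequencing quality profiles, GC/end bias in coverage, chimeric PCR
crossovers, and barcode whitelists. Passing tests therefore demonstrate the
correctness of the processing chain and estimators under the stated model,
not performance on real libraries.

## The processing chain

`run_pipeline_reads()` (or `run_pipeline()` from a FASTQ trio + FASTA +
BED) applies, in order:

1. **Adapter trimming** (`trim_adapters()`): exact-match 3' trimming with a
   minimum suffix/prefix overlap of 5 nt; three R1 adapters and one R2
   adapter by default.
2. **Barcode correction** (`correct_barcodes()`): a barcode seen on a
   single read pair that is Hamming distance 1 from exactly one multi-read
   (count ≥ 2) barcode is assumed to carry a sequencing error and merged
   into it. Ambiguous singletons are left alone — a conservative tie-break
   that avoids false merges at the cost of a few uncorrected reads.
3. **Mapping** (`map_reads()`): exact k-mer seed voting (k = 21, 5 seeds
   per mate, both strands) with substitution-only extension. Tied best
   placements are left unmapped. This is sufficient because the generator
   emits no indels and targets are small; real-data users can import
   external alignments through the SAM-like text layer.
4. **Duplicate marking** (`mark_duplicates()`): within each barcode only,
   pairs sharing (reference, R1 start, R2 start, orientation) beyond the
   first (stable sort by read id) are flagged. Identical coordinates under
   different barcodes are different molecules and are kept.
5. **Genotyping** (`pileup_counts()` + `call_genotypes()`): per-position
   nucleotide counts excluding duplicates; a site is heterozygous iff its
   two top bases each reach allele fraction ≥ 0.1 at depth ≥ `min_depth`.
   The depth default (10) is the smallest at which a 0.1 cutoff is
   meaningful; sites below it go uncalled and surface as failed genotyping.
   This rule makes haplotype dropout visible mechanically: at 90% dropout
   the minor allele sits near 5% < 0.1 and the site is recalled homozygous.
6. **Phasing** (`build_fragment_matrix()` + `phase_blocks()`): per-barcode
   majority alleles over het sites form the fragment matrix (ties dropped);
   site pairs within 40 kb are scored with a log-odds weight
   `(agree - disagree) * log((1 - e)/e)` under a symmetric observation
   error rate `e = 0.02`. Blocks are connected components of edges with
   `|weight| >=` the prune threshold (default 5, chosen so one supporting
   barcode — weight ~3.9 — can never phase a pair, but two can: thin
   linkage stays unphased rather than guessing). Within a block the
   haplotype assignment minimises MEC, exhaustively for blocks of ≤ 10
   sites (guaranteed optimum) and by maximum-spanning-tree construction
   plus single-site flips otherwise; a site whose flip costs less than one
   observation is reported unphased. Each block is canonically oriented
   (leftmost phased site carries allele 0 on haplotype 1), making output
   invariant under global relabeling. MEC is accounted per block because
   relative phase across blocks is undefined.

## Evaluation

`compare_phasing()` scores an inferred phasing against a benchmark:
recall of annotated het sites (matching positions *and* allele pairs),
missed and unphased counts, and a switch/flip decomposition per inferred
block, minimised over each block's orientation. Isolated single-site
disagreement runs are flips; longer runs cost one switch per interior run
boundary — `switch_flip_decompose()` equals the brute-force minimum over
all edit sequences, which the test suite verifies by enumeration for up to
8 sites. For accuracy tallies a flip makes one site incorrect and a switch
makes all downstream sites of its block incorrect; both "of annotated" and
"of recalled" percentages are reported because each denominator answers a
different question (absolute yield vs conditional accuracy), and unphased
recalled sites count against both. De novo phased sites (phased here,
unphased or absent in the benchmark) are confirmed when at least two
replicate libraries agree on their phase, generalising the observation that
erroneous phasing is non-reproducible.

`classify_quality_group()` maps a report onto four groups: (1) error-free
single block; (2) single block with exactly one flip or switch;
(3) missed genotypes, discontinuous blocks, or multiple errors;
(4) mostly unphased. "Mostly" is quantified as > 50% of annotated sites
unphased — the qualitative description gives no number, and 0.5 separates
the regimes cleanly. `coverage_titration()` re-runs duplicate marking,
genotyping and phasing down the subsampling ladder (50% … 0.78%), scoring
each cell; mapping is done once because Bernoulli pair subsampling commutes
with it.

Collision metrics work on what a barcode-based estimator can actually see:
a barcode is associated with a fragment when ≥ 2 of its read pairs map
there (one read is weak evidence; the counting rule is ours), it is
collision-free when associated with exactly one fragment, and two molecules
of the *same* fragment on one bead are invisible by construction.
Linked-read efficiency is, among barcodes not spanning multiple fragments,
the share of read pairs whose barcode has ≥ 2 pairs on one fragment. Under
deep uniform simulated coverage this approaches 100% — the real assay's
much lower efficiencies reflect capture and amplification losses the
generator deliberately does not model.

## Numerical choices and degenerate inputs

* Fragment-interval membership uses the pair midpoint (no edge
  double-counting; boundary handling is otherwise arbitrary).
* Genotype calls order the reference allele first; VCF output is 1-based
  with `GT` phased as `h1|h2` and `PS` equal to the block's leftmost
  phased position. BED intervals are 0-based half-open.
* Ties: tied mapper placements are unmapped; tied per-barcode allele votes
  are dropped; greedy tree edges break ties deterministically by weight,
  then site order.
* Degenerate inputs: zero-mass components produce no molecules; empty
  matrices (no het calls) phase nothing; single-site rows contribute to
  burden but never to linkage; a locus with all pairwise gaps above the
  link distance yields only unphased sites.

## Problem sizes

The shipped tests and the acceptance script run entirely on simulations
sized for a laptop: collision grids with 500–1300 barcodes and up to a few
thousand molecules, phasing benchmarks of a 13 kb locus at ~185× over 10–20
seeds, and titrations of ~18 k read pairs per seed across the seven-step
ladder. These sizes give binomial standard errors of 1–3 percentage points
on the reported fractions, which is adequate to demonstrate estimator
consistency and the monotone coverage–quality relationship.

## A worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(
  seed = 7,
  loci = list(list(length_bp = 13000L,
                   het_positions = cumsum(c(100L, 288L, 4299L, 23L,
                                            69L, 5560L, 2505L)),
                   locus_id = "amp13k")),
  target_mass_pg = molecules_to_mass(200, 13000),
  n_beads = 20000L, reads_per_kb = 3.2)
sim <- simulate_experiment(cfg)
res <- run_pipeline_reads(sim$reads, sim$refs, sim$targets, cfg)
compare_phasing(sim$truth_vcf, res$phased_vcf, target = "amp13k")
```

## Known limitations

The mapper is substitution-only and unsuitable for indel-bearing or
repetitive references; the phaser's error model is a single symmetric rate;
collisions are mitigated only experimentally (input mass, filling DNA), not
detected algorithmically at phasing time — a maternal + paternal collision
simply contributes conflicting matrix rows, exactly as in the real assay;
and structural variation is modelled only as haplotype dropout, not as
rearranged sequence.
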
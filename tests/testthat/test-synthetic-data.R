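# Synthetic-data generator: loci, mass conversion, pools, bead loading,
# reads, truth-set round trip.

test_that("filling fragment table is the complete 48.5 kb digest", {
  fs <- bstp1_fragments()
  expect_equal(nrow(fs), 14L)
  expect_equal(sum(fs$length_bp), 48502L)
  expect_false(anyDuplicated(fs$fragment_id) > 0)
})

test_that("diploid loci respect the renewal spacing and invariants", {
  loc <- make_diploid_locus(200000, 1500, seed = 7)
  n <- nrow(loc$het_sites)
  lambda <- 200000 / 1500
  expect_gt(n, lambda - 3 * sqrt(lambda))
  expect_lt(n, lambda + 3 * sqrt(lambda))
  expect_true(all(diff(loc$het_sites$pos) > 0))
  expect_true(all(loc$het_sites$allele_hap1 != loc$het_sites$allele_hap2))
  # one allele equals the reference base at every site
  rb <- substring(loc$ref_seq, loc$het_sites$pos + 1, loc$het_sites$pos + 1)
  expect_true(all(rb == loc$het_sites$allele_hap1 |
                    rb == loc$het_sites$allele_hap2))

  # low-heterozygosity regime: spacing as long as the locus leaves ~1 site
  loc2 <- make_diploid_locus(13000, 13000, seed = 3)
  expect_lt(nrow(loc2$het_sites), 6)

  expect_identical(make_diploid_locus(5000, 900, seed = 11),
                   make_diploid_locus(5000, 900, seed = 11))
  expect_error(make_diploid_locus(50, 1000), "length_bp")
  expect_error(make_diploid_locus(5000, 0), "spacing")
})

test_that("mass to molecule conversion follows 650 g/mol/bp", {
  expect_equal(mass_to_molecules(0, 1000), 0)
  # frozen from N = mass*1e-12*6.022e23/(len*650)
  expect_equal(mass_to_molecules(20, 8453), 2192030)
  expect_equal(mass_to_molecules(100, 48502), 1910151)
  expect_error(mass_to_molecules(-1, 100), "mass")
  # inverse round-trips
  expect_equal(mass_to_molecules(molecules_to_mass(500, 13000), 13000), 500)
})

test_that("fragment pools split haplotypes, thin by dropout, and keep the digest equimolar", {
  loc <- make_diploid_locus(10000, 1000, seed = 2)
  n_target <- 4000
  comp <- sample_composition(target_mass_pg = molecules_to_mass(n_target, 10000))
  pool <- build_fragment_pool(loc, comp, seed = 5)
  tab <- table(pool$source)
  expect_equal(sum(tab), n_target)
  # binomial 4 sigma around an even split
  expect_lt(abs(tab[["target_hap1"]] - n_target / 2), 4 * sqrt(n_target * 0.25))

  comp_do <- sample_composition(target_mass_pg = molecules_to_mass(n_target, 10000),
                                dropout_fraction = 0.9, dropout_hap = 2L)
  pool_do <- build_fragment_pool(loc, comp_do, seed = 5)
  tab_do <- table(pool_do$source)
  ratio <- tab_do[["target_hap2"]] / tab_do[["target_hap1"]]
  expect_lt(ratio, 0.2)
  expect_gt(ratio, 0.04)

  # equimolar digest: identical count for every fragment length
  compf <- sample_composition(target_mass_pg = 0,
                              filling_mass_pg = molecules_to_mass(25, 48502))
  poolf <- build_fragment_pool(list(), compf, seed = 9)
  cnt <- table(poolf$locus_id)
  expect_equal(length(cnt), 14L)
  expect_true(all(cnt == cnt[[1]]))

  # molecule sequences match their source intervals
  sq <- molecule_seq(pool, pool$molecule_id[1:3])
  expect_equal(unname(nchar(sq)), rep(10000L, 3))
})

test_that("bead loading is Poisson and conserves molecules", {
  loc <- make_diploid_locus(2000, 500, seed = 4)
  for (lambda in c(0.05, 0.5, 5)) {
    n_beads <- 100000L
    n_mol <- as.integer(lambda * n_beads)
    comp <- sample_composition(target_mass_pg = molecules_to_mass(n_mol, 2000))
    pool <- build_fragment_pool(loc, comp, seed = 21)
    asn <- assign_beads(pool, n_beads, seed = 22)
    # every molecule on exactly one bead
    expect_equal(sort(asn$assignment$molecule_id), pool$molecule_id)
    occ <- bead_occupancy(asn)
    # chi-square against Poisson(lambda) at alpha = 0.01, tail binned
    kmax <- max(occ$n_molecules)
    probs <- dpois(0:kmax, nrow(pool) / n_beads)
    probs[kmax + 1] <- probs[kmax + 1] + ppois(kmax, lambda, lower.tail = FALSE)
    obs <- integer(kmax + 1)
    obs[occ$n_molecules + 1] <- occ$n_beads
    keep <- probs * n_beads >= 5
    o <- obs[keep]; pr <- probs[keep]
    if (any(!keep)) { o <- c(o, sum(obs[!keep])); pr <- c(pr, sum(probs[!keep])) }
    p <- suppressWarnings(chisq.test(o, p = pr, rescale.p = TRUE))$p.value
    expect_gt(p, 0.01)
  }
  expect_error(assign_beads(pool, 10, bead_subsample_fraction = 0), "fraction")
})

test_that("low bead load leaves most barcoding events collision-free", {
  # P(>=2 | >=1) for Poisson(0.1) is ~0.049
  p2 <- 1 - dpois(0, 0.1) - dpois(1, 0.1)
  expect_equal(p2 / (1 - dpois(0, 0.1)), 0.0492, tolerance = 0.01)
  loc <- make_diploid_locus(2000, 500, seed = 4)
  comp <- sample_composition(target_mass_pg = molecules_to_mass(5000, 2000))
  pool <- build_fragment_pool(loc, comp, seed = 31)
  asn <- assign_beads(pool, 50000L, seed = 32)
  occ <- bead_occupancy(asn, include_empty = FALSE)
  frac_multi <- sum(occ[occ$n_molecules >= 2, n_beads]) / sum(occ$n_beads)
  expect_equal(frac_multi, 0.0492, tolerance = 0.35)
})

test_that("read generation honours geometry, noise and duplicate contracts", {
  s <- small_sim(seed = 42, n_molecules = 60, length_bp = 4000,
                 reads_per_kb = 6)
  rd <- s$sim$reads
  expect_true(all(nchar(rd$r1_seq) == 145))
  expect_true(all(nchar(rd$r2_seq) == 145))
  expect_true(all(nchar(rd$observed_barcode) == 18))
  # noiseless reads match their source haplotype sequence exactly
  seqs <- attr(s$sim$pool, "seqs")
  i <- sample(nrow(rd), 50)
  r1_expect <- substring(seqs[rd$seq_name[i]], rd$r1_pos[i] + 1,
                         rd$r1_pos[i] + 145)
  expect_equal(unname(r1_expect), rd$r1_seq[i])
  r2_expect <- substring(seqs[rd$seq_name[i]], rd$r2_pos[i] + 1,
                         rd$r2_pos[i] + 145)
  expect_equal(unname(vapply(r2_expect, function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x))),
    character(1))), rd$r2_seq[i])

  # barcode error rate ~1% single-base substitutions
  cfg2 <- s$config
  set.seed(99)
  rd2 <- generate_reads(s$sim$assignment, s$sim$pool, reads_per_kb = 50,
                        barcode_error_rate = 0.01)
  err <- rd2$observed_barcode != rd2$true_barcode
  expect_gt(nrow(rd2), 1e4)
  expect_equal(mean(err), 0.01, tolerance = 0.35)
  hd <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
               rd2$observed_barcode[err][1:20], rd2$true_barcode[err][1:20])
  expect_true(all(hd == 1))

  # PCR duplicates are exact re-emissions
  set.seed(7)
  rd3 <- generate_reads(s$sim$assignment, s$sim$pool, reads_per_kb = 5,
                        pcr_dup_rate = 0.3)
  d <- rd3[rd3$is_pcr_duplicate == TRUE, ]
  expect_gt(nrow(d), 0)
  orig <- rd3[rd3$is_pcr_duplicate == FALSE, ]
  key <- function(x) paste(x$molecule_id, x$r1_pos, x$r2_pos, x$true_barcode)
  expect_true(all(key(d) %in% key(orig)))

  # short molecules are skipped with a warning, not an error
  locS <- make_diploid_locus(2000, 500, seed = 1)
  compS <- sample_composition(target_mass_pg = 0,
                              filling_mass_pg = molecules_to_mass(3, 48502))
  poolS <- build_fragment_pool(list(), compS, seed = 2)
  asnS <- assign_beads(poolS, 1000, seed = 3)
  expect_warning(generate_reads(asnS, poolS, reads_per_kb = 2, seed = 4),
                 "shorter than")
})

test_that("the full generator is reproducible under a fixed seed", {
  a <- small_sim(seed = 123)$sim
  b <- small_sim(seed = 123)$sim
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth_vcf, b$truth_vcf)
  expect_identical(attr(a$pool, "seqs"), attr(b$pool, "seqs"))
})

test_that("truth sets round-trip through disk", {
  s <- small_sim(seed = 8, n_molecules = 40, length_bp = 3000,
                 reads_per_kb = 3)
  dir <- withr::local_tempdir()
  paths <- write_truth_set(s$sim$loci, s$sim$pool, s$sim$assignment,
                           s$sim$reads, dir)
  ts <- read_truth_set(dir)
  # reference and het sites reconstruct identically
  expect_equal(unname(ts$refs["loc1"]), s$sim$loci[[1]]$ref_seq)
  expect_equal(ts$truth_vcf$pos, s$sim$loci[[1]]$het_sites$pos + 1L)
  expect_equal(nrow(ts$truth_vcf), nrow(s$sim$loci[[1]]$het_sites))
  expect_true(all(ts$truth_vcf$phased))
  # FASTQ trio: same ids, 18-base I1 records
  expect_identical(ts$reads$read_id, s$sim$reads$read_id)
  expect_identical(ts$reads$r1_seq, s$sim$reads$r1_seq)
  expect_true(all(nchar(ts$reads$observed_barcode) == 18))
  expect_identical(ts$reads$observed_barcode, s$sim$reads$observed_barcode)
  expect_equal(ts$targets$end, 3000L)
})
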
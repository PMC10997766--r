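# Fragment matrix construction and MEC phasing.

# build a fragment_matrix directly from a row specification
mk_matrix <- function(rows, positions, ref = "loc",
                      params = phasing_params()) {
  sites <- data.table::data.table(
    site = seq_along(positions), ref = ref, pos = positions,
    a1 = "A", a2 = "G")
  rdt <- data.table::rbindlist(lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.table::data.table(barcode = sprintf("B%03d", i),
                           site = r$sites, allele = r$alleles,
                           n_reads = 1L)
  }))
  structure(list(sites = sites, rows = rdt, params = params),
            class = "fragment_matrix")
}

consistent_rows <- function(truth, n_per_pair) {
  rows <- list()
  for (i in seq_len(length(truth) - 1)) {
    for (k in seq_len(n_per_pair)) {
      hap <- (k %% 2)  # alternate haplotypes
      al <- if (hap == 0) truth[i:(i + 1)] else 1L - truth[i:(i + 1)]
      rows[[length(rows) + 1]] <- list(sites = c(i, i + 1L), alleles = al)
    }
  }
  rows
}

test_that("fragment matrix records majority alleles per barcode", {
  refs <- c(loc = strrep("ACGT", 300))
  al <- data.table::data.table(
    read_id = sprintf("r%d", 1:5), mate = 1L, ref = "loc",
    pos = c(0L, 0L, 0L, 0L, 500L), cigar = "21M", strand = "+",
    barcode = c("B1", "B1", "B1", "B2", "B2"),
    mapped = TRUE, dup = FALSE,
    seq = c("AAAAAAAAAAAAAAAAAAAAA",  # allele A at site pos 10
            "AAAAAAAAAAAAAAAAAAAAA",
            "AAAAAAAAAAGAAAAAAAAAA",  # one dissenting G vote
            "AAAAAAAAAAGAAAAAAAAAA",
            "AAAAAAAAAAGAAAAAAAAAA"))  # site pos 510
  data.table::setattr(al, "class",
                      c("aligned_reads", "data.table", "data.frame"))
  calls <- data.table::data.table(
    ref = "loc", pos = c(10L, 510L), ref_base = "C",
    genotype = "het", a1 = c("A", "A"), a2 = c("G", "G"),
    ad1 = 10L, ad2 = 10L, depth = 20L)
  fm <- build_fragment_matrix(al, calls)
  # B1: 2 votes A vs 1 vote G at site 1 -> majority allele 0
  expect_equal(fm$rows[fm$rows$barcode == "B1", ]$allele, 0L)
  # B2 covers site 1 (G) and site 2 (G): alleles 1, 1
  b2 <- fm$rows[fm$rows$barcode == "B2", ]
  expect_equal(b2$site, 1:2)
  expect_equal(b2$allele, c(1L, 1L))
  # single-site rows retained
  expect_true("B1" %in% fm$rows$barcode)
})

test_that("mec_score matches its definition", {
  m <- mk_matrix(list(list(sites = 1:2, alleles = c(0L, 0L)),
                      list(sites = 1:2, alleles = c(1L, 1L)),
                      list(sites = 1:2, alleles = c(0L, 1L))),
                 positions = c(100L, 600L))
  # consistent rows cost 0 under truth; fully opposite row costs 0 too
  expect_equal(mec_score(m, c(0L, 0L)), 1L)  # only the mixed row pays 1
  m2 <- mk_matrix(list(list(sites = 1:2, alleles = c(0L, 0L))),
                  positions = c(100L, 600L))
  expect_equal(mec_score(m2, c(0L, 0L)), 0L)
  expect_equal(mec_score(m2, c(1L, 1L)), 0L)  # row flips haplotype
  expect_equal(mec_score(m2, c(0L, 1L)), 1L)
})

test_that("noiseless linkage phases a single block at MEC 0", {
  truth <- c(0L, 1L, 0L)
  m <- mk_matrix(consistent_rows(truth, 10), positions = c(0L, 1000L, 2000L))
  res <- phase_blocks(m)
  expect_equal(sum(!is.na(res$assignment)), 3L)
  expect_equal(nrow(res$blocks), 1L)
  expect_equal(res$mec, 0L)
  # truth recovered up to global swap; canonical orientation pins site 1 to 0
  expect_true(identical(res$assignment, truth) ||
                identical(res$assignment, 1L - truth))
  expect_equal(res$assignment[1], 0L)

  # one contradictory row: same phasing, MEC 1, equal to brute force
  rows <- c(consistent_rows(truth, 10),
            list(list(sites = 1:2, alleles = c(truth[1], 1L - truth[2]))))
  m2 <- mk_matrix(rows, positions = c(0L, 1000L, 2000L))
  res2 <- phase_blocks(m2)
  expect_equal(res2$assignment, res$assignment)
  expect_equal(res2$mec, 1L)
  expect_equal(res2$mec, brute_force_mec(m2))
})

test_that("sites farther apart than the link distance split into blocks", {
  truth <- c(0L, 0L, 1L, 1L)
  rows <- list()
  for (k in 1:5) {
    rows[[length(rows) + 1]] <- list(sites = 1:2, alleles = truth[1:2])
    rows[[length(rows) + 1]] <- list(sites = 3:4, alleles = truth[3:4])
  }
  m <- mk_matrix(rows, positions = c(0L, 5000L, 60000L, 62000L))
  res <- phase_blocks(m)
  expect_equal(nrow(res$blocks), 2L)
  expect_equal(sum(!is.na(res$assignment)), 4L)
  expect_equal(sort(res$blocks$block_id), c(1L, 60001L))

  # only single-site rows: nothing to phase
  m2 <- mk_matrix(list(list(sites = 1L, alleles = 0L),
                       list(sites = 2L, alleles = 1L)),
                  positions = c(0L, 1000L))
  res2 <- phase_blocks(m2)
  expect_true(all(is.na(res2$assignment)))
  expect_equal(nrow(res2$blocks), 0L)
})

test_that("a single supporting barcode cannot phase a pair", {
  m <- mk_matrix(list(list(sites = 1:2, alleles = c(0L, 0L))),
                 positions = c(0L, 1000L))
  res <- phase_blocks(m)
  expect_true(all(is.na(res$assignment)))
  # two consistent rows pass the prune threshold
  m2 <- mk_matrix(list(list(sites = 1:2, alleles = c(0L, 0L)),
                       list(sites = 1:2, alleles = c(1L, 1L))),
                  positions = c(0L, 1000L))
  res2 <- phase_blocks(m2)
  expect_equal(sum(!is.na(res2$assignment)), 2L)
})

test_that("phasing output is invariant under global haplotype relabeling", {
  set.seed(41)
  truth <- c(0L, 1L, 1L, 0L, 1L)
  rows <- consistent_rows(truth, 6)
  m <- mk_matrix(rows, positions = c(0L, 800L, 1600L, 2400L, 3200L))
  res <- phase_blocks(m)
  # relabel: complement every allele in every row
  rows_flip <- lapply(rows, function(r)
    list(sites = r$sites, alleles = 1L - r$alleles))
  m_flip <- mk_matrix(rows_flip, positions = c(0L, 800L, 1600L, 2400L, 3200L))
  res_flip <- phase_blocks(m_flip)
  expect_identical(res$assignment, res_flip$assignment)
  expect_identical(res$block_id, res_flip$block_id)
})

test_that("MEC optimiser equals the exhaustive optimum on random matrices", {
  set.seed(13)
  for (trial in 1:20) {
    n_sites <- sample(3:8, 1)
    truth <- sample(0:1, n_sites, replace = TRUE)
    rows <- list()
    for (r in 1:12) {
      span <- sort(sample(n_sites, sample(2:min(3, n_sites), 1)))
      al <- truth[span]
      if (runif(1) < 0.5) al <- 1L - al
      flip <- runif(length(al)) < 0.1  # 10% observation noise
      al[flip] <- 1L - al[flip]
      rows[[r]] <- list(sites = span, alleles = al)
    }
    m <- mk_matrix(rows, positions = as.integer(seq(0, by = 900,
                                                    length.out = n_sites)))
    res <- phase_blocks(m)
    # every block's assignment is exhaustively optimal over its phased sites
    for (b in unique(res$block_id[!is.na(res$block_id)])) {
      mask <- res$assignment
      mask[is.na(res$block_id) | res$block_id != b] <- NA_integer_
      expect_equal(mec_score(m, mask),
                   brute_force_mec(m, which(!is.na(mask))))
    }
  }
})

test_that("phased variants emit ordered genotypes with phase sets and round-trip", {
  s <- small_sim(seed = 55, n_molecules = 120, length_bp = 6000,
                 mean_spacing = 900, reads_per_kb = 5)
  res <- run_pipeline_reads(s$sim$reads, s$sim$refs, s$sim$targets,
                            s$config, adapters = NULL)
  v <- res$phased_vcf
  expect_true(all(v$phased[!is.na(v$ps)]))
  expect_equal(length(unique(v$ps[!is.na(v$ps)])), nrow(res$phase$blocks))
  # write + read back preserves records
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(v, f)
  rt <- read_vcf(f)
  expect_equal(rt$pos, v$pos)
  expect_equal(rt$gt, v$gt)
  expect_equal(rt$ps, v$ps)
  expect_equal(rt$phased, v$phased)
})
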
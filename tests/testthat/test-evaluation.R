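# Switch/flip decomposition, benchmark comparison, quality groups,
# subsampling.

test_that("switch/flip decomposition handles the canonical cases", {
  expect_equal(switch_flip_decompose(c(0, 1, 0, 1), c(0, 1, 0, 1)),
               c(switches = 0L, flips = 0L))
  # one interior site inverted among >= 3: one flip
  expect_equal(switch_flip_decompose(c(0, 0, 0, 0), c(0, 1, 0, 0)),
               c(switches = 0L, flips = 1L))
  # all sites from position k inverted: one switch
  expect_equal(switch_flip_decompose(c(0, 0, 0, 0), c(0, 0, 1, 1)),
               c(switches = 1L, flips = 0L))
  # global inversion is free (orientation choice)
  expect_equal(switch_flip_decompose(c(0, 1, 0, 1), c(1, 0, 1, 0)),
               c(switches = 0L, flips = 0L))
  expect_error(switch_flip_decompose(c(0, 1), c(0, 1, 0)), "length")
})

test_that("switch/flip decomposition equals the enumeration oracle", {
  set.seed(29)
  for (trial in 1:200) {
    n <- sample(1:8, 1)
    truth <- sample(0:1, n, replace = TRUE)
    called <- sample(0:1, n, replace = TRUE)
    sf <- switch_flip_decompose(truth, called)
    expect_equal(sf[["switches"]] + sf[["flips"]],
                 brute_force_switch_flip(truth, called),
                 info = paste("truth:", paste(truth, collapse = ""),
                              "called:", paste(called, collapse = "")))
  }
})

test_that("eval reports enforce count identities and accuracy arithmetic", {
  r <- eval_report(target = "T2", annotated = 33, recalled = 30, phased = 29,
                   flips = 0, switches = 0, incorrect_sites = 0)
  expect_equal(r$missed, 3L)
  expect_equal(r$unphased, 1L)
  expect_equal(r$correct, 29L)
  expect_equal(round(r$accuracy_recalled_pct, 1), 96.7)
  expect_error(eval_report(annotated = 5, recalled = 6, phased = 2),
               "recalled")
  expect_error(eval_report(annotated = 5, recalled = 4, phased = 5),
               "phased")
})

test_that("compare_phasing scores recall, flips and blocks against truth", {
  truth <- data.table::data.table(
    chrom = "t", pos = c(10L, 20L, 30L, 40L, 50L), ref = "A", alt = "G",
    gt = c("0|1", "1|0", "0|1", "0|1", "1|0"), ps = 10L, phased = TRUE)
  # perfect inference (modulo global swap)
  inf <- data.table::copy(truth)
  inf$gt <- c("1|0", "0|1", "1|0", "1|0", "0|1")
  r <- compare_phasing(truth, inf)
  expect_equal(r$recalled, 5L)
  expect_equal(r$phased, 5L)
  expect_equal(r$flips + r$switches, 0L)
  expect_equal(r$accuracy_annotated_pct, 100)
  expect_true(r$single_block)

  # one flip, one unphased, one missed
  inf2 <- truth[1:4]
  inf2$gt <- c("0|1", "0|1", "0|1", "0/1")  # site 2 flipped, site 4 unphased
  r2 <- compare_phasing(truth, inf2)
  expect_equal(r2$missed, 1L)
  expect_equal(r2$unphased, 1L)
  expect_equal(r2$flips, 1L)
  expect_equal(r2$switches, 0L)
  expect_equal(r2$correct, 2L)

  # invariance to global swap of either input
  truth_sw <- data.table::copy(truth)
  truth_sw$gt <- c("1|0", "0|1", "1|0", "1|0", "0|1")
  expect_equal(compare_phasing(truth_sw, inf)$correct, r$correct)

  # disjoint site sets: recall 0, no error
  inf3 <- data.table::copy(truth)
  inf3$pos <- inf3$pos + 1000L
  r3 <- compare_phasing(truth, inf3)
  expect_equal(r3$recalled, 0L)
})

test_that("worked phasing-accuracy arithmetic reproduces known regimes", {
  # 16 recalled, 9 phased consistently: 56% of recalled
  r_low <- eval_report(target = "low-het", annotated = 16, recalled = 16,
                       phased = 9, incorrect_sites = 0)
  expect_equal(round(r_low$accuracy_recalled_pct), 56)
  # 9 recalled, 2 unphased: 7/9 = 77.8%
  r_t1 <- eval_report(target = "T1", annotated = 9, recalled = 9, phased = 7,
                      incorrect_sites = 0)
  expect_equal(round(r_t1$accuracy_recalled_pct, 1), 77.8)
})

test_that("de novo sites are counted and confirmed by replicates", {
  truth <- data.table::data.table(
    chrom = "t", pos = c(10L, 20L, 30L), ref = "A", alt = "G",
    gt = c("0|1", "1|0", "0/1"), ps = c(10L, 10L, NA), phased = c(TRUE, TRUE, FALSE))
  inf <- data.table::data.table(
    chrom = "t", pos = c(10L, 20L, 30L, 99L), ref = "A", alt = "G",
    gt = c("0|1", "1|0", "0|1", "1|0"), ps = 10L, phased = TRUE)
  r <- compare_phasing(truth, inf)
  expect_equal(r$de_novo, 2L)  # site 30 (benchmark-unphased) + site 99 (absent)
  expect_true(is.na(r$de_novo_confirmed))
  # two concordant replicates confirm; discordant ones do not
  rep1 <- data.table::copy(inf)
  rep2 <- data.table::copy(inf)
  rep2$gt <- c("0|1", "1|0", "0|1", "0|1")  # site 99 discordant
  rc <- compare_phasing(truth, inf, replicate_set = list(rep1, rep2))
  expect_equal(rc$de_novo_confirmed, 1L)
})

test_that("aggregation pools counts before recomputing accuracy", {
  counts <- list(c(308, 308, 0), c(71, 71, 0), c(110, 110, 0),
                 c(195, 195, 0), c(125, 125, 1))
  reports <- lapply(seq_along(counts), function(i)
    eval_report(target = paste0("L", i), annotated = counts[[i]][1],
                recalled = counts[[i]][2], phased = counts[[i]][2],
                flips = counts[[i]][3]))
  agg <- aggregate_eval_reports(reports)
  expect_equal(agg$annotated, 809L)
  expect_equal(agg$correct, 808L)
  expect_equal(round(agg$accuracy_annotated_pct, 2), 99.88)
})

test_that("quality groups follow the error taxonomy", {
  mk <- function(...) eval_report(target = "q", ...)
  g1 <- classify_quality_group(mk(annotated = 10, recalled = 10, phased = 10))
  expect_equal(g1$group, 1L)
  g2 <- classify_quality_group(mk(annotated = 10, recalled = 10, phased = 10,
                                  flips = 1))
  expect_equal(g2$group, 2L)
  # missed genotyping, or discontinuous blocks, or >1 error: group 3
  g3a <- classify_quality_group(mk(annotated = 10, recalled = 8, phased = 8))
  expect_equal(g3a$group, 3L)
  g3b <- classify_quality_group(mk(annotated = 10, recalled = 10, phased = 10,
                                   n_blocks = 2))
  expect_equal(g3b$group, 3L)
  g3c <- classify_quality_group(mk(annotated = 10, recalled = 10, phased = 10,
                                   flips = 1, switches = 1))
  expect_equal(g3c$group, 3L)
  # mostly unphased: group 4
  g4 <- classify_quality_group(mk(annotated = 10, recalled = 10, phased = 4))
  expect_equal(g4$group, 4L)
})

test_that("subsampling is Bernoulli per read pair", {
  s <- small_sim(seed = 3, n_molecules = 100, length_bp = 4000,
                 reads_per_kb = 10)
  rd <- s$sim$reads
  expect_identical(subsample_reads(rd, 1), rd)
  n <- nrow(rd)
  sub <- subsample_reads(rd, 0.5, seed = 17)
  expect_lt(abs(nrow(sub) - 0.5 * n), 3 * sqrt(n * 0.25) + 1)
  expect_error(subsample_reads(rd, 0), "fraction")
  expect_error(subsample_reads(rd, 1.2), "fraction")
  # halving expectation along the study ladder
  ladder <- c(0.5, 0.25, 0.125, 0.0625, 0.03125, 0.0156, 0.0078)
  expect_equal(ladder[-1] / ladder[-7], rep(0.5, 6), tolerance = 0.002)
})
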
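# Independent brute-force oracles used to freeze expected values.

# per-base pileup tally straight from aligned reads, one read at a time
brute_force_pileup <- function(aligned) {
  al <- as.data.frame(aligned)
  al <- al[al$mapped & !al$dup, ]
  acc <- list()
  for (r in seq_len(nrow(al))) {
    m <- cigar_to_ref_coords(al$pos[r], al$cigar[r])
    for (k in seq_len(nrow(m))) {
      b <- substring(al$seq[r], m$qidx[k] + 1, m$qidx[k] + 1)
      if (!b %in% c("A", "C", "G", "T")) next
      key <- paste(al$ref[r], m$rpos[k])
      if (is.null(acc[[key]])) acc[[key]] <- c(A = 0, C = 0, G = 0, T = 0)
      acc[[key]][b] <- acc[[key]][b] + 1
    }
  }
  acc
}

# exhaustive MEC optimum over all assignments of the given site subset
# (first subset site pinned to 0; others NA/unphased)
brute_force_mec <- function(matrix, subset = seq_len(nrow(matrix$sites))) {
  n <- nrow(matrix$sites)
  m <- length(subset)
  if (m == 0) return(0L)
  best <- Inf
  for (mask in 0:(2^(m - 1) - 1)) {
    a <- rep(NA_integer_, n)
    a[subset] <- c(0L, as.integer(intToBits(mask)[seq_len(m - 1)]))[seq_len(m)]
    best <- min(best, mec_score(matrix, a))
  }
  best
}

# minimal switches+flips by enumeration over orientation x switch subsets
brute_force_switch_flip <- function(truth, called) {
  n <- length(truth)
  best <- Inf
  for (o in 0:1) {
    v <- (called + o) %% 2
    gaps <- max(n - 1, 0)
    for (mask in 0:(2^gaps - 1)) {
      sw <- as.integer(intToBits(mask)[seq_len(gaps)])
      x <- v
      if (n > 1) {
        parity <- cumsum(c(0L, sw)) %% 2
        x <- (v + parity) %% 2
      }
      cost <- sum(sw) + sum(x != truth)
      best <- min(best, cost)
    }
  }
  best
}

# quick simulated experiment used across tests
small_sim <- function(seed = 1, n_molecules = 120, length_bp = 8000,
                      het_positions = NULL, mean_spacing = 1200,
                      reads_per_kb = 4, n_beads = 10000, ...) {
  spec <- list(length_bp = as.integer(length_bp), locus_id = "loc1")
  if (is.null(het_positions)) spec$mean_het_spacing_bp <- mean_spacing
  else spec$het_positions <- het_positions
  cfg <- pipeline_config(
    seed = seed, loci = list(spec),
    target_mass_pg = molecules_to_mass(n_molecules, length_bp),
    n_beads = as.integer(n_beads), reads_per_kb = reads_per_kb, ...)
  list(config = cfg, sim = simulate_experiment(cfg))
}

amp13k_positions <- cumsum(c(100L, 288L, 4299L, 23L, 69L, 5560L, 2505L))
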
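# Read generation: 2 x 145 bp paired-end reads sampled along each molecule
# on retained beads, tagged with the bead's 18-base barcode. Optional
# substitution errors, single-base barcode errors, and exact PCR duplicate
# re-emissions (same coordinates and barcode, so that within-barcode
# deduplication can be tested exactly).

#' Generate barcoded read pairs from a bead assignment
#'
#' For every molecule on a retained bead, the number of read pairs is Poisson
#' with mean `reads_per_kb * molecule_kb`. Each pair has an insert drawn
#' uniformly in `[2 * read_len, min(molecule length, insert_max)]` placed
#' uniformly along the molecule; R1 is the forward strand of the insert
#' start, R2 the reverse complement of the insert end. Substitution errors
#' are i.i.d. per base; with probability `barcode_error_rate` one random base
#' of the emitted barcode is substituted; with probability `pcr_dup_rate` a
#' pair is re-emitted unchanged and flagged as a PCR duplicate in the truth.
#' Molecules shorter than `2 * read_len` are skipped with a warning.
#'
#' @param assignment a `bead_assignment`.
#' @param pool the `fragment_pool` the assignment was built from.
#' @param reads_per_kb mean read pairs per kb of molecule.
#' @param read_len read length (default 145).
#' @param insert_max maximum insert size (default 500).
#' @param sub_error_rate per-base substitution error rate in `[0, 1)`.
#' @param barcode_error_rate probability of a single-base barcode error.
#' @param pcr_dup_rate probability a pair gains one duplicate copy.
#' @param seed optional integer seed.
#' @return data.table of class `read_pairs`: `read_id`, `r1_seq`, `r2_seq`,
#'   `q1`, `q2`, `observed_barcode`, and truth columns `true_barcode`,
#'   `molecule_id`, `seq_name`, `truth_ref`, `r1_pos`, `r2_pos` (0-based
#'   leftmost reference positions of each mate), `is_pcr_duplicate`.
#' @export
generate_reads <- function(assignment, pool, reads_per_kb, read_len = 145L,
                           insert_max = 500L, sub_error_rate = 0,
                           barcode_error_rate = 0, pcr_dup_rate = 0,
                           seed = NULL) {
  if (read_len < 20) stop_param("read_len must be >= 20")
  rates <- c(sub_error_rate, barcode_error_rate, pcr_dup_rate)
  if (any(rates < 0) || any(rates >= 1)) stop_param("rates must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  seqs <- attr(pool, "seqs")

  mol <- merge(pool, assignment$assignment, by = "molecule_id")
  mol <- merge(mol, assignment$beads[retained == TRUE, .(bead_id, barcode)],
               by = "bead_id")
  mol[, mol_len := end - start]
  n_short <- sum(mol$mol_len < 2L * read_len)
  if (n_short > 0) {
    warning(sprintf("skipping %d molecule(s) shorter than 2*read_len (%d bp)",
                    n_short, 2L * read_len))
    mol <- mol[mol_len >= 2L * read_len]
  }
  empty <- data.table(
    read_id = character(0), r1_seq = character(0), r2_seq = character(0),
    q1 = character(0), q2 = character(0), observed_barcode = character(0),
    true_barcode = character(0), molecule_id = integer(0),
    seq_name = character(0), truth_ref = character(0),
    r1_pos = integer(0), r2_pos = integer(0), is_pcr_duplicate = logical(0))
  setattr(empty, "read_len", as.integer(read_len))
  setattr(empty, "class", c("read_pairs", class(empty)))
  if (nrow(mol) == 0) return(empty)

  mol[, npairs := rpois(.N, reads_per_kb * mol_len / 1000)]
  mol <- mol[npairs > 0]
  if (nrow(mol) == 0) return(empty)

  rd <- mol[rep(seq_len(.N), npairs),
            .(molecule_id, seq_name, locus_id, start, mol_len, barcode)]
  n <- nrow(rd)
  ins_max_i <- pmin(rd$mol_len, as.integer(insert_max))
  insert <- 2L * read_len +
    as.integer(floor(runif(n) * (ins_max_i - 2L * read_len + 1L)))
  s <- as.integer(floor(runif(n) * (rd$mol_len - insert + 1L)))
  gs <- rd$start + s  # 0-based start of insert on source sequence

  # extract sequences per source sequence (vectorised substring)
  r1 <- character(n); r2 <- character(n)
  for (nm in unique(rd$seq_name)) {
    i <- which(rd$seq_name == nm)
    sq <- seqs[[nm]]
    r1[i] <- substring(sq, gs[i] + 1L, gs[i] + read_len)
    r2[i] <- revcomp(substring(sq, gs[i] + insert[i] - read_len + 1L,
                               gs[i] + insert[i]))
  }

  if (sub_error_rate > 0) {
    r1 <- mutate_bases(r1, sub_error_rate)
    r2 <- mutate_bases(r2, sub_error_rate)
  }

  obs_bc <- rd$barcode
  if (barcode_error_rate > 0) {
    hit <- which(runif(n) < barcode_error_rate)
    if (length(hit)) obs_bc[hit] <- mutate_one_base(obs_bc[hit])
  }

  # truth reference: target haplotype sequences share coordinates with the
  # locus reference (SNVs only), so truth ref = locus for targets
  truth_ref <- sub("\\.hap[12]$", "", rd$seq_name)

  out <- data.table(
    r1_seq = r1, r2_seq = r2,
    q1 = strrep("I", read_len), q2 = strrep("I", read_len),
    observed_barcode = obs_bc, true_barcode = rd$barcode,
    molecule_id = rd$molecule_id, seq_name = rd$seq_name,
    truth_ref = truth_ref,
    r1_pos = gs, r2_pos = gs + insert - read_len,
    is_pcr_duplicate = FALSE
  )

  if (pcr_dup_rate > 0) {
    dupd <- out[runif(.N) < pcr_dup_rate]
    if (nrow(dupd)) {
      dupd[, is_pcr_duplicate := TRUE]
      out <- rbind(out, dupd)
    }
  }
  out[, read_id := sprintf("read_%07d", seq_len(.N))]
  setcolorder(out, c("read_id", names(out)[names(out) != "read_id"]))
  setattr(out, "read_len", as.integer(read_len))
  setattr(out, "class", c("read_pairs", class(out)))
  out[]
}

# i.i.d. substitutions at the given per-base rate
mutate_bases <- function(x, rate) {
  if (length(x) == 0 || rate <= 0) return(x)
  w <- nchar(x[1])
  nerr <- rbinom(length(x), w, rate)
  hit <- which(nerr > 0)
  for (i in hit) {
    ch <- strsplit(x[i], "", fixed = TRUE)[[1]]
    p <- sample.int(w, nerr[i])
    ch[p] <- vapply(ch[p], function(b) sample(setdiff(DNA_BASES, b), 1L),
                    character(1), USE.NAMES = FALSE)
    x[i] <- paste(ch, collapse = "")
  }
  x
}

# substitute exactly one random base per string
mutate_one_base <- function(x) {
  w <- nchar(x)
  p <- 1L + as.integer(floor(runif(length(x)) * w))
  old <- substring(x, p, p)
  new <- vapply(old, function(b) sample(setdiff(DNA_BASES, b), 1L),
                character(1), USE.NAMES = FALSE)
  paste0(substring(x, 1L, p - 1L), new, substring(x, p + 1L, w))
}
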
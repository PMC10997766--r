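# Bead loading. Molecules bind barcoded microbeads uniformly at random, so
# the molecules-per-bead distribution is Poisson with mean
# lambda = |pool| / n_beads. Two or more distinct molecules on one bead are
# a "collision": their reads will spuriously share a barcode. Only a
# subsample of beads is indexed for sequencing (e.g. 1/40th of the bead
# solution in the amplicon protocol), controlled by
# `bead_subsample_fraction`.

#' Random bead barcodes
#'
#' @param n number of barcodes.
#' @param len barcode length in bases (default 18).
#' @return character vector of `n` distinct random barcodes.
#' @export
random_barcodes <- function(n, len = 18L) {
  if (n == 0) return(character(0))
  bc <- apply(matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n),
              1, paste, collapse = "")
  # collisions among random 18-mers are vanishingly rare; regenerate if any
  while (anyDuplicated(bc)) {
    d <- which(duplicated(bc))
    bc[d] <- vapply(d, function(i) random_seq(len), character(1))
  }
  bc
}

#' Assign molecules to barcoded beads
#'
#' Each molecule is placed on a bead uniformly at random (Poisson loading).
#' Beads are then subsampled: only retained beads emit reads downstream.
#'
#' @param pool a `fragment_pool`.
#' @param n_beads number of beads in the reaction (>= 1).
#' @param bead_subsample_fraction fraction of beads retained for sequencing,
#'   in (0, 1] (default 1).
#' @param seed optional integer seed.
#' @param barcode_len barcode length (default 18).
#' @return object of class `bead_assignment`: list with
#'   `assignment` (data.table molecule_id -> bead_id), `beads` (data.table
#'   bead_id, barcode, retained; occupied beads only), `n_beads`, `lambda`.
#' @export
assign_beads <- function(pool, n_beads, bead_subsample_fraction = 1,
                         seed = NULL, barcode_len = 18L) {
  if (n_beads < 1) stop_param("n_beads must be >= 1")
  if (bead_subsample_fraction <= 0 || bead_subsample_fraction > 1)
    stop_param("bead_subsample_fraction must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)

  n_mol <- nrow(pool)
  bead_of <- sample.int(n_beads, n_mol, replace = TRUE)
  assignment <- data.table(molecule_id = pool$molecule_id, bead_id = bead_of)
  occupied <- sort(unique(bead_of))
  beads <- data.table(
    bead_id = occupied,
    barcode = random_barcodes(length(occupied), barcode_len),
    retained = runif(length(occupied)) < bead_subsample_fraction
  )
  structure(
    list(assignment = assignment, beads = beads,
         n_beads = as.integer(n_beads), lambda = n_mol / n_beads),
    class = "bead_assignment"
  )
}

#' @export
print.bead_assignment <- function(x, ...) {
  cat(sprintf(
    "<bead_assignment> %d molecules on %d beads (lambda = %.3g), %d occupied, %d retained\n",
    nrow(x$assignment), x$n_beads, x$lambda, nrow(x$beads), sum(x$beads$retained)))
  invisible(x)
}

#' Molecules-per-bead occupancy table
#'
#' @param assignment a `bead_assignment`.
#' @param include_empty include beads holding zero molecules (default TRUE).
#' @return data.table with `n_molecules` and `n_beads` counts.
#' @export
bead_occupancy <- function(assignment, include_empty = TRUE) {
  occ <- assignment$assignment[, .N, by = bead_id]
  tab <- occ[, .(n_beads = .N), by = .(n_molecules = N)]
  if (include_empty) {
    empty <- assignment$n_beads - nrow(assignment$beads)
    tab <- rbind(data.table(n_molecules = 0L, n_beads = empty), tab)
  }
  setorder(tab, n_molecules)[]
}

#' True per-bead distinct-fragment counts
#'
#' For collision accounting from simulation truth: the number of distinct
#' reference fragments (locus or filling fragment ids) captured by each
#' retained occupied bead. A bead holding two molecules of the *same*
#' fragment counts as one, mirroring what a barcode-based estimator can see.
#'
#' @param assignment a `bead_assignment`.
#' @param pool the `fragment_pool` it was built from.
#' @param retained_only restrict to retained beads (default TRUE).
#' @return data.table with `bead_id`, `barcode`, `n_fragments`.
#' @export
bead_truth_fragments <- function(assignment, pool, retained_only = TRUE) {
  a <- merge(assignment$assignment,
             pool[, .(molecule_id, locus_id)], by = "molecule_id")
  n <- a[, .(n_fragments = uniqueN(locus_id)), by = bead_id]
  out <- merge(assignment$beads, n, by = "bead_id")
  if (retained_only) out <- out[retained == TRUE]
  out[]
}
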
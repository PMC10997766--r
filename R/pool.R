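# Sample composition and molecule pools. Experiments are specified in
# picograms of input DNA; conversion to molecule counts uses the average
# molar mass of one double-stranded base pair (650 g/mol).

AVOGADRO <- 6.022e23
BP_G_PER_MOL <- 650

#' Convert a DNA mass to a molecule count
#'
#' `N = round(mass_pg * 1e-12 * 6.022e23 / (length_bp * 650))`, using
#' 650 g/mol per base pair.
#'
#' @param mass_pg DNA mass in picograms (>= 0).
#' @param length_bp molecule length in bp (> 0).
#' @return integer molecule count.
#' @export
#' @examples
#' mass_to_molecules(20, 8453)    # ~2.19e6
#' mass_to_molecules(100, 48502)  # ~1.91e6
mass_to_molecules <- function(mass_pg, length_bp) {
  if (any(mass_pg < 0)) stop_param("mass_pg must be >= 0")
  if (any(length_bp <= 0)) stop_param("length_bp must be > 0")
  round(mass_pg * 1e-12 * AVOGADRO / (length_bp * BP_G_PER_MOL))
}

#' Inverse of [mass_to_molecules()]
#'
#' Mass in pg that yields (approximately) `n_molecules` molecules of the
#' given length. Convenient for setting up simulations by molecule count.
#'
#' @param n_molecules desired molecule count.
#' @param length_bp molecule length in bp.
#' @return mass in picograms.
#' @export
molecules_to_mass <- function(n_molecules, length_bp) {
  n_molecules * length_bp * BP_G_PER_MOL / AVOGADRO * 1e12
}

#' Describe the DNA composition of a library input
#'
#' Captures the mass-based sample description: per-locus target mass, optional
#' off-target background (impure enrichments carry < 1-5% target DNA over
#' total), optional filling DNA (equimolar restriction digest), a haplotype
#' amplification bias and a haplotype dropout fraction (models e.g. an
#' inversion breaking one haplotype's enrichment, possibly mosaic).
#'
#' @param target_mass_pg numeric; per-locus target mass in pg. Either a
#'   scalar (recycled over loci) or a vector named by locus id.
#' @param background_mass_pg off-target genomic DNA mass in pg.
#' @param background_genome_bp length of the synthetic background genome.
#' @param background_frag_bp fragment length of background molecules.
#' @param filling_mass_pg filling DNA mass in pg.
#' @param filling_set data.frame of filling fragment lengths
#'   (default [bstp1_fragments()]).
#' @param hap_bias fraction of target molecules drawn from haplotype 1
#'   (default 0.5, balanced).
#' @param dropout_fraction fraction of `dropout_hap` molecules removed
#'   (default 0).
#' @param dropout_hap which haplotype suffers dropout (1 or 2; default 2).
#' @param purity_class "pure" (e.g. amplicons) or "impure" (partial
#'   enrichment); informational label.
#' @return object of class `sample_composition`.
#' @export
sample_composition <- function(target_mass_pg,
                               background_mass_pg = 0,
                               background_genome_bp = 100000,
                               background_frag_bp = 3000,
                               filling_mass_pg = 0,
                               filling_set = bstp1_fragments(),
                               hap_bias = 0.5,
                               dropout_fraction = 0,
                               dropout_hap = 2L,
                               purity_class = c("pure", "impure")) {
  purity_class <- match.arg(purity_class)
  if (any(target_mass_pg < 0) || background_mass_pg < 0 || filling_mass_pg < 0)
    stop_param("masses must be >= 0")
  if (hap_bias < 0 || hap_bias > 1) stop_param("hap_bias must be in [0, 1]")
  if (dropout_fraction < 0 || dropout_fraction > 1)
    stop_param("dropout_fraction must be in [0, 1]")
  stopifnot(dropout_hap %in% c(1L, 2L))
  structure(
    list(target_mass_pg = target_mass_pg,
         background_mass_pg = background_mass_pg,
         background_genome_bp = as.integer(background_genome_bp),
         background_frag_bp = as.integer(background_frag_bp),
         filling_mass_pg = filling_mass_pg,
         filling_set = filling_set,
         hap_bias = hap_bias,
         dropout_fraction = dropout_fraction,
         dropout_hap = as.integer(dropout_hap),
         purity_class = purity_class),
    class = "sample_composition"
  )
}

#' Build the molecule pool of a library input
#'
#' Converts the mass-based composition into individual molecules. Target
#' molecules are full-length copies of the locus haplotype sequences, split
#' between haplotypes by `hap_bias` (binomially) and thinned by
#' `dropout_fraction` on the designated haplotype. Filling molecules follow
#' the equimolar digest (one copy of each fragment per genome equivalent).
#' Background molecules are fixed-length fragments drawn uniformly from a
#' random background genome that is absent from the mapping reference, so
#' their reads stay off-target.
#'
#' Molecule sequences are not materialised: each molecule is an interval on a
#' named source sequence; use [molecule_seq()] to extract sequences.
#'
#' @param loci list of `diploid_locus` objects (or a single one).
#' @param composition a [sample_composition()].
#' @param seed optional integer seed.
#' @return data.table of class `fragment_pool` with columns `molecule_id`,
#'   `source` (target_hap1/target_hap2/background/filling), `locus_id`,
#'   `seq_name`, `start`, `end` (0-based half-open on the source sequence).
#'   Source sequences are attached as attribute `seqs`; the loci as `loci`.
#' @export
build_fragment_pool <- function(loci, composition, seed = NULL) {
  if (inherits(loci, "diploid_locus")) loci <- list(loci)
  stopifnot(inherits(composition, "sample_composition"))
  if (!is.null(seed)) set.seed(seed)

  ids <- vapply(loci, `[[`, character(1), "locus_id")
  if (anyDuplicated(ids)) stop_param("loci must have distinct locus_id")
  tm <- composition$target_mass_pg
  if (length(loci) == 0 && any(tm > 0))
    stop_param("nonzero target mass with no loci")
  if (length(tm) > 1) {
    if (is.null(names(tm)) || !all(ids %in% names(tm)))
      stop_param("vector target_mass_pg must be named by locus id")
    tm <- tm[ids]
  } else {
    tm <- rep(tm, length(loci))
  }

  seqs <- character(0)
  parts <- list()

  for (i in seq_along(loci)) {
    loc <- loci[[i]]
    hs <- hap_seqs(loc)
    n1_name <- paste0(loc$locus_id, ".hap1")
    n2_name <- paste0(loc$locus_id, ".hap2")
    seqs[n1_name] <- hs[["hap1"]]
    seqs[n2_name] <- hs[["hap2"]]
    n_total <- mass_to_molecules(tm[i], loc$length_bp)
    n1 <- rbinom(1, n_total, composition$hap_bias)
    n2 <- n_total - n1
    if (composition$dropout_fraction > 0) {
      if (composition$dropout_hap == 1L)
        n1 <- rbinom(1, n1, 1 - composition$dropout_fraction)
      else
        n2 <- rbinom(1, n2, 1 - composition$dropout_fraction)
    }
    if (n1 + n2 > 0) {
      parts[[length(parts) + 1L]] <- data.table(
        source = rep(c("target_hap1", "target_hap2"), c(n1, n2)),
        locus_id = loc$locus_id,
        seq_name = rep(c(n1_name, n2_name), c(n1, n2)),
        start = 0L, end = loc$length_bp
      )
    }
  }

  if (composition$filling_mass_pg > 0) {
    fs <- composition$filling_set
    genome_bp <- sum(fs$length_bp)
    fill_seqs <- filling_reference(fs)
    seqs[names(fill_seqs)] <- fill_seqs
    n_copies <- mass_to_molecules(composition$filling_mass_pg, genome_bp)
    if (n_copies > 0) {
      parts[[length(parts) + 1L]] <- data.table(
        source = "filling",
        locus_id = rep(fs$fragment_id, each = n_copies),
        seq_name = rep(fs$fragment_id, each = n_copies),
        start = 0L,
        end = rep(fs$length_bp, each = n_copies)
      )
    }
  }

  if (composition$background_mass_pg > 0) {
    gbp <- composition$background_genome_bp
    fbp <- min(composition$background_frag_bp, gbp)
    seqs["background"] <- random_seq(gbp)
    nb <- mass_to_molecules(composition$background_mass_pg, fbp)
    if (nb > 0) {
      st <- as.integer(floor(runif(nb, 0, gbp - fbp + 1)))
      parts[[length(parts) + 1L]] <- data.table(
        source = "background", locus_id = "background",
        seq_name = "background", start = st, end = st + fbp
      )
    }
  }

  pool <- if (length(parts)) rbindlist(parts) else
    data.table(source = character(0), locus_id = character(0),
               seq_name = character(0), start = integer(0), end = integer(0))
  pool[, molecule_id := seq_len(.N)]
  setcolorder(pool, c("molecule_id", "source", "locus_id", "seq_name",
                      "start", "end"))
  setattr(pool, "seqs", seqs)
  setattr(pool, "loci", loci)
  setattr(pool, "class", c("fragment_pool", class(pool)))
  pool[]
}

#' Extract molecule sequences from a pool
#'
#' @param pool a `fragment_pool`.
#' @param molecule_ids molecule ids (default all).
#' @return character vector of sequences named by molecule id.
#' @export
molecule_seq <- function(pool, molecule_ids = pool$molecule_id) {
  seqs <- attr(pool, "seqs")
  idx <- match(molecule_ids, pool$molecule_id)
  if (anyNA(idx)) stop_param("unknown molecule id")
  out <- substring(seqs[pool$seq_name[idx]], pool$start[idx] + 1L, pool$end[idx])
  names(out) <- molecule_ids
  out
}
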
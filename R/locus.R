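# Diploid target loci: a reference segment plus truth haplotypes at
# heterozygous SNV sites. In typical human targets heterozygous sites occur
# roughly every 1-2 kb; low-heterozygosity regions (spacings > 10 kb) are the
# hard case for barcode-linked phasing.

#' Construct a diploid locus with known haplotypes
#'
#' Generates a random reference segment and places biallelic heterozygous SNV
#' sites along it. Site positions follow a renewal process with geometric
#' inter-site distances of the given mean (so the site count over `length_bp`
#' is approximately Poisson with mean `length_bp / mean_het_spacing_bp`), or
#' can be fixed explicitly via `het_positions`. At every site one haplotype
#' carries the reference base and the other a random alternate base; which
#' haplotype carries the reference allele is randomised per site.
#'
#' @param length_bp locus length in bp (>= 100).
#' @param mean_het_spacing_bp mean distance between adjacent heterozygous
#'   sites in bp (default 1500, the typical human regime).
#' @param seed optional integer seed for reproducibility.
#' @param het_positions optional integer vector of 0-based site positions
#'   (strictly increasing, < `length_bp`); overrides the renewal process.
#' @param locus_id locus name (default "locus1").
#' @return An object of class `diploid_locus`: a list with `locus_id`,
#'   `ref_seq`, `length_bp` and `het_sites` (data.frame with 0-based `pos`,
#'   `allele_hap1`, `allele_hap2`).
#' @export
#' @examples
#' loc <- make_diploid_locus(20000, 1500, seed = 1)
#' nrow(loc$het_sites)
make_diploid_locus <- function(length_bp, mean_het_spacing_bp = 1500,
                               seed = NULL, het_positions = NULL,
                               locus_id = "locus1") {
  if (length_bp < 100) stop_param("length_bp must be >= 100")
  if (mean_het_spacing_bp <= 0) stop_param("mean_het_spacing_bp must be > 0")
  if (!is.null(seed)) set.seed(seed)

  ref_seq <- random_seq(length_bp)

  if (is.null(het_positions)) {
    # geometric gaps with mean spacing: rgeom has mean (1-p)/p, add 1
    n_draw <- max(10L, ceiling(3 * length_bp / mean_het_spacing_bp) + 10L)
    gaps <- rgeom(n_draw, prob = 1 / mean_het_spacing_bp) + 1L
    pos <- cumsum(gaps) - 1L
    while (length(pos) && max(pos) < length_bp) {
      gaps <- rgeom(n_draw, prob = 1 / mean_het_spacing_bp) + 1L
      pos <- c(pos, max(pos) + 1L + cumsum(gaps) - 1L)
    }
    pos <- pos[pos < length_bp]
  } else {
    pos <- as.integer(het_positions)
    if (any(pos < 0) || any(pos >= length_bp) || is.unsorted(pos, strictly = TRUE))
      stop_param("het_positions must be strictly increasing and in [0, length_bp)")
  }

  n <- length(pos)
  ref_base <- substring(ref_seq, pos + 1L, pos + 1L)
  alt_base <- vapply(ref_base, function(b) sample(setdiff(DNA_BASES, b), 1L),
                     character(1), USE.NAMES = FALSE)
  ref_on_hap1 <- sample(c(TRUE, FALSE), n, replace = TRUE)
  het <- data.frame(
    pos = pos,
    allele_hap1 = ifelse(ref_on_hap1, ref_base, alt_base),
    allele_hap2 = ifelse(ref_on_hap1, alt_base, ref_base),
    stringsAsFactors = FALSE
  )

  out <- structure(
    list(locus_id = locus_id, ref_seq = ref_seq, length_bp = as.integer(length_bp),
         het_sites = het),
    class = "diploid_locus"
  )
  validate_diploid_locus(out)
  out
}

#' @export
print.diploid_locus <- function(x, ...) {
  cat(sprintf("<diploid_locus> %s: %d bp, %d heterozygous sites\n",
              x$locus_id, x$length_bp, nrow(x$het_sites)))
  invisible(x)
}

validate_diploid_locus <- function(x) {
  stopifnot(inherits(x, "diploid_locus"))
  h <- x$het_sites
  if (nrow(h)) {
    if (is.unsorted(h$pos, strictly = TRUE))
      stop_param("het site positions must be strictly increasing")
    if (any(h$pos < 0 | h$pos >= x$length_bp))
      stop_param("het site positions out of range")
    if (any(h$allele_hap1 == h$allele_hap2))
      stop_param("het site alleles must differ between haplotypes")
  }
  if (grepl("[^ACGT]", x$ref_seq)) stop_param("ref_seq must be A/C/G/T only")
  invisible(TRUE)
}

#' Haplotype sequences of a diploid locus
#'
#' @param locus a `diploid_locus`.
#' @return named character vector with elements `hap1` and `hap2`: the
#'   reference sequence with each haplotype's alleles substituted in.
#' @export
hap_seqs <- function(locus) {
  stopifnot(inherits(locus, "diploid_locus"))
  h <- locus$het_sites
  make_hap <- function(alleles) {
    s <- strsplit(locus$ref_seq, "", fixed = TRUE)[[1]]
    if (nrow(h)) s[h$pos + 1L] <- alleles
    paste(s, collapse = "")
  }
  c(hap1 = make_hap(h$allele_hap1), hap2 = make_hap(h$allele_hap2))
}
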
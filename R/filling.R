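# Filling DNA: restriction digest of the 48.5 kb lambda phage genome used to
# stabilise library yield at low target input and dilute same-locus collisions.

#' BstP I lambda digest fragment table
#'
#' The fourteen non-overlapping fragments produced by BstP I digestion of the
#' 48,502 bp lambda phage genome. The digest is equimolar: every genome copy
#' contributes exactly one molecule of each fragment, so per-fragment molecule
#' counts are identical while mass share is proportional to fragment length.
#'
#' @return A data.frame with columns `fragment_id` and `length_bp` (14 rows,
#'   lengths summing to 48,502).
#' @export
#' @examples
#' sum(bstp1_fragments()$length_bp)  # 48502
bstp1_fragments <- function() {
  len <- c(117L, 224L, 702L, 1264L, 1371L, 1929L, 2323L, 3675L, 4324L,
           4822L, 5687L, 6369L, 7242L, 8453L)
  data.frame(
    fragment_id = sprintf("lambda_bstp1_%04d", len),
    length_bp = len,
    stringsAsFactors = FALSE
  )
}

#' Synthetic reference sequences for a filling-fragment set
#'
#' Generates random nucleotide sequences of the digest fragment lengths.
#' These are synthetic stand-ins: only the fragment lengths (and hence
#' molarities) matter for collision and coverage analyses.
#'
#' @param filling_set data.frame with `fragment_id` and `length_bp`
#'   (default [bstp1_fragments()]).
#' @param seed optional integer seed.
#' @return named character vector of sequences.
#' @export
filling_reference <- function(filling_set = bstp1_fragments(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  setNames(
    vapply(filling_set$length_bp, random_seq, character(1)),
    filling_set$fragment_id
  )
}
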
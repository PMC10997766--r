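# Preprocessing: 3' adapter trimming, bead-barcode error correction
# (single-read barcodes one mismatch away from a multi-read barcode are
# assumed to carry a sequencing error), and within-barcode duplicate marking.

#' Default library adapter sequences
#'
#' The three R1 adapters (accounting for adapter dimers) and the single R2
#' adapter used for 3' trimming.
#'
#' @return list with character vectors `r1` and `r2`.
#' @export
default_adapters <- function() {
  list(
    r1 = c("TGAAGCGGCGCACGAAAAACGCGAAAGCGTTTCAC",
           "ATCACGGACTGCCCATAGAGAGGCTCTGG",
           "TGGTCATGTGGAGACGCTGGG"),
    r2 = "TGGGCCGGTGCAGTTAATGTAGGGAAAGAGTGT"
  )
}

#' Trim 3' adapters from read sequences
#'
#' Exact-match 3' trimming: a full internal occurrence of an adapter
#' truncates the read from the match start; otherwise the longest read
#' suffix equal to an adapter prefix of length >= `min_overlap` is removed.
#'
#' @param read_seq character vector of read sequences.
#' @param adapter_set character vector of adapter sequences (an empty set
#'   returns reads unchanged).
#' @param min_overlap minimum suffix/prefix overlap (>= 1; default 5).
#' @return character vector of trimmed sequences.
#' @export
#' @examples
#' trim_adapters("ACGTACGTTGGGC", "TGGGCC", min_overlap = 5)
trim_adapters <- function(read_seq, adapter_set, min_overlap = 5L) {
  if (min_overlap < 1) stop_param("min_overlap must be >= 1")
  if (length(adapter_set) == 0) return(read_seq)
  out <- read_seq
  for (ad in adapter_set) {
    # full internal occurrence: cut from match start
    hit <- regexpr(ad, out, fixed = TRUE)
    has <- hit > 0
    out[has] <- substring(out[has], 1L, hit[has] - 1L)
    # partial adapter at the read end: longest suffix == adapter prefix
    # (one removal per adapter: longest match wins)
    max_l <- min(nchar(ad) - 1L, max(nchar(out), 0L))
    if (max_l >= min_overlap) {
      done <- rep(FALSE, length(out))
      for (l in seq(max_l, min_overlap)) {
        pre <- substring(ad, 1L, l)
        n <- nchar(out)
        is_suffix <- !done & n >= l & substring(out, n - l + 1L, n) == pre
        out[is_suffix] <- substring(out[is_suffix], 1L, n[is_suffix] - l)
        done <- done | is_suffix
      }
    }
  }
  out
}

#' Correct sequencing errors in bead barcodes
#'
#' Every barcode observed on a single read pair that lies at Hamming
#' distance 1 from exactly one multi-read barcode (count >= 2) is mapped to
#' that barcode; ambiguous singletons (two or more candidate neighbours) and
#' all multi-read barcodes are left unchanged.
#'
#' @param barcode_counts named integer vector: observed barcode -> read count
#'   (all counts >= 1, all barcodes the same length).
#' @return object of class `barcode_table`: data.table with `observed`,
#'   `count`, `corrected`.
#' @export
correct_barcodes <- function(barcode_counts) {
  if (length(barcode_counts) == 0)
    return(structure(data.table(observed = character(0), count = integer(0),
                                corrected = character(0)),
                     class = c("barcode_table", "data.table", "data.frame")))
  bc <- names(barcode_counts)
  if (is.null(bc) || any(barcode_counts < 1))
    stop_param("barcode_counts must be a named vector of counts >= 1")
  w <- nchar(bc)
  if (length(unique(w)) != 1) stop_param("barcodes must have equal length")
  w <- w[1]

  multi <- bc[barcode_counts >= 2]
  singles <- bc[barcode_counts == 1]
  corrected <- setNames(bc, bc)

  if (length(singles) && length(multi)) {
    for (s in seq_along(singles)) {
      x <- singles[s]
      cand <- character(0)
      for (p in seq_len(w)) {
        b <- substring(x, p, p)
        for (nb in setdiff(DNA_BASES, b)) {
          v <- paste0(substring(x, 1L, p - 1L), nb, substring(x, p + 1L, w))
          if (v %chin% multi) cand <- c(cand, v)
        }
      }
      cand <- unique(cand)
      if (length(cand) == 1L) corrected[x] <- cand
    }
  }
  out <- data.table(observed = bc, count = as.integer(barcode_counts),
                    corrected = unname(corrected[bc]))
  setattr(out, "class", c("barcode_table", "data.table", "data.frame"))
  out[]
}

#' Apply a barcode table to observed barcodes
#'
#' @param table a `barcode_table` from [correct_barcodes()].
#' @param observed character vector of observed barcodes.
#' @return character vector of corrected barcodes (unknown barcodes pass
#'   through unchanged).
#' @export
apply_barcode_correction <- function(table, observed) {
  i <- match(observed, table$observed)
  out <- observed
  out[!is.na(i)] <- table$corrected[i[!is.na(i)]]
  out
}

#' Mark PCR duplicates within barcodes
#'
#' Within each barcode, read pairs sharing (reference, R1 start, R2 start,
#' orientation) beyond the first are flagged as duplicates. Pairs with equal
#' coordinates but different barcodes are never flagged (they derive from
#' different molecules). The first pair in a stable sort by read id is kept;
#' the operation is idempotent. Unaligned reads pass through unflagged.
#'
#' @param aligned an `aligned_reads` table (mate-level; see [map_reads()]).
#' @return the table with the `dup` column set.
#' @export
mark_duplicates <- function(aligned) {
  al <- copy(as.data.table(aligned))
  al[, dup := FALSE]
  pair <- dcast(al[mapped == TRUE],
                read_id + barcode + ref ~ mate,
                value.var = c("pos", "strand"))
  # only pairs with both mates mapped to the same reference participate
  if (!all(c("pos_1", "pos_2") %in% names(pair))) {
    cls <- class(aligned)
    setattr(al, "class", cls)
    return(al[])
  }
  pair <- pair[!is.na(pos_1) & !is.na(pos_2)]
  setorder(pair, read_id)
  pair[, dup := duplicated(.SD),
       .SDcols = c("barcode", "ref", "pos_1", "pos_2", "strand_1")]
  dups <- pair[dup == TRUE, read_id]
  al[read_id %in% dups, dup := TRUE]
  setattr(al, "class", class(aligned))
  al[]
}
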
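# Lite read mapping for small target references. Reads are placed by exact
# k-mer seed voting (both strands) and extended with a substitution-only
# alignment, giving CIGARs over soft-clips and matches. This stands in for a
# full gapped aligner only because the generator emits no indels; real-data
# users can import externally produced alignments via the SAM-like layer.

#' Build a k-mer index over reference sequences
#' @param refs named character vector of reference sequences.
#' @param k seed length (default 21).
#' @return data.table keyed by `kmer` with columns `ref`, `pos` (0-based).
#' @export
kmer_index <- function(refs, k = 21L) {
  stopifnot(!is.null(names(refs)))
  parts <- lapply(names(refs), function(nm) {
    sq <- refs[[nm]]
    n <- nchar(sq) - k + 1L
    if (n < 1) return(NULL)
    data.table(kmer = substring(sq, seq_len(n), seq_len(n) + k - 1L),
               ref = nm, pos = seq_len(n) - 1L)
  })
  idx <- rbindlist(parts)
  setkey(idx, kmer)
  setattr(idx, "k", as.integer(k))
  idx
}

#' Map read pairs to references by k-mer seed voting
#'
#' Each mate is mapped independently on both strands: equally spaced exact
#' seeds vote for an implied (reference, strand, start); the placement with
#' the most votes wins and a tied best vote leaves the read unmapped. The
#' CIGAR is substitution-only (`M` with terminal `S` soft-clips where the
#' read would overhang the reference). On error-free simulated reads the
#' placement equals the truth origin; reads from sequences absent from the
#' reference set (e.g. off-target background) have no seed hits and are
#' flagged unmapped.
#'
#' @param reads a `read_pairs` table (or any table with `read_id`, `r1_seq`,
#'   `r2_seq`, `observed_barcode`).
#' @param refs named character vector of reference sequences.
#' @param k seed length (default 21).
#' @param n_seeds seeds per read (default 5).
#' @return data.table of class `aligned_reads`, one row per mate: `read_id`,
#'   `mate` (1/2), `ref`, `pos` (0-based), `cigar`, `strand`, `barcode`,
#'   `mapped`, `dup`, `seq` (reference-forward orientation, as in SAM).
#' @export
map_reads <- function(reads, refs, k = 21L, n_seeds = 5L) {
  idx <- kmer_index(refs, k)
  rl <- data.table(
    read_id = rep(reads$read_id, 2L),
    mate = rep(c(1L, 2L), each = nrow(reads)),
    barcode = rep(reads$observed_barcode, 2L),
    seq = c(reads$r1_seq, reads$r2_seq)
  )
  align_mates(rl, refs, idx, k, n_seeds)
}

align_mates <- function(rl, refs, idx, k, n_seeds) {
  n <- nrow(rl)
  rl[, pair_id := seq_len(n)]
  wid <- nchar(rl$seq)

  # seed offsets depend only on read width; group by width for speed
  uw <- unique(wid)
  offs_by_w <- lapply(uw, function(w) {
    if (w < k) return(integer(0))
    unique(as.integer(round(seq(0L, w - k, length.out = min(n_seeds, w - k + 1L)))))
  })
  seed_tpl <- rbindlist(lapply(seq_along(uw), function(j) {
    o <- offs_by_w[[j]]
    if (!length(o)) return(NULL)
    ids <- rl$pair_id[wid == uw[j]]
    data.table(pair_id = rep(ids, each = length(o)),
               off = rep(o, length(ids)))
  }))

  cand_all <- list()
  for (str in c("+", "-")) {
    sq <- if (str == "+") rl$seq else revcomp(rl$seq)
    if (nrow(seed_tpl) == 0) break
    seeds <- copy(seed_tpl)
    seeds[, kmer := substring(sq[pair_id], off + 1L, off + k)]
    hits <- idx[seeds, on = "kmer", allow.cartesian = TRUE, nomatch = NULL]
    if (nrow(hits)) {
      hits[, start := pos - off]
      cand_all[[str]] <- hits[, .(votes = .N),
                              by = .(pair_id, ref, start)][, strand := str]
    }
  }
  cand <- rbindlist(cand_all)

  out <- rl[, .(read_id, mate, barcode, seq)]
  out[, `:=`(ref = NA_character_, pos = NA_integer_, cigar = NA_character_,
             strand = NA_character_, mapped = FALSE, dup = FALSE)]
  if (nrow(cand)) {
    setorder(cand, pair_id, -votes, ref, start, strand)
    first <- which(!duplicated(cand$pair_id))
    nxt <- first + 1L
    has_nxt <- nxt <= nrow(cand)
    tied <- has_nxt & cand$pair_id[pmin(nxt, nrow(cand))] == cand$pair_id[first] &
      cand$votes[pmin(nxt, nrow(cand))] == cand$votes[first]
    best <- cand[first[!tied]]
    if (nrow(best)) {
      i <- best$pair_id
      w <- wid[i]
      reflen <- nchar(refs)[match(best$ref, names(refs))]
      clip_l <- pmax(0L, -best$start)
      m_end <- pmin(w, reflen - best$start)
      clip_r <- w - m_end
      m_len <- w - clip_l - clip_r
      ok <- m_len >= 1L
      i <- i[ok]
      out[i, `:=`(
        ref = best$ref[ok],
        pos = best$start[ok] + clip_l[ok],
        cigar = paste0(ifelse(clip_l[ok] > 0, paste0(clip_l[ok], "S"), ""),
                       m_len[ok], "M",
                       ifelse(clip_r[ok] > 0, paste0(clip_r[ok], "S"), "")),
        strand = best$strand[ok],
        mapped = TRUE
      )]
      # store reference-forward sequence for minus-strand alignments
      neg <- which(out$mapped & out$strand == "-")
      if (length(neg)) out[neg, seq := revcomp(seq)]
    }
  }
  setcolorder(out, c("read_id", "mate", "ref", "pos", "cigar", "strand",
                     "barcode", "mapped", "dup", "seq"))
  setattr(out, "class", c("aligned_reads", "data.table", "data.frame"))
  out[]
}

#' Parse a CIGAR string
#' @param cigar a single CIGAR string over M/I/D/S.
#' @return data.frame with `op` and `len`.
#' @export
parse_cigar <- function(cigar) {
  if (is.na(cigar) || !grepl("^([0-9]+[MIDS])+$", cigar))
    stop_param("malformed CIGAR: ", cigar)
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDS]", cigar))[[1]]
  data.frame(op = ops, len = lens, stringsAsFactors = FALSE)
}

#' Project aligned query bases onto reference coordinates
#'
#' Walks the CIGAR: `M` advances query and reference, `I` and `S` advance the
#' query only, `D` advances the reference only. Only aligned (`M`) bases emit
#' a pair, so the result is a bijection between aligned query bases and the
#' reference positions the read covers.
#'
#' @param pos 0-based alignment start on the reference.
#' @param cigar CIGAR string over M/I/D/S.
#' @return data.frame with `qidx` (0-based query index) and `rpos` (0-based
#'   reference position) for every aligned base.
#' @export
#' @examples
#' cigar_to_ref_coords(100, "5S140M")
cigar_to_ref_coords <- function(pos, cigar) {
  cg <- parse_cigar(cigar)
  q <- 0L; r <- as.integer(pos)
  qs <- integer(0); rs <- integer(0)
  for (i in seq_len(nrow(cg))) {
    op <- cg$op[i]; l <- cg$len[i]
    if (op == "M") {
      qs <- c(qs, q + seq_len(l) - 1L)
      rs <- c(rs, r + seq_len(l) - 1L)
      q <- q + l; r <- r + l
    } else if (op == "I" || op == "S") {
      q <- q + l
    } else if (op == "D") {
      r <- r + l
    }
  }
  data.frame(qidx = qs, rpos = rs)
}
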
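# Per-position nucleotide counting and diploid SNV genotyping. Each read's
# CIGAR determines where every read base maps on the reference; duplicates
# are excluded; a site is heterozygous when the two most frequent bases both
# reach the allele-frequency cutoff at sufficient depth.

# expand aligned reads into one row per aligned base
# fast path for "aS bM cS" CIGARs (the lite mapper's output); general CIGARs
# go through cigar_to_ref_coords()
expand_aligned_bases <- function(aligned, keep_pos = NULL) {
  al <- as.data.table(aligned)[mapped == TRUE & dup == FALSE & !is.na(cigar)]
  if (nrow(al) == 0)
    return(data.table(ref = character(0), rpos = integer(0),
                      base = character(0), barcode = character(0),
                      read_id = character(0)))
  simple <- grepl("^([0-9]+S)?[0-9]+M([0-9]+S)?$", al$cigar)
  parts <- list()
  if (any(simple)) {
    s <- al[simple]
    clip_l <- rep(0L, nrow(s))
    has_clip <- grepl("^[0-9]+S", s$cigar)
    clip_l[has_clip] <- as.integer(sub("^([0-9]+)S.*$", "\\1",
                                       s$cigar[has_clip]))
    m_len <- as.integer(sub("^(?:[0-9]+S)?([0-9]+)M.*$", "\\1", s$cigar))
    mseq <- substring(s$seq, clip_l + 1L, clip_l + m_len)
    bases <- unlist(strsplit(mseq, "", fixed = TRUE), use.names = FALSE)
    parts$simple <- data.table(
      ref = rep(s$ref, m_len),
      rpos = sequence(m_len) - 1L + rep(s$pos, m_len),
      base = bases,
      barcode = rep(s$barcode, m_len),
      read_id = rep(s$read_id, m_len)
    )
  }
  if (any(!simple)) {
    g <- al[!simple]
    parts$general <- rbindlist(lapply(seq_len(nrow(g)), function(i) {
      m <- cigar_to_ref_coords(g$pos[i], g$cigar[i])
      data.table(ref = g$ref[i], rpos = m$rpos,
                 base = substring(g$seq[i], m$qidx + 1L, m$qidx + 1L),
                 barcode = g$barcode[i], read_id = g$read_id[i])
    }))
  }
  out <- if (length(parts) == 1L) parts[[1L]] else rbindlist(parts)
  if (!is.null(keep_pos))
    out <- out[keep_pos, on = c("ref", "rpos"), nomatch = NULL]
  out
}

#' Per-position nucleotide counts (pileup)
#'
#' Counts A/C/G/T occurrences of aligned bases at each reference position,
#' excluding duplicate-flagged and unmapped reads.
#'
#' @param aligned an `aligned_reads` table.
#' @param ref optional reference name to restrict to.
#' @param region optional `c(start, end)` 0-based half-open window.
#' @return data.table of class `site_counts`: `ref`, `pos` (0-based), `A`,
#'   `C`, `G`, `T`, `depth`.
#' @export
pileup_counts <- function(aligned, ref = NULL, region = NULL) {
  bases <- expand_aligned_bases(aligned)
  if (!is.null(ref)) bases <- bases[bases$ref == ref]
  if (!is.null(region)) bases <- bases[rpos >= region[1] & rpos < region[2]]
  if (nrow(bases) == 0) {
    out <- data.table(ref = character(0), pos = integer(0), A = integer(0),
                      C = integer(0), G = integer(0), T = integer(0),
                      depth = integer(0))
  } else {
    bases <- bases[base %chin% DNA_BASES]
    cnt <- dcast(bases[, .N, by = .(ref, pos = rpos, base)],
                 ref + pos ~ base, value.var = "N", fill = 0L)
    for (b in DNA_BASES) if (!b %in% names(cnt)) cnt[, (b) := 0L]
    out <- cnt[, .(ref, pos, A, C, G, T, depth = A + C + G + T)]
    setorder(out, ref, pos)
  }
  setattr(out, "class", c("site_counts", "data.table", "data.frame"))
  out[]
}

#' Call diploid SNV genotypes from pileup counts
#'
#' A site is heterozygous iff its two most frequent bases each reach
#' fraction >= `af_cutoff` of the depth and depth >= `min_depth`; otherwise
#' it is homozygous for the majority base. Only sites that are heterozygous
#' or differ from the reference are emitted; zero-depth or sub-`min_depth`
#' sites yield no call (they surface downstream as failed genotyping).
#'
#' @param site_counts a `site_counts` table.
#' @param refs named character vector of reference sequences (for the
#'   reference base).
#' @param af_cutoff minor allele-frequency cutoff in (0, 0.5] (default 0.1).
#' @param min_depth minimum depth to call a site (default 10).
#' @return data.table of class `genotype_calls`: `ref`, `pos` (0-based),
#'   `ref_base`, `genotype` (het/hom_alt), `a1`, `a2` (a2 `NA` for hom),
#'   `ad1`, `ad2`, `depth`.
#' @export
call_genotypes <- function(site_counts, refs, af_cutoff = 0.1, min_depth = 10L) {
  if (af_cutoff <= 0 || af_cutoff > 0.5)
    stop_param("af_cutoff must be in (0, 0.5]")
  if (min_depth < 1) stop_param("min_depth must be >= 1")
  sc <- as.data.table(site_counts)
  empty <- data.table(ref = character(0), pos = integer(0),
                      ref_base = character(0), genotype = character(0),
                      a1 = character(0), a2 = character(0),
                      ad1 = integer(0), ad2 = integer(0), depth = integer(0))
  setattr(empty, "class", c("genotype_calls", "data.table", "data.frame"))
  if (nrow(sc) == 0) return(empty[])
  sc <- sc[depth >= min_depth]
  if (nrow(sc) == 0) return(empty[])

  m <- as.matrix(sc[, .(A, C, G, T)])
  ord1 <- max.col(m, ties.method = "first")
  top1 <- m[cbind(seq_len(nrow(m)), ord1)]
  m2 <- m; m2[cbind(seq_len(nrow(m)), ord1)] <- -1L
  ord2 <- max.col(m2, ties.method = "first")
  top2 <- m[cbind(seq_len(nrow(m)), ord2)]

  ref_base <- substring(refs[sc$ref], sc$pos + 1L, sc$pos + 1L)
  is_het <- (top1 / sc$depth >= af_cutoff) & (top2 / sc$depth >= af_cutoff) &
    top2 > 0
  a1 <- DNA_BASES[ord1]; a2 <- DNA_BASES[ord2]

  out <- data.table(ref = sc$ref, pos = sc$pos, ref_base = ref_base,
                    genotype = ifelse(is_het, "het", "hom"),
                    a1 = a1, a2 = ifelse(is_het, a2, NA_character_),
                    ad1 = top1, ad2 = ifelse(is_het, top2, NA_integer_),
                    depth = sc$depth)
  # emit only informative sites: het, or hom different from reference
  out <- out[genotype == "het" | a1 != ref_base]
  out[genotype == "hom", genotype := "hom_alt"]
  # put the reference allele first for het sites when present
  swap <- out$genotype == "het" & !is.na(out$a2) & out$a2 == out$ref_base
  if (any(swap)) {
    tmp_a <- out$a1[swap]; tmp_d <- out$ad1[swap]
    out[swap, `:=`(a1 = a2, ad1 = ad2)]
    out[swap, `:=`(a2 = tmp_a, ad2 = tmp_d)]
  }
  setattr(out, "class", c("genotype_calls", "data.table", "data.frame"))
  out[]
}
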
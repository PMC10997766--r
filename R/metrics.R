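# Library-level statistics: collision-free fraction, linked-read
# efficiency, on-target recovery and coverage, and allele burden. The
# counting unit throughout is the read pair (one sequencing event of one
# molecule); fragment membership is decided by the pair midpoint.

# pair-level view of aligned reads: one row per read pair with both mates
# mapped to the same reference
pair_view <- function(aligned) {
  al <- as.data.table(aligned)[mapped == TRUE]
  if (nrow(al) == 0)
    return(data.table(read_id = character(0), barcode = character(0),
                      ref = character(0), pos_1 = integer(0),
                      pos_2 = integer(0), dup = logical(0), mid = integer(0)))
  p <- dcast(al, read_id + barcode + ref ~ mate, value.var = "pos")
  if (!all(c("1", "2") %in% names(p))) {
    for (m in c("1", "2")) if (!m %in% names(p)) p[, (m) := NA_integer_]
  }
  setnames(p, c("1", "2"), c("pos_1", "pos_2"))
  p <- p[!is.na(pos_1) & !is.na(pos_2)]
  dup <- al[, .(dup = any(dup)), by = read_id]
  p <- merge(p, dup, by = "read_id")
  rl <- al[, nchar(seq[1])]
  p[, mid := as.integer((pmin(pos_1, pos_2) + pmax(pos_1, pos_2) + rl) %/% 2L)]
  p[]
}

check_intervals <- function(fragments) {
  f <- as.data.table(fragments)
  stopifnot(all(c("ref", "start", "end") %in% names(f)))
  if (!"name" %in% names(f)) f[, name := ref]
  setorder(f, ref, start)
  ov <- f[, any(start[-1] < end[-.N]), by = ref]$V1
  if (any(ov)) stop_param("fragment intervals overlap")
  f[]
}

#' Collision report: barcodes spanning multiple target fragments
#'
#' A barcode is associated with every fragment on which at least `min_reads`
#' of its non-duplicate read pairs fall (by pair midpoint); it is
#' collision-free iff it is associated with exactly one fragment. Two
#' molecules of the same fragment on one bead are invisible to this
#' estimator and count as collision-free. Fractions are reported per
#' fragment (share of the fragment's barcodes touching no other fragment)
#' and overall.
#'
#' @param aligned an `aligned_reads` table (deduplicated, corrected).
#' @param fragment_intervals data.frame `ref`, `start`, `end` (0-based
#'   half-open), optional `name`; non-overlapping.
#' @param min_reads read pairs needed to assert a barcode-fragment
#'   association (default 2).
#' @return object of class `collision_report`: list with `barcodes`
#'   (data.table `barcode`, `n_fragments`), `per_fragment` (data.table
#'   `name`, `n_barcodes`, `collision_free_pct`), and
#'   `overall_collision_free_pct`.
#' @export
collision_report <- function(aligned, fragment_intervals, min_reads = 2L) {
  f <- check_intervals(fragment_intervals)
  p <- pair_view(aligned)[dup == FALSE]
  hits <- p[f, on = .(ref, mid >= start, mid < end),
            .(barcode, name = i.name), nomatch = NULL]
  assoc <- hits[, .(n_pairs = .N), by = .(barcode, name)][n_pairs >= min_reads]
  bc <- assoc[, .(n_fragments = uniqueN(name)), by = barcode]
  per_frag <- merge(assoc[, .(barcode, name)], bc, by = "barcode")[
    , .(n_barcodes = .N,
        collision_free_pct = 100 * mean(n_fragments == 1L)), by = name]
  overall <- if (nrow(bc)) 100 * mean(bc$n_fragments == 1L) else NA_real_
  structure(list(barcodes = bc, assoc = assoc,
                 pair_counts = hits[, .(n_pairs = .N), by = .(barcode, name)],
                 per_fragment = per_frag,
                 overall_collision_free_pct = overall,
                 min_reads = as.integer(min_reads)),
            class = "collision_report")
}

#' @export
print.collision_report <- function(x, ...) {
  cat(sprintf("<collision_report> %d barcodes, %.1f%% collision-free\n",
              nrow(x$barcodes), x$overall_collision_free_pct))
  invisible(x)
}

#' Linked-read efficiency among collision-free barcodes
#'
#' Restricted to collision-free barcodes, a read pair is "linked" iff its
#' barcode has at least two non-duplicate pairs on the same fragment.
#' Efficiency is linked pairs over total pairs of those barcodes, in
#' percent.
#'
#' @param aligned an `aligned_reads` table.
#' @param collision_report a [collision_report()].
#' @return object of class `efficiency_report`: list with `linked_reads`,
#'   `total_reads`, `efficiency_pct`, `collision_free_only = TRUE`.
#' @export
linked_read_efficiency <- function(aligned, collision_report) {
  # exclude barcodes associated with two or more fragments (collisions);
  # barcodes too thin to be associated anywhere still count in the total
  multi <- collision_report$barcodes[n_fragments >= 2L, barcode]
  p <- pair_view(aligned)[dup == FALSE & !barcode %chin% multi]
  if (nrow(p) == 0) stop_param("no reads from collision-free barcodes")
  pc <- collision_report$pair_counts[!barcode %chin% multi]
  linked <- pc[n_pairs >= 2L, sum(n_pairs)]
  total <- nrow(p)
  structure(list(linked_reads = linked, total_reads = total,
                 efficiency_pct = 100 * linked / total,
                 collision_free_only = TRUE),
            class = "efficiency_report")
}

#' On-target recovery and mean target coverage
#'
#' On-target percent is the share of mapped, non-duplicate read pairs whose
#' midpoint falls in a target interval; mean coverage per target is aligned
#' bases over the interval divided by its length.
#'
#' @param aligned an `aligned_reads` table.
#' @param targets data.frame `ref`, `start`, `end` (0-based half-open),
#'   optional `name`.
#' @return list with `on_target_pct`, `per_target` (data.table `name`,
#'   `n_pairs`, `mean_coverage`), `mean_coverage` (average over targets).
#' @export
target_recovery <- function(aligned, targets) {
  f <- check_intervals(targets)
  if (nrow(f) == 0) stop_param("empty target set")
  p <- pair_view(aligned)[dup == FALSE]
  if (nrow(p) == 0) stop_param("no mapped read pairs")
  hits <- p[f, on = .(ref, mid >= start, mid < end),
            .(read_id, name = i.name), nomatch = NULL]
  on_target_pct <- 100 * uniqueN(hits$read_id) / nrow(p)

  bases <- expand_aligned_bases(aligned)
  cov <- f[, {
    nb <- bases[ref == .BY$ref & rpos >= start & rpos < end, .N]
    .(n_pairs = uniqueN(hits[name == .BY$name, read_id]),
      mean_coverage = nb / (end - start))
  }, by = .(ref, name, start, end)]
  list(on_target_pct = on_target_pct,
       per_target = cov[, .(name, n_pairs, mean_coverage)],
       mean_coverage = mean(cov$mean_coverage))
}

#' Allele burden at annotated heterozygous sites
#'
#' Per-site fraction of reads carrying each of the two annotated alleles,
#' among reads carrying either (other bases are tallied separately); target
#' means of the per-site fractions; an imbalance flag when the mean minor
#' fraction falls below `imbalance_threshold` (putative haplotype dropout).
#'
#' @param site_counts a `site_counts` table from deduplicated reads.
#' @param het_sites data.frame `ref`, `pos` (0-based), `allele_hap1`,
#'   `allele_hap2` (truth or benchmark annotation).
#' @param imbalance_threshold mean minor-allele fraction below which the
#'   target is flagged imbalanced (default 0.2).
#' @return object of class `burden_report`: list with `per_site`
#'   (data.table `ref`, `pos`, `frac_hap1`, `frac_hap2`, `other`, `depth`),
#'   `per_target` (data.table `ref`, `mean_frac_hap1`, `mean_frac_hap2`,
#'   `imbalanced`), `excluded_sites` (zero-depth sites).
#' @export
allele_burden <- function(site_counts, het_sites,
                          imbalance_threshold = 0.2) {
  hs <- as.data.table(het_sites)
  sc <- as.data.table(site_counts)
  m <- merge(hs, sc, by = c("ref", "pos"), all.x = TRUE)
  cnt_of <- function(dt, al) {
    v <- numeric(nrow(dt))
    for (b in DNA_BASES) v[al == b] <- dt[[b]][al == b]
    v
  }
  m[is.na(depth), depth := 0L]
  excluded <- m[depth == 0L, .(ref, pos)]
  m <- m[depth > 0L]
  n1 <- cnt_of(m, m$allele_hap1)
  n2 <- cnt_of(m, m$allele_hap2)
  per_site <- m[, .(ref, pos,
                    frac_hap1 = n1 / (n1 + n2),
                    frac_hap2 = n2 / (n1 + n2),
                    other = depth - n1 - n2, depth)]
  per_target <- per_site[, .(
    mean_frac_hap1 = mean(frac_hap1, na.rm = TRUE),
    mean_frac_hap2 = mean(frac_hap2, na.rm = TRUE)), by = ref]
  per_target[, imbalanced :=
      pmin(mean_frac_hap1, mean_frac_hap2) < imbalance_threshold]
  structure(list(per_site = per_site, per_target = per_target,
                 excluded_sites = excluded),
            class = "burden_report")
}
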
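# Scoring inferred phasing against a benchmark: genotyping recall,
# switch/flip error decomposition, phase-block accounting, de novo phased
# sites, phasing quality groups, and the sequencing-depth titration.

#' Decompose phasing disagreement into switch and flip errors
#'
#' Both vectors give, per phased het site in order, which haplotype carries
#' the site's first allele (0/1). The decomposition minimises
#' switches + flips over the two global orientations: a flip inverts one
#' site, a switch inverts all downstream sites. Scanning the maximal runs of
#' disagreement, an isolated single-site run is a flip and a longer run
#' costs one switch per run boundary (one if it touches the end of the
#' vector, two if interior). The result equals the brute-force minimum.
#'
#' @param truth_phase_vector,called_phase_vector integer vectors in `{0,1}`
#'   over the same ordered site set.
#' @return named integer vector `c(switches =, flips =)`.
#' @export
#' @examples
#' switch_flip_decompose(c(0, 0, 0, 0), c(0, 1, 0, 0))  # one flip
#' switch_flip_decompose(c(0, 0, 0, 0), c(0, 1, 1, 1))  # one switch
switch_flip_decompose <- function(truth_phase_vector, called_phase_vector) {
  t <- as.integer(truth_phase_vector); c2 <- as.integer(called_phase_vector)
  if (length(t) != length(c2)) stop_param("phase vectors differ in length")
  if (length(t) == 0) return(c(switches = 0L, flips = 0L))
  best <- NULL
  for (o in 0:1) {
    d <- as.integer(t != ((c2 + o) %% 2L))
    r <- rle(d)
    sw <- 0L; fl <- 0L
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    n <- length(d)
    for (k in seq_along(r$values)) {
      if (r$values[k] == 0L) next
      L <- r$lengths[k]
      nb <- (starts[k] > 1L) + (ends[k] < n)
      if (L == 1L) fl <- fl + 1L
      else if (nb == 0L) fl <- fl + 0L  # whole-vector run: orientation flip
      else sw <- sw + min(nb, L)
    }
    tot <- sw + fl
    if (is.null(best) || tot < best[["switches"]] + best[["flips"]] ||
        (tot == best[["switches"]] + best[["flips"]] &&
         sw < best[["switches"]]))
      best <- c(switches = sw, flips = fl)
  }
  best
}

# number of sites disagreeing with truth under the best global orientation
phase_mismatch_sites <- function(truth, called) {
  if (length(truth) == 0) return(0L)
  d0 <- sum(truth != called)
  min(d0, length(truth) - d0)
}

#' Construct a phasing evaluation report
#'
#' Collects the per-target counts of the phasing evaluation and derives the
#' accuracy percentages. `correct` defaults to `phased - incorrect_sites`,
#' where a flip contributes one incorrectly phased site and a switch all
#' sites downstream of it within the block. Accuracy is reported both over
#' annotated and over recalled sites (unphased recalled sites count against
#' both).
#'
#' @param target target label.
#' @param annotated benchmark-annotated het sites.
#' @param recalled annotated sites recalled as het.
#' @param phased recalled sites phased by the method.
#' @param flips,switches error counts from the decomposition.
#' @param incorrect_sites sites phased discordantly with the benchmark
#'   (default `flips`, i.e. one per flip).
#' @param n_blocks number of phase blocks (default 1 when any site phased).
#' @param de_novo sites phased by the method but unphased/absent in the
#'   benchmark; `de_novo_confirmed` those concordant across replicates.
#' @return object of class `eval_report`.
#' @export
eval_report <- function(target = "target", annotated, recalled, phased,
                        flips = 0L, switches = 0L,
                        incorrect_sites = flips,
                        n_blocks = as.integer(phased > 0),
                        de_novo = 0L, de_novo_confirmed = NA_integer_) {
  if (recalled > annotated) stop_param("recalled > annotated")
  if (phased > recalled) stop_param("phased > recalled")
  correct <- phased - incorrect_sites
  structure(list(
    target = target,
    annotated = as.integer(annotated),
    recalled = as.integer(recalled),
    missed = as.integer(annotated - recalled),
    phased = as.integer(phased),
    unphased = as.integer(recalled - phased),
    flips = as.integer(flips),
    switches = as.integer(switches),
    incorrect_sites = as.integer(incorrect_sites),
    correct = as.integer(correct),
    accuracy_annotated_pct = 100 * correct / annotated,
    accuracy_recalled_pct = 100 * correct / recalled,
    n_blocks = as.integer(n_blocks),
    single_block = n_blocks == 1L,
    de_novo = as.integer(de_novo),
    de_novo_confirmed = as.integer(de_novo_confirmed)
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> %s: %d/%d recalled, %d phased (%d correct, %.2f%% of annotated), %d flip(s), %d switch(es), %d block(s)\n",
    x$target, x$recalled, x$annotated, x$phased, x$correct,
    x$accuracy_annotated_pct, x$flips, x$switches, x$n_blocks))
  invisible(x)
}

#' Aggregate evaluation reports across targets
#'
#' Sums the counts and recomputes the pooled accuracy percentages
#' (sum of correctly phased sites over sum of denominators).
#'
#' @param reports list of `eval_report` objects.
#' @return an `eval_report` for the pooled counts (target "combined").
#' @export
aggregate_eval_reports <- function(reports) {
  g <- function(f) sum(vapply(reports, `[[`, numeric(1), f))
  dn_conf <- vapply(reports, `[[`, numeric(1), "de_novo_confirmed")
  eval_report(
    target = "combined",
    annotated = g("annotated"), recalled = g("recalled"),
    phased = g("phased"), flips = g("flips"), switches = g("switches"),
    incorrect_sites = g("incorrect_sites"),
    n_blocks = g("n_blocks"),
    de_novo = g("de_novo"),
    de_novo_confirmed = if (all(is.na(dn_conf))) NA_integer_
                        else sum(dn_conf, na.rm = TRUE)
  )
}

# phase table from VCF-style records (emit_phased_variants()/read_vcf()):
# per het site, which haplotype carries the first ALT-ordered allele
phase_table <- function(vcf) {
  v <- as.data.table(vcf)
  v[, het := grepl("^([0-9]+)[/|]([0-9]+)$", gt) &
      sub("^([0-9]+).*", "\\1", gt) != sub(".*[/|]([0-9]+)$", "\\1", gt)]
  v[, phased := grepl("|", gt, fixed = TRUE) & het]
  v[, `:=`(h1 = as.integer(sub("^([0-9]+).*", "\\1", gt)),
           h2 = as.integer(sub(".*[/|]([0-9]+)$", "\\1", gt)))]
  if (!"ps" %in% names(v)) v[, ps := NA_integer_]
  v[]
}

#' Compare inferred phasing with a benchmark
#'
#' Matches het sites by position and allele content, counts recall, missed
#' sites, phased/unphased sites, decomposes phasing disagreements into
#' switch and flip errors per inferred block (minimised over each block's
#' orientation), counts de novo phased sites (phased by the method, absent
#' or unphased in the benchmark) and, when replicate phasings are supplied,
#' confirms de novo sites that agree in at least two replicates.
#'
#' @param benchmark VCF-style records of the benchmark phasing (columns
#'   `chrom`, `pos`, `ref`, `alt`, `gt`, `ps`).
#' @param inferred VCF-style records of the inferred phasing.
#' @param replicate_set optional list of VCF-style records from replicate
#'   libraries (used only for de novo confirmation).
#' @param target label for the report.
#' @return an [eval_report()].
#' @export
compare_phasing <- function(benchmark, inferred, replicate_set = NULL,
                            target = "target") {
  b <- phase_table(benchmark)[het == TRUE]
  i <- phase_table(inferred)[het == TRUE]
  m <- merge(b[, .(chrom, pos, ref, alt, b_phased = phased,
                   b_h1 = h1, b_ps = ps)],
             i[, .(chrom, pos, ref, alt, i_phased = phased,
                   i_h1 = h1, i_ps = ps)],
             by = c("chrom", "pos"), suffixes = c("_b", "_i"))
  # a site is recalled only if the same allele pair was called
  same_alleles <- function(r1, a1, r2, a2) {
    s1 <- paste(pmin(r1, a1), pmax(r1, a1))
    s2 <- paste(pmin(r2, a2), pmax(r2, a2))
    s1 == s2
  }
  if (nrow(m)) {
    m <- m[same_alleles(ref_b, alt_b, ref_i, alt_i)]
    # harmonise allele coding: h1 allele index refers to each file's own
    # REF/ALT order; recode inferred h1 to the benchmark's coding when the
    # pair is (REF, first ALT) in both (guaranteed by same_alleles for
    # biallelic sites with matching REF)
    m[ref_b != ref_i, i_h1 := 1L - i_h1]
  }
  annotated <- nrow(b)
  recalled <- nrow(m)
  phased_dt <- m[b_phased == TRUE & i_phased == TRUE]
  phased <- m[, sum(i_phased)]
  flips <- 0L; switches <- 0L; incorrect <- 0L
  if (nrow(phased_dt)) {
    setorder(phased_dt, chrom, pos)
    for (blk in split(phased_dt, phased_dt$i_ps)) {
      sf <- switch_flip_decompose(blk$b_h1, blk$i_h1)
      flips <- flips + sf[["flips"]]
      switches <- switches + sf[["switches"]]
      incorrect <- incorrect + phase_mismatch_sites(blk$b_h1, blk$i_h1)
    }
  }
  # de novo: phased by the method, absent from or unphased in the benchmark
  dn <- i[phased == TRUE][!b[, .(chrom, pos)], on = c("chrom", "pos")]
  dn <- rbind(dn, merge(i[phased == TRUE], b[phased == FALSE, .(chrom, pos)],
                        by = c("chrom", "pos")), fill = TRUE)
  de_novo <- nrow(dn)
  de_novo_confirmed <- NA_integer_
  if (!is.null(replicate_set) && de_novo > 0) {
    conf <- 0L
    for (r in seq_len(nrow(dn))) {
      n_agree <- sum(vapply(replicate_set, function(rv) {
        rt <- phase_table(rv)
        hit <- rt[chrom == dn$chrom[r] & pos == dn$pos[r] & phased == TRUE]
        nrow(hit) > 0 && hit$h1[1] == dn$h1[r]
      }, logical(1)))
      if (n_agree >= 2L) conf <- conf + 1L
    }
    de_novo_confirmed <- conf
  }
  n_blocks <- if (phased > 0) uniqueN(m[i_phased == TRUE, i_ps]) else 0L
  eval_report(target = target, annotated = annotated, recalled = recalled,
              phased = phased, flips = flips, switches = switches,
              incorrect_sites = incorrect, n_blocks = n_blocks,
              de_novo = de_novo, de_novo_confirmed = de_novo_confirmed)
}

#' Classify a phasing result into a quality group
#'
#' Group 1: no genotyping or phasing errors and a single phase block.
#' Group 2: no genotyping errors, single block, exactly one flip or switch.
#' Group 3: missed-genotype sites, discontinuous blocks, or more than one
#' flip/switch error. Group 4: mostly unphased heterozygous sites.
#'
#' @param report an `eval_report`.
#' @param mostly_unphased_threshold unphased fraction (of annotated sites)
#'   above which the result is group 4 (default 0.5).
#' @return object of class `quality_group`: list with `group` (1-4) and the
#'   booleans that determined it.
#' @export
classify_quality_group <- function(report, mostly_unphased_threshold = 0.5) {
  unphased_frac <- if (report$annotated > 0)
    (report$annotated - report$phased) / report$annotated else 1
  err <- report$flips + report$switches
  mostly_unphased <- unphased_frac > mostly_unphased_threshold
  has_missed <- report$missed > 0
  multi_block <- report$n_blocks > 1
  group <- if (mostly_unphased) 4L
    else if (has_missed || multi_block || err > 1) 3L
    else if (err == 1) 2L
    else 1L
  structure(list(group = group, mostly_unphased = mostly_unphased,
                 has_missed_sites = has_missed, multi_block = multi_block,
                 n_flip_switch = as.integer(err),
                 unphased_fraction = unphased_frac),
            class = "quality_group")
}

#' @export
print.quality_group <- function(x, ...) {
  cat(sprintf("<quality_group> %d (errors: %d, missed: %s, multi-block: %s, unphased frac: %.2f)\n",
              x$group, x$n_flip_switch, x$has_missed_sites, x$multi_block,
              x$unphased_fraction))
  invisible(x)
}

#' Subsample read pairs
#'
#' Each pair is retained independently with probability `fraction`
#' (duplicate marking must be re-applied downstream).
#'
#' @param read_set a `read_pairs` or `aligned_reads` table.
#' @param fraction retention probability in (0, 1].
#' @param seed optional integer seed.
#' @return the table restricted to retained pairs.
#' @export
subsample_reads <- function(read_set, fraction, seed = NULL) {
  if (fraction <= 0 || fraction > 1) stop_param("fraction must be in (0, 1]")
  if (fraction == 1) return(read_set)
  if (!is.null(seed)) set.seed(seed)
  ids <- unique(read_set$read_id)
  keep <- ids[runif(length(ids)) < fraction]
  out <- as.data.table(read_set)[read_id %chin% keep]
  setattr(out, "class", class(read_set))
  setattr(out, "read_len", attr(read_set, "read_len"))
  out[]
}
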
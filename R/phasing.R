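# Barcode-linked phasing. Reads sharing a bead barcode derive (absent
# collisions) from one molecule, hence one haplotype: per-barcode allele
# observations over heterozygous sites form a fragment matrix, and phasing
# minimises the number of observations that must be corrected for every
# barcode row to fit one haplotype (the MEC objective). Sites are linked
# into phase blocks only where the evidence passes a log-odds prune
# threshold; thin or ambiguous linkage leaves sites unphased.

#' Phasing parameters
#'
#' @param max_link_distance maximum distance (bp) across which two sites may
#'   be directly linked (default 40000).
#' @param prune_threshold log-odds required on an edge for its sites to be
#'   co-phased (default 5; with the default error rate a single supporting
#'   barcode scores ~3.9, so at least two independent consistent rows are
#'   required).
#' @param error_rate assumed symmetric per-observation error rate used in
#'   the edge log-odds (default 0.02).
#' @param min_flip_margin minimum MEC increase a single-site flip must incur
#'   for the site to be reported as phased (default 1).
#' @param min_reads_per_site_per_barcode minimum read bases a barcode needs
#'   at a site to record an allele (default 1).
#' @return list of class `phasing_params`.
#' @export
phasing_params <- function(max_link_distance = 40000L, prune_threshold = 5,
                           error_rate = 0.02, min_flip_margin = 1,
                           min_reads_per_site_per_barcode = 1L) {
  if (max_link_distance <= 0) stop_param("max_link_distance must be > 0")
  structure(list(max_link_distance = as.integer(max_link_distance),
                 prune_threshold = prune_threshold,
                 error_rate = error_rate,
                 min_flip_margin = min_flip_margin,
                 min_reads_per_site_per_barcode =
                   as.integer(min_reads_per_site_per_barcode)),
            class = "phasing_params")
}

#' Build the per-barcode fragment matrix over heterozygous sites
#'
#' For each (corrected) barcode, the allele at each het site it covers is
#' taken by majority over that barcode's non-duplicate read bases; ties and
#' bases matching neither call allele are dropped. Alleles are coded 0 for
#' the call's first allele and 1 for the second. Only heterozygous calls
#' enter the matrix.
#'
#' @param aligned an `aligned_reads` table (deduplicated, corrected
#'   barcodes).
#' @param calls a `genotype_calls` table.
#' @param params a [phasing_params()].
#' @return object of class `fragment_matrix`: list with `sites` (data.table
#'   `site`, `ref`, `pos`, `a1`, `a2`) and `rows` (data.table `barcode`,
#'   `site`, `allele`, `n_reads`). Empty when there are no het calls.
#' @export
build_fragment_matrix <- function(aligned, calls, params = phasing_params()) {
  het <- as.data.table(calls)[genotype == "het"]
  setorder(het, ref, pos)
  sites <- het[, .(site = seq_len(.N), ref, pos, a1, a2)]
  rows <- data.table(barcode = character(0), site = integer(0),
                     allele = integer(0), n_reads = integer(0))
  if (nrow(sites)) {
    bases <- expand_aligned_bases(aligned,
                                  keep_pos = sites[, .(ref, rpos = pos)])
    if (nrow(bases)) {
      bases <- merge(bases, sites, by.x = c("ref", "rpos"),
                     by.y = c("ref", "pos"))
      bases <- bases[base == a1 | base == a2]
      bases[, allele := as.integer(base == a2)]
      tal <- bases[, .(n0 = sum(allele == 0L), n1 = sum(allele == 1L)),
                   by = .(barcode, site)]
      tal <- tal[pmax(n0, n1) >= params$min_reads_per_site_per_barcode]
      tal <- tal[n0 != n1]  # conflicting ties dropped
      rows <- tal[, .(barcode, site, allele = as.integer(n1 > n0),
                      n_reads = n0 + n1)]
      setorder(rows, barcode, site)
    }
  }
  structure(list(sites = sites, rows = rows, params = params),
            class = "fragment_matrix")
}

#' @export
print.fragment_matrix <- function(x, ...) {
  cat(sprintf("<fragment_matrix> %d sites, %d barcode rows\n",
              nrow(x$sites), length(unique(x$rows$barcode))))
  invisible(x)
}

#' Minimum-error-correction score of a haplotype assignment
#'
#' Sum over barcode rows of the smaller number of mismatches against the
#' assignment or its complement, restricted to phased (non-`NA`) sites.
#'
#' @param matrix a `fragment_matrix`.
#' @param assignment integer vector (0/1/`NA`) over the matrix's sites:
#'   the allele carried by haplotype 1 at each site.
#' @return integer MEC score.
#' @export
mec_score <- function(matrix, assignment) {
  rows <- matrix$rows[site %in% which(!is.na(assignment))]
  if (nrow(rows) == 0) return(0L)
  rows[, mm := as.integer(allele != assignment[site])]
  per_row <- rows[, .(m1 = sum(mm), n = .N), by = barcode]
  sum(pmin(per_row$m1, per_row$n - per_row$m1))
}

# observations of one block as a compact list
block_obs <- function(rows, block_sites) {
  obs <- rows[site %in% block_sites]
  obs[, ls := match(site, block_sites)]
  split(obs[, .(ls, allele)], obs$barcode)
}

block_mec <- function(obs_list, a) {
  tot <- 0L
  for (o in obs_list) {
    m <- sum(o$allele != a[o$ls])
    tot <- tot + min(m, nrow(o) - m)
  }
  tot
}

# exhaustive MEC optimum over a block (first site pinned to 0)
solve_block_exhaustive <- function(obs_list, m) {
  best_a <- rep(0L, m); best <- Inf
  for (mask in 0:(2^(m - 1) - 1)) {
    a <- c(0L, as.integer(intToBits(mask)[seq_len(m - 1)]))
    v <- block_mec(obs_list, a)
    if (v < best) { best <- v; best_a <- a }
  }
  list(assignment = best_a, mec = best)
}

# greedy: maximum spanning tree over |w| then single-site flips while MEC
# decreases (deterministic order)
solve_block_greedy <- function(obs_list, m, edges) {
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  rel <- rep(NA_integer_, m)  # relative phase to component root (0 same)
  setorder(edges, -aw, i, j)
  adj <- vector("list", m)
  for (e in seq_len(nrow(edges))) {
    i <- edges$i[e]; j <- edges$j[e]
    ri <- find(i); rj <- find(j)
    if (ri != rj) {
      parent[rj] <- ri
      adj[[i]] <- c(adj[[i]], list(c(j, edges$flip[e])))
      adj[[j]] <- c(adj[[j]], list(c(i, edges$flip[e])))
    }
  }
  a <- rep(NA_integer_, m)
  for (s in seq_len(m)) {
    if (!is.na(a[s])) next
    a[s] <- 0L
    queue <- s
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (ed in adj[[u]]) {
        v <- ed[1]
        if (is.na(a[v])) {
          a[v] <- if (ed[2] == 1L) 1L - a[u] else a[u]
          queue <- c(queue, v)
        }
      }
    }
  }
  cur <- block_mec(obs_list, a)
  repeat {
    improved <- FALSE
    for (s in seq_len(m)) {
      a2 <- a; a2[s] <- 1L - a2[s]
      v <- block_mec(obs_list, a2)
      if (v < cur) { a <- a2; cur <- v; improved <- TRUE }
    }
    if (!improved) break
  }
  list(assignment = a, mec = cur)
}

#' Phase heterozygous sites into blocks by MEC optimisation
#'
#' Builds a site graph whose edge weights are the log-odds that two sites
#' are co-phased given the counts of agreeing and disagreeing barcode rows
#' under a symmetric error rate; site pairs farther apart than
#' `max_link_distance` (or on different references) contribute no edge.
#' Phase blocks are the connected components of edges with
#' `|weight| >= prune_threshold`. Within each block the haplotype assignment
#' minimises MEC: exhaustively for blocks of up to 10 sites (guaranteed
#' optimum), else greedy maximum-spanning-tree construction followed by
#' single-site flips while MEC decreases. Sites whose flip changes the block
#' MEC by less than `min_flip_margin` are reported unphased, as are sites in
#' no block. Each block is canonically oriented (its leftmost phased site
#' carries allele 0 on haplotype 1), so output is invariant under global
#' haplotype relabeling.
#'
#' @param matrix a `fragment_matrix`.
#' @param params a [phasing_params()] (default taken from the matrix).
#' @return object of class `phase_result`: list with `sites`, `assignment`
#'   (0/1/`NA` per site: haplotype 1 allele), `block_id` (1-based leftmost
#'   phased position of the site's block, `NA` if unphased), `blocks`
#'   (data.table `block_id`, `ref`, `n_sites`), and `mec`, the sum over
#'   blocks of each block's MEC restricted to its own phased sites
#'   (relative phase across blocks is undefined, so cross-block rows do not
#'   contribute).
#' @export
phase_blocks <- function(matrix, params = NULL) {
  params <- params %||% matrix$params
  sites <- matrix$sites
  n <- nrow(sites)
  assignment <- rep(NA_integer_, n)
  block_of <- rep(NA_integer_, n)

  if (n > 0 && nrow(matrix$rows) > 0) {
    rows <- matrix$rows
    pr <- merge(rows, rows, by = "barcode", allow.cartesian = TRUE)
    pr <- pr[site.x < site.y]
    if (nrow(pr)) {
      pr <- merge(pr, sites[, .(site.x = site, ref_x = ref, pos_x = pos)],
                  by = "site.x")
      pr <- merge(pr, sites[, .(site.y = site, ref_y = ref, pos_y = pos)],
                  by = "site.y")
      pr <- pr[ref_x == ref_y & pos_y - pos_x <= params$max_link_distance]
    }
    if (nrow(pr)) {
      ew <- pr[, .(n_agree = sum(allele.x == allele.y),
                   n_dis = sum(allele.x != allele.y)),
               by = .(i = site.x, j = site.y)]
      lo <- log((1 - params$error_rate) / params$error_rate)
      ew[, w := (n_agree - n_dis) * lo]
      ew[, aw := abs(w)]
      ew[, flip := as.integer(w < 0)]
      strong <- ew[aw >= params$prune_threshold]

      if (nrow(strong)) {
        # connected components over strong edges (label propagation)
        comp <- seq_len(n)
        repeat {
          changed <- FALSE
          for (e in seq_len(nrow(strong))) {
            i2 <- strong$i[e]; j2 <- strong$j[e]
            mn <- min(comp[i2], comp[j2])
            if (comp[i2] != mn || comp[j2] != mn) {
              comp[i2] <- mn; comp[j2] <- mn; changed <- TRUE
            }
          }
          if (!changed) break
        }
        for (cid in unique(comp[c(strong$i, strong$j)])) {
          members <- which(comp == cid)
          if (length(members) < 2) next
          m <- length(members)
          obs <- block_obs(rows, members)
          if (m <= 10L) {
            sol <- solve_block_exhaustive(obs, m)
          } else {
            bed <- strong[i %in% members & j %in% members]
            bed2 <- copy(bed)[, `:=`(i = match(i, members), j = match(j, members))]
            sol <- solve_block_greedy(obs, m, bed2)
          }
          # ambiguity: a flip must cost at least min_flip_margin
          keep <- rep(TRUE, m)
          for (s in seq_len(m)) {
            a2 <- sol$assignment; a2[s] <- 1L - a2[s]
            if (block_mec(obs, a2) - sol$mec < params$min_flip_margin)
              keep[s] <- FALSE
          }
          if (sum(keep) < 2) next  # nothing left to phase relative to
          ph <- members[keep]
          a <- sol$assignment[keep]
          if (a[1] == 1L) a <- 1L - a  # canonical orientation
          assignment[ph] <- a
          block_of[ph] <- sites$pos[ph[1]] + 1L
        }
      }
    }
  }

  blocks <- data.table(block_id = integer(0), ref = character(0),
                       n_sites = integer(0))
  if (any(!is.na(block_of))) {
    bdt <- data.table(block_id = block_of, ref = sites$ref)[!is.na(block_id)]
    blocks <- bdt[, .(n_sites = .N), by = .(block_id, ref)]
    setorder(blocks, ref, block_id)
  }
  # MEC is accounted per block: each block's score uses only observations
  # at its own phased sites (relative phase across blocks is undefined)
  mec <- 0L
  for (b in unique(block_of[!is.na(block_of)])) {
    mask <- assignment
    mask[is.na(block_of) | block_of != b] <- NA_integer_
    mec <- mec + mec_score(matrix, mask)
  }
  structure(list(sites = sites, assignment = assignment,
                 block_id = block_of, blocks = blocks,
                 mec = mec),
            class = "phase_result")
}

#' @export
print.phase_result <- function(x, ...) {
  cat(sprintf("<phase_result> %d/%d sites phased in %d block(s); MEC = %d\n",
              sum(!is.na(x$assignment)), nrow(x$sites), nrow(x$blocks), x$mec))
  invisible(x)
}

#' Emit phased VCF-style records from calls and a phase result
#'
#' Phased het sites get an ordered genotype (`i|j`, haplotype 1 first) and a
#' phase-set (`PS`) value equal to their block id; unphased het sites get an
#' unordered genotype; hom-alt sites `1/1`.
#'
#' @param calls a `genotype_calls` table.
#' @param phase_result a `phase_result` over the het subset of the calls.
#' @return data.table of VCF-style records: `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `gt`, `ps` (`NA` when unphased), `phased`.
#' @export
emit_phased_variants <- function(calls, phase_result) {
  cl <- as.data.table(calls)
  ph <- data.table(chrom = phase_result$sites$ref,
                   pos0 = phase_result$sites$pos,
                   hap1_allele = phase_result$assignment,
                   ps = phase_result$block_id)
  het_called <- cl[genotype == "het", .(ref, pos)]
  if (nrow(ph[!is.na(hap1_allele)]) &&
      !all(ph[!is.na(hap1_allele), paste(chrom, pos0)] %in%
           het_called[, paste(ref, pos)]))
    stop_param("phased site without a genotype call")
  out <- merge(cl, ph, by.x = c("ref", "pos"), by.y = c("chrom", "pos0"),
               all.x = TRUE)
  recs <- out[, {
    alts <- unique(c(a1, a2))
    alts <- alts[!is.na(alts) & alts != ref_base]
    idx <- function(b) ifelse(b == ref_base, 0L, match(b, alts))
    if (genotype == "hom_alt") {
      gt <- "1/1"
    } else if (!is.na(hap1_allele)) {
      h1 <- if (hap1_allele == 0L) a1 else a2
      h2 <- if (hap1_allele == 0L) a2 else a1
      gt <- paste0(idx(h1), "|", idx(h2))
    } else {
      gt <- paste(sort(c(idx(a1), idx(a2))), collapse = "/")
    }
    .(ref_base = ref_base, alt = paste(alts, collapse = ","),
      gt = gt, ps = ps, phased = grepl("|", gt, fixed = TRUE))
  }, by = .(chrom = ref, pos = pos + 1L)]
  setnames(recs, "ref_base", "ref")
  setorder(recs, chrom, pos)
  recs[]
}
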
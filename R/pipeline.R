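# End-to-end commands: configuration, simulation, the processing chain
# (trim -> barcode correction -> map -> dedup -> genotype -> phase) and the
# coverage titration experiment. All randomness flows from explicit seeds.

#' Pipeline configuration
#'
#' Nested configuration for simulation, processing and evaluation. The
#' processing defaults are the study conditions: minimum adapter overlap 5,
#' allele-frequency cutoff 0.1, phasing link distance 40 kb, and the
#' subsampling ladder 50%, 25%, 12.5%, 6.25%, 3.125%, 1.56%, 0.78%.
#'
#' @param seed integer seed; required, drives all randomness.
#' @param loci list of locus specs, each a list with `length_bp`,
#'   `mean_het_spacing_bp` and/or `het_positions`, and optional `locus_id`.
#' @param target_mass_pg,background_mass_pg,filling_mass_pg,hap_bias,dropout_fraction,dropout_hap
#'   sample composition (see [sample_composition()]).
#' @param n_beads,bead_subsample_fraction bead loading (see
#'   [assign_beads()]).
#' @param reads_per_kb,read_len,sub_error_rate,barcode_error_rate,pcr_dup_rate
#'   read generation (see [generate_reads()]).
#' @param min_overlap adapter trimming minimum overlap (default 5).
#' @param af_cutoff,min_depth genotyping (defaults 0.1 and 10).
#' @param k mapper seed length (default 21).
#' @param max_link_distance,prune_threshold,error_rate phasing (defaults
#'   40000, 5, 0.02).
#' @param fraction_ladder titration subsampling fractions, descending.
#' @param mostly_unphased_threshold quality-group 4 threshold (default 0.5).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            loci = list(list(length_bp = 13000L,
                                             mean_het_spacing_bp = 1500)),
                            target_mass_pg = 2e-5,
                            background_mass_pg = 0,
                            filling_mass_pg = 0,
                            hap_bias = 0.5,
                            dropout_fraction = 0,
                            dropout_hap = 2L,
                            n_beads = 20000L,
                            bead_subsample_fraction = 1,
                            reads_per_kb = 3.2,
                            read_len = 145L,
                            sub_error_rate = 0,
                            barcode_error_rate = 0,
                            pcr_dup_rate = 0,
                            min_overlap = 5L,
                            af_cutoff = 0.1,
                            min_depth = 10L,
                            k = 21L,
                            max_link_distance = 40000L,
                            prune_threshold = 5,
                            error_rate = 0.02,
                            fraction_ladder = c(0.5, 0.25, 0.125, 0.0625,
                                                0.03125, 0.0156, 0.0078),
                            mostly_unphased_threshold = 0.5) {
  if (missing(seed) || is.null(seed)) stop_param("an explicit seed is required")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Simulate a targeted linked-read experiment in memory
#'
#' Builds the loci, molecule pool, bead assignment and read set described by
#' the configuration, all seeded from `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @return list with `loci`, `composition`, `pool`, `assignment`, `reads`,
#'   `refs` (mapping references), `targets` (BED-style data.table) and
#'   `truth_vcf`.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  loci <- lapply(seq_along(config$loci), function(i) {
    sp <- config$loci[[i]]
    make_diploid_locus(
      length_bp = sp$length_bp,
      mean_het_spacing_bp = sp$mean_het_spacing_bp %||% 1500,
      het_positions = sp$het_positions,
      locus_id = sp$locus_id %||% paste0("locus", i))
  })
  comp <- sample_composition(
    target_mass_pg = config$target_mass_pg,
    background_mass_pg = config$background_mass_pg,
    filling_mass_pg = config$filling_mass_pg,
    hap_bias = config$hap_bias,
    dropout_fraction = config$dropout_fraction,
    dropout_hap = config$dropout_hap)
  pool <- build_fragment_pool(loci, comp)
  assignment <- assign_beads(pool, config$n_beads,
                             config$bead_subsample_fraction)
  reads <- generate_reads(assignment, pool,
                          reads_per_kb = config$reads_per_kb,
                          read_len = config$read_len,
                          sub_error_rate = config$sub_error_rate,
                          barcode_error_rate = config$barcode_error_rate,
                          pcr_dup_rate = config$pcr_dup_rate)
  seqs <- attr(pool, "seqs")
  hap_names <- unlist(lapply(loci, function(l)
    paste0(l$locus_id, c(".hap1", ".hap2"))))
  refs <- c(setNames(vapply(loci, `[[`, character(1), "ref_seq"),
                     vapply(loci, `[[`, character(1), "locus_id")),
            seqs[setdiff(names(seqs), c(hap_names, "background"))])
  targets <- data.table(
    ref = vapply(loci, `[[`, character(1), "locus_id"),
    start = 0L,
    end = vapply(loci, `[[`, integer(1), "length_bp"),
    name = vapply(loci, `[[`, character(1), "locus_id"))
  truth_vcf <- rbindlist(lapply(loci, truth_vcf_records))
  list(loci = loci, composition = comp, pool = pool,
       assignment = assignment, reads = reads, refs = refs,
       targets = targets, truth_vcf = truth_vcf)
}

#' Simulate an experiment and write its truth set to disk
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return named character vector of file paths (see [write_truth_set()]).
#' @export
run_simulation <- function(config, out_dir) {
  sim <- simulate_experiment(config)
  paths <- write_truth_set(sim$loci, sim$pool, sim$assignment, sim$reads,
                           out_dir)
  write_config(config, file.path(out_dir, "config.yaml"))
  c(paths, config = file.path(out_dir, "config.yaml"))
}

#' Run the processing chain on a read set in memory
#'
#' Stages in order: adapter trimming, bead-barcode correction, k-mer
#' mapping, within-barcode duplicate marking, pileup genotyping, fragment
#' matrix construction and MEC phasing. Returns all intermediates plus a
#' per-stage log of counts.
#'
#' @param reads a `read_pairs` table (simulated or from
#'   [read_fastq_trio()]).
#' @param refs named character vector of mapping references.
#' @param targets BED-style data.table of target intervals.
#' @param config a [pipeline_config()].
#' @param adapters adapter set for trimming (default [default_adapters()]).
#' @return list of class `pipeline_result` with `aligned`, `barcode_table`,
#'   `site_counts`, `calls`, `matrix`, `phase`, `phased_vcf`, `recovery`,
#'   `log`.
#' @export
run_pipeline_reads <- function(reads, refs, targets, config,
                               adapters = default_adapters()) {
  log <- list(n_read_pairs_in = nrow(reads))
  reads <- as.data.table(reads)
  if (!is.null(adapters)) {
    reads <- copy(reads)
    reads[, r1_seq := trim_adapters(r1_seq, adapters$r1, config$min_overlap)]
    reads[, r2_seq := trim_adapters(r2_seq, adapters$r2, config$min_overlap)]
  }
  bc_counts <- table(reads$observed_barcode)
  btab <- correct_barcodes(setNames(as.integer(bc_counts), names(bc_counts)))
  log$n_barcodes_observed <- nrow(btab)
  log$n_barcodes_corrected <- sum(btab$observed != btab$corrected)
  reads[, observed_barcode := apply_barcode_correction(btab, observed_barcode)]

  aligned <- map_reads(reads, refs, k = config$k)
  log$n_mates_mapped <- sum(aligned$mapped)
  aligned <- mark_duplicates(aligned)
  log$n_pairs_duplicate <- length(unique(aligned[dup == TRUE, read_id]))

  counts <- pileup_counts(aligned)
  calls <- call_genotypes(counts, refs, af_cutoff = config$af_cutoff,
                          min_depth = config$min_depth)
  log$n_sites_called <- nrow(calls)
  log$n_sites_het <- sum(calls$genotype == "het")

  params <- phasing_params(max_link_distance = config$max_link_distance,
                           prune_threshold = config$prune_threshold,
                           error_rate = config$error_rate)
  fm <- build_fragment_matrix(aligned, calls, params)
  ph <- phase_blocks(fm, params)
  log$n_sites_phased <- sum(!is.na(ph$assignment))
  log$n_blocks <- nrow(ph$blocks)
  phased_vcf <- emit_phased_variants(calls, ph)

  recovery <- tryCatch(target_recovery(aligned, targets),
                       error = function(e) NULL)
  structure(list(aligned = aligned, barcode_table = btab,
                 site_counts = counts, calls = calls, matrix = fm,
                 phase = ph, phased_vcf = phased_vcf,
                 recovery = recovery, log = log),
            class = "pipeline_result")
}

#' Run the processing chain from files
#'
#' @param r1,r2,i1 FASTQ trio paths.
#' @param reference FASTA path of mapping references.
#' @param targets_bed BED path of target intervals.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for the phased VCF and SAM-like
#'   alignment export.
#' @return a `pipeline_result` (see [run_pipeline_reads()]).
#' @export
run_pipeline <- function(r1, r2, i1, reference, targets_bed, config,
                         out_dir = NULL) {
  reads <- read_fastq_trio(r1, r2, i1)
  refs <- read_fasta(reference)
  targets <- read_bed(targets_bed)
  res <- run_pipeline_reads(reads, refs, targets, config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_vcf(res$phased_vcf, file.path(out_dir, "phased.vcf"),
              contigs = setNames(nchar(refs), names(refs)))
    write_sam_like(res$aligned, file.path(out_dir, "aligned.tsv"))
    yaml::write_yaml(res$log, file.path(out_dir, "pipeline_log.yaml"))
  }
  res
}

# re-run genotyping + phasing on a subsampled alignment (mapping and
# barcode correction commute with pair subsampling, so they are done once)
call_and_phase <- function(aligned, refs, config) {
  aligned <- mark_duplicates(aligned)
  counts <- pileup_counts(aligned)
  calls <- call_genotypes(counts, refs, af_cutoff = config$af_cutoff,
                          min_depth = config$min_depth)
  params <- phasing_params(max_link_distance = config$max_link_distance,
                           prune_threshold = config$prune_threshold,
                           error_rate = config$error_rate)
  fm <- build_fragment_matrix(aligned, calls, params)
  ph <- phase_blocks(fm, params)
  list(aligned = aligned, counts = counts, calls = calls,
       phase = ph, phased_vcf = emit_phased_variants(calls, ph))
}

#' Coverage titration with phasing quality groups
#'
#' Subsamples an aligned read set down a fraction ladder, re-runs duplicate
#' marking, genotyping and phasing at every fraction, scores each result
#' against the truth phasing and assigns the phasing quality group.
#'
#' @param aligned an `aligned_reads` table at full depth (duplicates
#'   unmarked or marked; marking is re-applied).
#' @param refs named character vector of mapping references.
#' @param truth_vcf truth phased records (e.g. from [simulate_experiment()]).
#' @param targets BED-style target intervals.
#' @param config a [pipeline_config()] (supplies the fraction ladder).
#' @param seeds integer vector of subsampling seeds.
#' @return data.table with one row per (seed, fraction): post-dedup mean
#'   coverage, recall/phasing counts and the quality `group`.
#' @export
coverage_titration <- function(aligned, refs, truth_vcf, targets, config,
                               seeds = 1:10) {
  ladder <- sort(config$fraction_ladder, decreasing = TRUE)
  out <- list()
  for (sd in seeds) {
    for (fr in ladder) {
      sub <- subsample_reads(aligned, fr, seed = sd * 10000L + round(fr * 1e4))
      row <- tryCatch({
        cp <- call_and_phase(sub, refs, config)
        cov <- tryCatch(target_recovery(cp$aligned, targets)$mean_coverage,
                        error = function(e) 0)
        rep_ <- compare_phasing(truth_vcf, cp$phased_vcf)
        qg <- classify_quality_group(rep_, config$mostly_unphased_threshold)
        data.table(seed = sd, fraction = fr, mean_coverage = cov,
                   annotated = rep_$annotated, recalled = rep_$recalled,
                   missed = rep_$missed, phased = rep_$phased,
                   flips = rep_$flips, switches = rep_$switches,
                   n_blocks = rep_$n_blocks, group = qg$group,
                   note = "")
      }, error = function(e) {
        data.table(seed = sd, fraction = fr, mean_coverage = 0,
                   annotated = NA_integer_, recalled = NA_integer_,
                   missed = NA_integer_, phased = NA_integer_,
                   flips = NA_integer_, switches = NA_integer_,
                   n_blocks = NA_integer_, group = 4L,
                   note = paste("failure:", conditionMessage(e)))
      })
      out[[length(out) + 1L]] <- row
    }
  }
  rbindlist(out)
}
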
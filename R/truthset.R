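# Truth-set serialisation: everything needed to re-run the processing chain
# from files and score it against simulation truth.

#' Write the complete truth set of a simulated experiment
#'
#' Emits the mapping reference (locus references plus any filling-fragment
#' references), the target BED, the truth phased VCF (haplotype 1 first,
#' phase-set tag spanning each locus), the bead-to-molecule table, the
#' FASTQ trio (R1/R2/I1 with shared read ids) and a YAML manifest.
#'
#' @param loci list of `diploid_locus` objects.
#' @param pool the `fragment_pool`.
#' @param assignment the `bead_assignment`.
#' @param reads the `read_pairs` table.
#' @param out_dir output directory (created if missing).
#' @return named character vector of file paths.
#' @export
write_truth_set <- function(loci, pool, assignment, reads, out_dir) {
  if (inherits(loci, "diploid_locus")) loci <- list(loci)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)

  seqs <- attr(pool, "seqs")
  ref_names <- setdiff(names(seqs),
                       c("background",
                         unlist(lapply(loci, function(l)
                           paste0(l$locus_id, c(".hap1", ".hap2"))))))
  refs <- c(setNames(vapply(loci, `[[`, character(1), "ref_seq"),
                     vapply(loci, `[[`, character(1), "locus_id")),
            seqs[ref_names])
  write_fasta(refs, p("reference.fasta"))

  targets <- data.table(
    ref = vapply(loci, `[[`, character(1), "locus_id"),
    start = 0L,
    end = vapply(loci, `[[`, integer(1), "length_bp"))
  targets[, name := ref]
  write_bed(targets, p("targets.bed"))

  truth <- rbindlist(lapply(loci, function(l) truth_vcf_records(l)))
  write_vcf(truth, p("truth.vcf"), sample = "TRUTH",
            contigs = setNames(nchar(refs), names(refs)))

  bead_tab <- merge(assignment$assignment, assignment$beads, by = "bead_id")
  write.table(bead_tab[, .(molecule_id, bead_id, barcode, retained)],
              p("beads.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  write_fastq_trio(reads, p("R1.fastq.gz"), p("R2.fastq.gz"),
                   p("I1.fastq.gz"))

  manifest <- list(
    format_version = "1",
    package = "linkphase",
    package_version = as.character(utils::packageVersion("linkphase")),
    n_loci = length(loci),
    n_molecules = nrow(pool),
    n_beads = assignment$n_beads,
    lambda = assignment$lambda,
    n_read_pairs = nrow(reads),
    files = list(reference = "reference.fasta", targets = "targets.bed",
                 truth_vcf = "truth.vcf", beads = "beads.tsv",
                 r1 = "R1.fastq.gz", r2 = "R2.fastq.gz", i1 = "I1.fastq.gz"))
  yaml::write_yaml(manifest, p("manifest.yaml"))

  c(reference = p("reference.fasta"), targets = p("targets.bed"),
    truth_vcf = p("truth.vcf"), beads = p("beads.tsv"),
    r1 = p("R1.fastq.gz"), r2 = p("R2.fastq.gz"), i1 = p("I1.fastq.gz"),
    manifest = p("manifest.yaml"))
}

#' Truth VCF-style records of a diploid locus
#'
#' @param locus a `diploid_locus`.
#' @return data.table of VCF-style records (`gt` = "hap1|hap2" against
#'   REF/ALT, `ps` = first het position, 1-based).
#' @export
truth_vcf_records <- function(locus) {
  h <- locus$het_sites
  if (nrow(h) == 0)
    return(data.table(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      gt = character(0), ps = integer(0),
                      phased = logical(0)))
  ref_base <- substring(locus$ref_seq, h$pos + 1L, h$pos + 1L)
  alt <- ifelse(h$allele_hap1 == ref_base, h$allele_hap2, h$allele_hap1)
  g1 <- ifelse(h$allele_hap1 == ref_base, 0L, 1L)
  g2 <- ifelse(h$allele_hap2 == ref_base, 0L, 1L)
  data.table(chrom = locus$locus_id, pos = h$pos + 1L, ref = ref_base,
             alt = alt, gt = paste0(g1, "|", g2),
             ps = h$pos[1] + 1L, phased = TRUE)
}

#' Read a truth set back from disk
#'
#' @param dir directory written by [write_truth_set()].
#' @return list with `refs`, `targets`, `truth_vcf`, `beads`, `reads`,
#'   `manifest`.
#' @export
read_truth_set <- function(dir) {
  p <- function(f) file.path(dir, f)
  list(refs = read_fasta(p("reference.fasta")),
       targets = read_bed(p("targets.bed")),
       truth_vcf = read_vcf(p("truth.vcf")),
       beads = as.data.table(read.delim(p("beads.tsv"))),
       reads = read_fastq_trio(p("R1.fastq.gz"), p("R2.fastq.gz"),
                               p("I1.fastq.gz")),
       manifest = yaml::read_yaml(p("manifest.yaml")))
}
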
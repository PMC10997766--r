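# Format I/O. Conventions: BED is 0-based half-open; VCF positions are
# 1-based with phased genotypes "0|1" and a PS phase-set tag; the SAM-like
# flat layer is tab-separated with documented columns and carries the bead
# barcode as a BX tag; FASTQ trios share read ids across R1/R2/I1.

#' Write a FASTQ trio (R1, R2, I1)
#'
#' @param reads a `read_pairs` table.
#' @param r1_path,r2_path,i1_path output paths (".gz" suffix gzips).
#' @return invisibly, the three paths.
#' @export
write_fastq_trio <- function(reads, r1_path, r2_path, i1_path) {
  wr <- function(path, seqs, quals) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    writeLines(paste0("@", reads$read_id, "\n", seqs, "\n+\n", quals), con)
  }
  wr(r1_path, reads$r1_seq, reads$q1)
  wr(r2_path, reads$r2_seq, reads$q2)
  wr(i1_path, reads$observed_barcode,
     substring(reads$q1, 1L, nchar(reads$observed_barcode)))
  invisible(c(r1_path, r2_path, i1_path))
}

#' Read a FASTQ trio back into a read-pair table
#'
#' @param r1_path,r2_path,i1_path FASTQ paths (gzipped or plain).
#' @return data.table with `read_id`, `r1_seq`, `r2_seq`, `q1`, `q2`,
#'   `observed_barcode` (ids must match across the trio).
#' @export
read_fastq_trio <- function(r1_path, r2_path, i1_path) {
  rd <- function(p) {
    x <- Biostrings::readDNAStringSet(p, format = "fastq", with.qualities = TRUE)
    data.table(read_id = sub("\\s.*$", "", names(x)),
               seq = as.character(x),
               qual = as.character(S4Vectors::mcols(x)$qualities))
  }
  r1 <- rd(r1_path); r2 <- rd(r2_path); i1 <- rd(i1_path)
  if (!identical(r1$read_id, r2$read_id) ||
      !identical(r1$read_id, i1$read_id))
    stop_param("read ids differ across the FASTQ trio")
  out <- data.table(read_id = r1$read_id, r1_seq = r1$seq, r2_seq = r2$seq,
                    q1 = r1$qual, q2 = r2$qual, observed_barcode = i1$seq)
  setattr(out, "read_len", nchar(out$r1_seq[1]))
  setattr(out, "class", c("read_pairs", class(out)))
  out[]
}

#' Write reference sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA into a named character vector
#' @param path FASTA path.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write target intervals to BED (0-based half-open)
#' @param targets data.frame with `ref`, `start`, `end`, optional `name`.
#' @param path output path.
#' @export
write_bed <- function(targets, path) {
  t <- as.data.table(targets)
  gr <- GenomicRanges::GRanges(
    t$ref, IRanges::IRanges(start = t$start + 1L, end = t$end),
    name = if ("name" %in% names(t)) t$name else t$ref)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED file into 0-based half-open intervals
#' @param path BED path.
#' @return data.table with `ref`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.table(ref = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) gr$name
                    else as.character(GenomicRanges::seqnames(gr)))
}

#' Write VCF-style phased records to a VCF v4.2 file
#'
#' @param records data.table with `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `gt`, optional `ps`.
#' @param path output path.
#' @param sample sample name (default "SAMPLE").
#' @param contigs optional named integer vector of contig lengths for the
#'   header.
#' @export
write_vcf <- function(records, path, sample = "SAMPLE", contigs = NULL) {
  r <- as.data.table(records)
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=linkphase-%s",
            as.character(utils::packageVersion("linkphase"))),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=PS,Number=1,Type=Integer,Description="Phase set">')
  if (!is.null(contigs))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                          as.integer(contigs)))
  hdr <- c(hdr, paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                       sample))
  has_ps <- "ps" %in% names(r) && any(!is.na(r$ps))
  if (nrow(r)) {
    fmt <- if (has_ps) ifelse(is.na(r$ps), "GT", "GT:PS") else "GT"
    val <- if (has_ps) ifelse(is.na(r$ps), r$gt, paste0(r$gt, ":", r$ps)) else r$gt
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\t%s\t%s",
                    r$chrom, as.integer(r$pos), r$ref,
                    ifelse(r$alt == "" | is.na(r$alt), ".", r$alt), fmt, val)
  } else body <- character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF into VCF-style records
#'
#' @param path VCF path.
#' @return data.table with `chrom`, `pos`, `ref`, `alt`, `gt`, `ps`,
#'   `phased`.
#' @export
read_vcf <- function(path) {
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- as.data.table(vcfR::getFIX(v))
  if (nrow(fix) == 0)
    return(data.table(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      gt = character(0), ps = integer(0),
                      phased = logical(0)))
  gt <- vcfR::extract.gt(v, element = "GT")[, 1]
  ps <- tryCatch(vcfR::extract.gt(v, element = "PS")[, 1],
                 error = function(e) rep(NA_character_, nrow(fix)))
  data.table(chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
             alt = ifelse(is.na(fix$ALT), "", fix$ALT), gt = unname(gt),
             ps = as.integer(ps),
             phased = grepl("|", gt, fixed = TRUE))
}

SAM_LIKE_COLS <- c("read_id", "mate", "ref", "pos", "cigar", "strand",
                   "barcode", "dup", "seq")

#' Export aligned reads to the SAM-like flat text layer
#'
#' Tab-separated, one line per mate, with a `#` header line declaring the
#' columns: id, mate, ref, pos (0-based), CIGAR, strand, BX barcode tag,
#' duplicate flag, sequence. Unmapped mates carry `*` for ref/cigar/strand
#' and -1 for pos.
#'
#' @param aligned an `aligned_reads` table.
#' @param path output path.
#' @export
write_sam_like <- function(aligned, path) {
  al <- as.data.table(aligned)
  out <- al[, .(read_id, mate,
                ref = ifelse(mapped, ref, "*"),
                pos = ifelse(mapped, pos, -1L),
                cigar = ifelse(mapped, cigar, "*"),
                strand = ifelse(mapped, strand, "*"),
                barcode, dup = as.integer(dup), seq)]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(SAM_LIKE_COLS, collapse = "\t")), con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Import the SAM-like flat text layer
#' @param path file path.
#' @return an `aligned_reads` table.
#' @export
read_sam_like <- function(path) {
  d <- as.data.table(read.delim(path, header = FALSE, comment.char = "#",
                                col.names = SAM_LIKE_COLS,
                                colClasses = c("character", "integer",
                                               "character", "integer",
                                               "character", "character",
                                               "character", "integer",
                                               "character")))
  d[, mapped := ref != "*"]
  d[mapped == FALSE, `:=`(ref = NA_character_, pos = NA_integer_,
                          cigar = NA_character_, strand = NA_character_)]
  d[, dup := dup == 1L]
  setcolorder(d, c("read_id", "mate", "ref", "pos", "cigar", "strand",
                   "barcode", "mapped", "dup", "seq"))
  setattr(d, "class", c("aligned_reads", "data.table", "data.frame"))
  d[]
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; must contain a `seed` field.
#' @return a `pipeline_config` list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop_param("config must set an explicit seed")
  do.call(pipeline_config, cfg)
}

#' Write a pipeline configuration to YAML
#' @param config a `pipeline_config`.
#' @param path output path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
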
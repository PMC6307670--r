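## On-disk realization of a simulated world in the standard plain-text
## formats the pipeline reads: FASTA for sequences, BLAST-outfmt6-like TSV
## for hits, TSV expression/masking tables, minimal VCF 4.2 for SNPs, BED 6
## for junction reads and a JSON truth record.

#' Write a simulated world to disk and return a checksum manifest
#'
#' @param world a [simulate_world()] result.
#' @param dir output directory (created if missing).
#' @param pairs optional [simulate_brother_pairs()] result to include.
#' @return data.frame manifest (file, class, md5), invisibly also written
#'   as `manifest.tsv`.
#' @export
write_fixtures <- function(world, dir, pairs = NULL) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, 2) != 0) stop("I/O error: unwritable directory ", dir)
  files <- character(0); classes <- character(0)
  add <- function(path, cls) {
    files <<- c(files, path); classes <<- c(classes, cls)
  }
  write_fa <- function(seqs, names, path) {
    Biostrings::writeXStringSet(
      stats::setNames(Biostrings::DNAStringSet(seqs), names), path)
  }
  if (!is.null(world)) {
    for (sp in world$species) {
      if (!is.null(world$genomes[[sp]])) {
        p <- file.path(dir, paste0("genome_", sp, ".fa"))
        write_fa(world$genomes[[sp]], paste0(sp, "_chr1"), p)
        add(p, "fasta")
      }
      if (!is.null(world$te[[sp]]) && length(world$te[[sp]]$copies)) {
        p <- file.path(dir, paste0("te_copies_", sp, ".fa"))
        write_fa(world$te[[sp]]$copies,
                 paste0(sp, "_copy", seq_along(world$te[[sp]]$copies)), p)
        add(p, "fasta")
      }
      if (!is.null(world$genes[[sp]])) {
        p <- file.path(dir, paste0("genes_", sp, ".fa"))
        write_fa(world$genes[[sp]],
                 paste0(sp, "_gene", seq_along(world$genes[[sp]])), p)
        add(p, "fasta")
      }
      h <- world$hits[[sp]]
      if (!is.null(h) && nrow(h)) {
        p <- file.path(dir, paste0("hits_", sp, ".tsv"))
        utils::write.table(h, p, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        add(p, "hits_tsv")
      }
    }
    if (!is.null(world$expression)) {
      for (s in world$expression$samples) {
        p <- file.path(dir, paste0("reference_tpm_", s, ".tsv"))
        utils::write.table(
          data.frame(gene_id = paste0("ref", seq_along(
            world$expression$reference[[s]])),
            tpm = world$expression$reference[[s]]),
          p, sep = "\t", quote = FALSE, row.names = FALSE)
        add(p, "expression_tsv")
        p <- file.path(dir, paste0("te_transcripts_", s, ".tsv"))
        utils::write.table(world$expression$te[[s]], p, sep = "\t",
                           quote = FALSE, row.names = FALSE)
        add(p, "expression_tsv")
      }
    }
    p <- file.path(dir, "truth.json")
    jsonlite::write_json(world$truth, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    add(p, "json")
  }
  if (!is.null(pairs)) {
    for (fam in unique(pairs$snps$family)) {
      p <- file.path(dir, paste0("snps_", fam, ".vcf"))
      sub <- pairs$snps[pairs$snps$family == fam, , drop = FALSE]
      con <- file(p, "w")
      writeLines(c("##fileformat=VCFv4.2",
                   paste0("##source=activeTE_simulator"),
                   "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
      if (nrow(sub)) {
        writeLines(sprintf("%s\t%d\t.\tN\tN\t.\tPASS\tFAM=%s",
                           sub$chrom, sub$pos, fam), con)
      }
      close(con)
      add(p, "vcf")
    }
    p <- file.path(dir, "junction_reads.bed")
    b <- pairs$reads
    utils::write.table(
      data.frame(b$chrom, b$start, b$end,
                 paste(b$read_id, b$side, b$family, b$individual, b$te,
                       sep = "|"),
                 b$mapq, b$strand),
      p, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    add(p, "bed")
    p <- file.path(dir, "pair_truth.json")
    jsonlite::write_json(pairs$truth, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    add(p, "json")
  }
  manifest <- data.frame(
    file = basename(files), class = classes,
    md5 = unname(tools::md5sum(files)))
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest
}

#' Read a BED 6 junction-read table written by [write_fixtures()]
#' @param path BED file path.
#' @return junction read data.frame (0-based half-open intervals).
#' @export
read_junction_bed <- function(path) {
  b <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  meta <- strsplit(b$V4, "|", fixed = TRUE)
  data.frame(chrom = b$V1, start = b$V2, end = b$V3,
             read_id = vapply(meta, `[`, character(1), 1),
             mapq = b$V5, strand = b$V6,
             side = vapply(meta, `[`, character(1), 2),
             family = vapply(meta, `[`, character(1), 3),
             individual = vapply(meta, `[`, character(1), 4),
             te = vapply(meta, `[`, character(1), 5))
}
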
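# Serialisation of a synthetic bundle to the package's on-disk input
# formats, and reading it back through the package's own readers.

#' Write a synthetic bundle to a directory
#'
#' Emits every pipeline input in its standard plain-text format: genome
#' FASTA, GTF annotation, per-cell-line methylation call TSVs, probe-level
#' expression matrix + probe map + tissue classes, cell-line RPKM table,
#' two miRNA target tables, 3'UTR pair FASTA and MAF alignments, cancer
#' labels, ground truth and planted-region BEDs.
#'
#' @param bundle A `methmir_bundle`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "methmir_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  Biostrings::writeXStringSet(bundle$genome, p("genome.fa"))
  writeLines(bundle$gtf_lines, p("annotation.gtf"))
  fwrite(as.data.table(bundle$calls_a), p("meth_H1.tsv"), sep = "\t")
  fwrite(as.data.table(bundle$calls_b), p("meth_IMR90.tsv"), sep = "\t")
  pm <- data.table(probe_id = rownames(bundle$probe_matrix),
                   as.data.table(bundle$probe_matrix))
  fwrite(pm, p("expression_ad.tsv"), sep = "\t")
  fwrite(as.data.table(bundle$probe_map), p("probe_map.tsv"), sep = "\t")
  fwrite(as.data.table(bundle$tissue_classes), p("tissue_classes.tsv"),
         sep = "\t")
  fwrite(as.data.table(bundle$rpkm), p("expression_rpkm.tsv"), sep = "\t")
  fwrite(as.data.table(bundle$targets_mirtarget2),
         p("targets_mirtarget2.tsv"), sep = "\t")
  fwrite(as.data.table(bundle$targets_pictar), p("targets_pictar.tsv"),
         sep = "\t")
  utr <- bundle$utr_pairs
  fa <- Biostrings::BStringSet(setNames(
    c(utr$seq_a, utr$seq_b),
    c(paste0(utr$gene_id, "|hsa"), paste0(utr$gene_id, "|mmu"))))
  Biostrings::writeXStringSet(fa, p("utr3_pairs.fa"))
  writeLines(bundle$maf_lines, p("utr3.maf"))
  fwrite(as.data.table(bundle$cancer_labels), p("cancer_labels.tsv"),
         sep = "\t")
  fwrite(as.data.table(bundle$truth), p("ground_truth.tsv"), sep = "\t")
  fwrite(as.data.table(bundle$dmr_truth), p("dmr_truth.bed"), sep = "\t")
  fwrite(as.data.table(bundle$pmd_truth), p("pmd_truth.bed"), sep = "\t")
  invisible(dir)
}

#' Read a written bundle back through the package readers
#'
#' @param dir Directory produced by [write_bundle()].
#' @return A list with the same data components as the in-memory bundle
#'   (no config; `gtf` is the parsed transcript table).
#' @export
read_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  genome <- Biostrings::readDNAStringSet(p("genome.fa"))
  pm <- read_expression_matrix(p("expression_ad.tsv"))
  list(
    genome = genome,
    chrom_lengths = setNames(Biostrings::width(genome), names(genome)),
    transcripts = read_gtf_transcripts(p("annotation.gtf")),
    calls_a = read_methylation_calls(p("meth_H1.tsv")),
    calls_b = read_methylation_calls(p("meth_IMR90.tsv")),
    probe_matrix = pm,
    probe_map = as.data.frame(fread(p("probe_map.tsv"))),
    tissue_classes = as.data.frame(fread(p("tissue_classes.tsv"))),
    rpkm = as.data.frame(fread(p("expression_rpkm.tsv"))),
    targets_mirtarget2 = read_target_table(p("targets_mirtarget2.tsv")),
    targets_pictar = read_target_table(p("targets_pictar.tsv")),
    utr_pairs = read_alignment_pairs(p("utr3_pairs.fa"), focal = "hsa"),
    maf = read_maf(p("utr3.maf")),
    cancer_labels = as.data.frame(fread(p("cancer_labels.tsv"))),
    dmr_truth = as.data.frame(fread(p("dmr_truth.bed"))),
    pmd_truth = as.data.frame(fread(p("pmd_truth.bed"))),
    truth = as.data.frame(fread(p("ground_truth.tsv")))
  )
}
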
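# Shared synthetic bundles, built once per test run and cached.

.bundle_cache <- new.env(parent = emptyenv())

# moderate bundle: segmentation-scale conditions (20 DMRs, 5 PMDs)
medium_config <- function(...) {
  simulation_config(n_genes = 600L, n_chromosomes = 2L, seed = 101L,
                    dmr_count = 20L, pmd_count = 5L, pmd_length = 30000L,
                    ...)
}

medium_bundle <- function() {
  if (is.null(.bundle_cache$medium))
    .bundle_cache$medium <- simulate_bundle(medium_config())
  .bundle_cache$medium
}

medium_pipeline <- function() {
  if (is.null(.bundle_cache$medium_res))
    .bundle_cache$medium_res <- run_pipeline(medium_bundle())
  .bundle_cache$medium_res
}

# full-scale bundle: the default study conditions (5000 genes)
big_bundle <- function() {
  if (is.null(.bundle_cache$big))
    .bundle_cache$big <- simulate_bundle(simulation_config(seed = 2024L))
  .bundle_cache$big
}

big_pipeline <- function() {
  if (is.null(.bundle_cache$big_res))
    .bundle_cache$big_res <- run_pipeline(big_bundle(), segment = FALSE)
  .bundle_cache$big_res
}

tiny_config <- function(seed = 5L, ...) {
  simulation_config(n_genes = 80L, n_chromosomes = 2L, seed = seed,
                    dmr_count = 3L, pmd_count = 1L, pmd_length = 20000L,
                    cancer_fraction = 0.1, ...)
}

# toy transcript-table row in the reader's format
tx_row <- function(transcript_id, gene_id, tss, strand = "+",
                   chrom = "chr1", cds_length = 900L, span = 2000L,
                   utr3 = c(tss + 1500L, tss + 1900L)) {
  data.frame(transcript_id = transcript_id, gene_id = gene_id,
             chrom = chrom, strand = strand,
             tx_start = tss, tx_end = tss + span, tss = tss,
             cds_length = cds_length,
             utr3_start = utr3[1L], utr3_end = utr3[2L],
             utr3_length = utr3[2L] - utr3[1L], stringsAsFactors = FALSE)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
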
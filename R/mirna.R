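# Per-gene miRNA target-site burden from prediction tables.

#' Read a miRNA target table
#'
#' TSV with columns `gene_id`, `mirna_id`, `source` and optionally
#' `position` (a 3'UTR offset of the predicted site).
#'
#' @param path File path.
#' @return `data.frame` of target records.
#' @export
read_target_table <- function(path) {
  as.data.frame(fread(path))
}

#' Count miRNA target sites per gene
#'
#' Records are deduplicated on (`gene_id`, `mirna_id`, `source`,
#' `position`). With `by = "sites"` the count per gene is the number of
#' unique (`mirna_id`, `position`) pairs, falling back to unique miRNAs when
#' positions are absent; `by = "mirnas"` always counts unique miRNAs.
#' When a reference gene list is supplied and the table is flagged
#' genome-wide, genes absent from the table get count 0; otherwise they get
#' a missing value (absence in a partial-coverage table is not evidence of
#' zero sites).
#'
#' @param records Target-record `data.frame`.
#' @param source Optional source filter (value of the `source` column).
#' @param by `"sites"` (default) or `"mirnas"`.
#' @param genes Optional character vector of reference gene IDs.
#' @param genome_wide Is the table genome-wide? (default `TRUE`).
#' @return `data.frame` with `gene_id`, `n_sites`.
#' @export
count_target_sites <- function(records, source = NULL,
                               by = c("sites", "mirnas"), genes = NULL,
                               genome_wide = TRUE) {
  by <- match.arg(by)
  dt <- as.data.table(records)
  if (!is.null(source)) dt <- dt[dt$source == source]
  has_pos <- "position" %in% names(dt)
  cols <- c("gene_id", "mirna_id", if ("source" %in% names(dt)) "source",
            if (has_pos) "position")
  dt <- unique(dt[, cols, with = FALSE])
  if (by == "sites" && has_pos) {
    cnt <- dt[, list(n_sites = length(unique(paste(mirna_id, position)))),
              by = "gene_id"]
  } else {
    cnt <- dt[, list(n_sites = length(unique(mirna_id))), by = "gene_id"]
  }
  out <- as.data.frame(cnt)
  if (!is.null(genes)) {
    out <- merge(data.frame(gene_id = genes, stringsAsFactors = FALSE),
                 out, by = "gene_id", all.x = TRUE, sort = TRUE)
    if (genome_wide) out$n_sites[is.na(out$n_sites)] <- 0L
  }
  out
}

#' 3'UTR length as a target-capacity proxy
#'
#' Labeled projection of the annotation's UL column so the correlation
#' battery can treat UTR length as a third burden measure.
#'
#' @param gene_models `data.frame` from [build_gene_models()].
#' @return `data.frame` with `gene_id`, `ul`; genes lacking a 3'UTR are
#'   absent.
#' @export
utr_length_proxy <- function(gene_models) {
  out <- gene_models[!is.na(gene_models$ul), c("gene_id", "ul")]
  row.names(out) <- NULL
  out
}
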
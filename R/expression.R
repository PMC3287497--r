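# Expression matrices: probe collapse, mean level, expression broadness (EB).

#' Read an expression matrix from TSV
#'
#' First column is the probe/gene identifier, header gives sample labels.
#' Duplicate column labels (replicates) are preserved.
#'
#' @param path File path.
#' @return Numeric matrix with row names = identifiers, column names =
#'   sample labels.
#' @export
read_expression_matrix <- function(path) {
  d <- fread(path, header = TRUE, check.names = FALSE)
  ids <- as.character(d[[1L]])
  m <- as.matrix(d[, -1L, with = FALSE])
  rownames(m) <- ids
  m
}

average_replicates <- function(m) {
  labs <- colnames(m)
  if (!anyDuplicated(labs)) return(m)
  u <- unique(labs)
  out <- matrix(0, nrow(m), length(u),
                dimnames = list(rownames(m), u))
  for (l in u) out[, l] <- rowMeans(m[, labs == l, drop = FALSE])
  out
}

#' Collapse probe-level intensities to gene level
#'
#' Replicate samples (identical column labels) are averaged first. Probes
#' with low-confidence identifiers (suffix `_x_at` or `_s_at`) are
#' discarded, the remaining probes mapped to genes and averaged per gene and
#' sample. Genes with no surviving probe are absent from the output.
#'
#' @param probe_matrix Numeric matrix, rows = probe IDs, columns = samples.
#' @param probe_map `data.frame` with columns `probe_id`, `gene_id`.
#' @param drop_suffixes Probe-ID suffixes to discard
#'   (default `c("_x_at", "_s_at")`).
#' @return Gene-by-sample numeric matrix.
#' @export
collapse_probes <- function(probe_matrix, probe_map,
                            drop_suffixes = c("_x_at", "_s_at")) {
  m <- average_replicates(probe_matrix)
  keep <- !Reduce(`|`, lapply(drop_suffixes, function(s)
    endsWith(rownames(m), s)))
  m <- m[keep, , drop = FALSE]
  map <- probe_map[probe_map$probe_id %in% rownames(m), , drop = FALSE]
  if (nrow(map) == 0L)
    return(matrix(numeric(), 0L, ncol(m), dimnames = list(NULL, colnames(m))))
  m <- m[map$probe_id, , drop = FALSE]
  genes <- sort(unique(map$gene_id))
  g <- factor(map$gene_id, levels = genes)
  counts <- as.vector(table(g))
  out <- rowsum(m, g) / counts
  rownames(out) <- genes
  out
}

#' Expression level and broadness (EB) per gene
#'
#' EB is the number of tissues in which a gene's intensity reaches the
#' threshold (inclusive); the level is the mean intensity over all tissues.
#'
#' @param m Gene-by-tissue numeric matrix.
#' @param threshold Intensity threshold (default 200, the AD cutoff).
#' @return `data.frame` with `gene_id`, `mean_level`, `eb`.
#' @export
expression_broadness <- function(m, threshold = 200) {
  stopifnot(threshold > 0)
  data.frame(gene_id = rownames(m), mean_level = rowMeans(m),
             eb = as.integer(rowSums(m >= threshold)),
             stringsAsFactors = FALSE, row.names = NULL)
}
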
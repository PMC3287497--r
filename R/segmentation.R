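# Methylome segmentation: differentially methylated regions (DMRs) between
# two call sets and partially methylated domains (PMDs) within one.

window_site_counts <- function(calls, methylated, window) {
  dt <- as.data.table(calls)
  dt[, methylated := methylated]
  dt <- dt[context == "CG"]
  dt[, win := (pos %/% as.integer(window))]
  dt[, list(n_meth = sum(methylated), n_unmeth = sum(!methylated)),
     by = c("chrom", "win")]
}

#' Detect differentially methylated regions (DMRs)
#'
#' Tiles the genome in fixed non-overlapping windows; in each window builds
#' the 2x2 table of called site states (methylated / unmethylated) by cell
#' line and tests, one-sided by default, for higher methylation in the second
#' call set by Fisher's exact test. P-values are Benjamini-Hochberg adjusted
#' across windows; significant windows separated by less than one window are
#' merged into DMRs. Windows with no covered site in either set are skipped.
#'
#' @param calls_a,calls_b Call `data.frame`s for the two cell lines (same
#'   genome).
#' @param window Window size in bases (default 1000).
#' @param fdr BH q-value cutoff (default 0.05).
#' @param alternative `"greater_in_b"` (one-sided, mirrors the DMR
#'   definition) or `"two.sided"`.
#' @param call_method,... Site caller and its parameters, passed to
#'   [call_methylated_sites()].
#' @param merge_gap Maximum gap (bases) between significant windows that are
#'   merged; defaults to `window` (i.e. only adjacent windows merge).
#' @return `data.frame` with `kind`, `chrom`, `start`, `end`, `statistic`
#'   (difference of methylated-site fractions, B minus A), `q_value`.
#' @export
detect_dmrs <- function(calls_a, calls_b, window = 1000L, fdr = 0.05,
                        alternative = c("greater_in_b", "two.sided"),
                        call_method = "binomial", merge_gap = window, ...) {
  if (window < 1L) stop("window must be >= 1")
  alternative <- match.arg(alternative)
  ma <- call_methylated_sites(calls_a, method = call_method, ...)
  mb <- call_methylated_sites(calls_b, method = call_method, ...)
  wa <- window_site_counts(calls_a, ma, window)
  wb <- window_site_counts(calls_b, mb, window)
  tab <- merge(wa, wb, by = c("chrom", "win"), suffixes = c("_a", "_b"))
  empty <- data.frame(kind = character(), chrom = character(),
                      start = integer(), end = integer(),
                      statistic = numeric(), q_value = numeric())
  if (nrow(tab) == 0L) return(empty)
  mA <- tab$n_meth_a; uA <- tab$n_unmeth_a
  mB <- tab$n_meth_b; uB <- tab$n_unmeth_b
  if (alternative == "greater_in_b") {
    # one-sided Fisher: P(meth_A <= observed) under the hypergeometric null
    p <- phyper(mA, mA + mB, uA + uB, mA + uA)
  } else {
    p <- vapply(seq_along(mA), function(i) {
      stats::fisher.test(matrix(c(mA[i], uA[i], mB[i], uB[i]), 2L,
                                byrow = TRUE))$p.value
    }, numeric(1))
  }
  q <- p.adjust(p, method = "BH")
  frac_diff <- mB / (mB + uB) - mA / (mA + uA)
  sig <- which(q <= fdr)
  if (length(sig) == 0L) return(empty)
  sg <- data.table(chrom = tab$chrom[sig],
                   start = tab$win[sig] * as.integer(window),
                   q_value = q[sig], statistic = frac_diff[sig])
  sg[, end := start + as.integer(window)]
  sg <- sg[order(chrom, start)]
  merge_regions(sg, max_gap = merge_gap, kind = "DMR")
}

# merge sorted windows whose gap is < max_gap; aggregates statistic (mean)
# and q_value (min)
merge_regions <- function(sg, max_gap, kind) {
  grp <- integer(nrow(sg)); g <- 1L; grp[1L] <- 1L
  if (nrow(sg) > 1L) {
    for (i in 2:nrow(sg)) {
      if (sg$chrom[i] != sg$chrom[i - 1L] ||
          sg$start[i] - sg$end[i - 1L] >= max_gap) g <- g + 1L
      grp[i] <- g
    }
  }
  sg[, grp := grp]
  out <- sg[, list(chrom = chrom[1L], start = min(start), end = max(end),
                   statistic = mean(statistic), q_value = min(q_value)),
            by = "grp"]
  data.frame(kind = kind, chrom = out$chrom, start = out$start,
             end = out$end, statistic = out$statistic,
             q_value = out$q_value, stringsAsFactors = FALSE)
}

#' Detect partially methylated domains (PMDs)
#'
#' Slides non-overlapping windows over one methylome; per window computes the
#' read-weighted mean methylation (sum of methylated reads / sum of total
#' reads over CpG sites). Consecutive windows with mean strictly below
#' `threshold` are merged, and merged runs spanning at least `min_length`
#' bases are reported as PMDs. Windows without covered sites break runs.
#'
#' @param calls Call `data.frame` for one cell line.
#' @param window Window size in bases (default 10000).
#' @param threshold PMD mean-methylation threshold, strict less-than
#'   (default 0.70).
#' @param min_length Minimum merged-region length in bases (default 10000).
#' @return `data.frame` with `kind`, `chrom`, `start`, `end`,
#'   `mean_methylation`.
#' @export
detect_pmds <- function(calls, window = 10000L, threshold = 0.70,
                        min_length = 10000L) {
  stopifnot(threshold > 0, threshold < 1)
  dt <- as.data.table(calls)
  dt <- dt[context == "CG"]
  dt[, win := pos %/% as.integer(window)]
  w <- dt[, list(mc = sum(mc_reads), tot = sum(total_reads)),
          by = c("chrom", "win")]
  w <- w[w$tot > 0L]
  w[, meth := mc / tot]
  sub <- w[w$meth < threshold]
  empty <- data.frame(kind = character(), chrom = character(),
                      start = integer(), end = integer(),
                      mean_methylation = numeric())
  if (nrow(sub) == 0L) return(empty)
  sub <- sub[order(chrom, win)]
  grp <- cumsum(c(TRUE, sub$chrom[-1] != sub$chrom[-nrow(sub)] |
                    diff(sub$win) != 1L))
  sub[, grp := grp]
  reg <- sub[, list(chrom = chrom[1L],
                    start = min(win) * as.integer(window),
                    end = (max(win) + 1L) * as.integer(window),
                    mean_methylation = sum(mc) / sum(tot)), by = "grp"]
  reg <- reg[(reg$end - reg$start) >= min_length]
  if (nrow(reg) == 0L) return(empty)
  data.frame(kind = "PMD", chrom = reg$chrom, start = reg$start,
             end = reg$end, mean_methylation = reg$mean_methylation,
             stringsAsFactors = FALSE)
}

#' Assign genes to regions by interval overlap
#'
#' A gene belongs to a region set when its promoter (default) or whole gene
#' span overlaps any region by at least one base. The resulting flag
#' partitions the gene set exhaustively and disjointly.
#'
#' @param gene_models `data.frame` from [build_gene_models()].
#' @param regions Region `data.frame` (from [detect_dmrs()] or
#'   [detect_pmds()]).
#' @param by `"promoter"` or `"gene"` (promoter start to transcript span is
#'   approximated by the promoter plus the 3'UTR extent).
#' @return Logical vector along `gene_models` rows: in-region membership.
#' @export
assign_genes_to_regions <- function(gene_models, regions,
                                    by = c("promoter", "gene")) {
  by <- match.arg(by)
  if (nrow(regions) == 0L) return(rep(FALSE, nrow(gene_models)))
  if (by == "promoter") {
    s <- gene_models$promoter_start; e <- gene_models$promoter_end
  } else {
    s <- pmin(gene_models$promoter_start, gene_models$utr3_start)
    e <- pmax(gene_models$promoter_end, gene_models$utr3_end)
  }
  ggr <- GenomicRanges::GRanges(gene_models$chrom,
                                IRanges::IRanges(s + 1L, e))
  rgr <- GenomicRanges::GRanges(regions$chrom,
                                IRanges::IRanges(regions$start + 1L,
                                                 regions$end))
  ov <- suppressWarnings(GenomicRanges::countOverlaps(ggr, rgr))
  ov > 0L
}

#' Write / read region sets as BED4+ text
#' @param regions Region `data.frame`.
#' @param path File path.
#' @export
write_regions <- function(regions, path) {
  fwrite(as.data.table(regions), path, sep = "\t")
  invisible(path)
}

#' @rdname write_regions
#' @export
read_regions <- function(path) {
  as.data.frame(fread(path))
}
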
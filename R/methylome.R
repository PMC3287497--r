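# Promoter methylation broadness (mCG/CG), normalized CpG content (CpG O/E)
# and CpG-island counting from single-base bisulfite call sets.

#' Read single-base methylation calls
#'
#' Six-column TSV (optionally gzipped): `chrom`, `pos` (0-based position of
#' the C of a CpG on the forward strand), `strand`, `context` (CG/CHG/CHH),
#' `mc_reads`, `total_reads`. One file per cell line.
#'
#' @param path File path.
#' @return `data.frame` of calls; rows violating `0 <= mc <= total`,
#'   `total >= 1` raise an error.
#' @export
read_methylation_calls <- function(path) {
  d <- as.data.frame(fread(path, col.names = c("chrom", "pos", "strand",
                                               "context", "mc_reads",
                                               "total_reads")))
  validate_calls(d)
  d
}

validate_calls <- function(calls) {
  stopifnot(all(c("chrom", "pos", "strand", "context", "mc_reads",
                  "total_reads") %in% names(calls)))
  bad <- calls$mc_reads < 0 | calls$mc_reads > calls$total_reads |
    calls$total_reads < 1
  if (any(bad)) stop(sum(bad), " call rows violate read-count invariants")
  invisible(calls)
}

#' Call methylated sites from read counts
#'
#' Two pluggable callers. `binomial`: a site is methylated when a one-sided
#' binomial test of `mc_reads` out of `total_reads` against the
#' bisulfite non-conversion error rate rejects at a per-site
#' Benjamini-Hochberg q-value below `q_cutoff` (adjusted across the whole
#' call set). `fraction`: methylated when `mc_reads / total_reads >= theta`.
#'
#' @param calls Call `data.frame` (see [read_methylation_calls()]).
#' @param method `"binomial"` or `"fraction"`.
#' @param error_rate Assumed per-read error rate for the binomial test
#'   (default 0.01).
#' @param q_cutoff BH q-value cutoff (default 0.01).
#' @param theta Methylation-fraction threshold (default 0.5).
#' @return Logical vector, one element per call row.
#' @export
call_methylated_sites <- function(calls, method = c("binomial", "fraction"),
                                  error_rate = 0.01, q_cutoff = 0.01,
                                  theta = 0.5) {
  method <- match.arg(method)
  validate_calls(calls)
  if (method == "fraction") {
    return(calls$mc_reads / calls$total_reads >= theta)
  }
  p <- pbinom(calls$mc_reads - 1L, calls$total_reads, error_rate,
              lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  q <= q_cutoff & calls$mc_reads > 0L
}

#' Locate CpG dinucleotides in a genome
#'
#' Enumerates CpG dinucleotides on the forward strand (the dinucleotide is
#' palindromic, so one entry represents the site on both strands). Positions
#' are 0-based positions of the C.
#'
#' @param genome A named [Biostrings::DNAStringSet] (one entry per contig),
#'   or a named character vector.
#' @return `data.frame` with `chrom`, `pos`.
#' @export
find_cpg_sites <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  hits <- Biostrings::vmatchPattern("CG", genome)
  starts <- lapply(hits, BiocGenerics::start)
  data.frame(
    chrom = rep(names(genome), lengths(starts)),
    pos = unlist(starts, use.names = FALSE) - 1L,
    stringsAsFactors = FALSE
  )
}

#' Promoter methylation broadness (mCG/CG)
#'
#' For each gene, the fraction of covered CpG sites inside the promoter
#' window that are called methylated: `mCG/CG = methylated promoter CpGs /
#' covered promoter CpGs`. Sites with coverage below `min_coverage` are
#' excluded from numerator and denominator; a promoter with no covered CpG
#' gets a missing value. Following the sense-strand convention, when a
#' position carries separate per-strand call rows the row matching the
#' gene's annotated strand is used (`strand_mode = "sense"`); `"merge"` sums
#' reads across strands instead.
#'
#' @param gene_models `data.frame` from [build_gene_models()].
#' @param cpg_sites `data.frame` of genomic CpG positions
#'   (see [find_cpg_sites()]).
#' @param calls Call `data.frame` for one cell line.
#' @param methylated Logical vector per call row, as from
#'   [call_methylated_sites()].
#' @param min_coverage Minimum `total_reads` for a site to count (default 1).
#' @param strand_mode `"sense"` or `"merge"`.
#' @return `data.frame` with `gene_id`, `mcg_cg`, `n_cpg_covered`,
#'   `n_cpg_total`.
#' @export
promoter_mcg_cg <- function(gene_models, cpg_sites, calls, methylated,
                            min_coverage = 1L,
                            strand_mode = c("sense", "merge")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(length(methylated) == nrow(calls))
  cg <- as.data.table(calls)
  cg[, methylated := methylated]
  cg <- cg[context == "CG"]
  if (strand_mode == "merge") {
    cg <- cg[, list(strand = "*", mc_reads = sum(mc_reads),
                    total_reads = sum(total_reads),
                    methylated = any(methylated)),
             by = c("chrom", "pos")]
  }
  cg <- cg[total_reads >= min_coverage]

  gm <- gene_models
  sgr <- GenomicRanges::GRanges(cpg_sites$chrom,
                                IRanges::IRanges(cpg_sites$pos + 1L,
                                                 cpg_sites$pos + 1L))
  pgr <- GenomicRanges::GRanges(gm$chrom,
                                IRanges::IRanges(gm$promoter_start + 1L,
                                                 gm$promoter_end))
  ov <- suppressWarnings(GenomicRanges::findOverlaps(sgr, pgr))
  hit <- data.table(chrom = cpg_sites$chrom[S4Vectors::queryHits(ov)],
                    pos = cpg_sites$pos[S4Vectors::queryHits(ov)],
                    gene_idx = S4Vectors::subjectHits(ov))
  hit[, gstrand := gm$strand[gene_idx]]
  n_total <- integer(nrow(gm))
  if (nrow(hit)) {
    tt <- hit[, list(n = .N), by = "gene_idx"]
    n_total[tt$gene_idx] <- tt$n
  }
  j <- merge(hit, cg, by = c("chrom", "pos"), allow.cartesian = TRUE)
  if (strand_mode == "sense" && nrow(j)) {
    j[, ndup := .N, by = c("gene_idx", "chrom", "pos")]
    j <- j[ndup == 1L | strand == gstrand | strand == "*"]
    j <- j[!duplicated(j[, c("gene_idx", "chrom", "pos"), with = FALSE])]
  }
  n_cov <- integer(nrow(gm)); n_meth <- integer(nrow(gm))
  if (nrow(j)) {
    agg <- j[, list(n_cov = .N, n_meth = sum(methylated)), by = "gene_idx"]
    n_cov[agg$gene_idx] <- agg$n_cov
    n_meth[agg$gene_idx] <- agg$n_meth
  }
  data.frame(gene_id = gm$gene_id,
             mcg_cg = ifelse(n_cov == 0L, NA_real_, n_meth / n_cov),
             n_cpg_covered = n_cov, n_cpg_total = n_total,
             stringsAsFactors = FALSE)
}

#' Normalized CpG content (CpG O/E)
#'
#' Observed/expected CpG ratio of a sequence: the CpG dinucleotide frequency
#' divided by the product of the C and G frequencies,
#' `n_cpg * length / (n_c * n_g)`. Dinucleotides are counted by overlapping
#' scan and the denominator uses the full (non-N) sequence length.
#' Positions containing N are excluded from all counts and from the length.
#' The ratio is missing when the sequence has no C or no G (or is empty
#' after N exclusion).
#'
#' @param seq Character vector of sequences (or a
#'   [Biostrings::DNAStringSet]).
#' @return `data.frame` with `length`, `n_c`, `n_g`, `n_cpg`, `cpg_oe`.
#' @export
cpg_oe <- function(seq) {
  if (is.character(seq)) {
    stopifnot(all(nchar(seq) > 0L))
    sset <- Biostrings::DNAStringSet(seq)
  } else {
    sset <- seq
    stopifnot(all(Biostrings::width(sset) > 0L))
  }
  lf <- Biostrings::letterFrequency(sset, c("C", "G", "N"))
  n_cpg <- Biostrings::vcountPattern("CG", sset)
  len <- Biostrings::width(sset) - lf[, "N"]
  n_c <- lf[, "C"]; n_g <- lf[, "G"]
  oe <- ifelse(n_c == 0 | n_g == 0 | len == 0, NA_real_,
               n_cpg * len / (n_c * n_g))
  data.frame(length = as.integer(len), n_c = as.integer(n_c),
             n_g = as.integer(n_g), n_cpg = as.integer(n_cpg), cpg_oe = oe)
}

#' Count CpG islands in a sequence
#'
#' Gardiner-Garden--Frommer style detection: a 200-bp window (slid 1 bp at a
#' time) qualifies when GC content is at least `min_gc` and windowed CpG O/E
#' at least `min_oe`; maximal runs of consecutive qualifying window starts
#' are merged into islands (each island therefore spans at least `window`
#' bases). Returns the number of islands per sequence.
#'
#' @param seq Character vector of sequences.
#' @param window Window size in bp (default 200).
#' @param min_gc Minimum GC fraction (default 0.5).
#' @param min_oe Minimum windowed CpG O/E (default 0.6).
#' @return Integer vector of island counts.
#' @export
count_cgis <- function(seq, window = 200L, min_gc = 0.5, min_oe = 0.6) {
  vapply(seq, function(s) {
    L <- nchar(s)
    if (L < window) return(0L)
    ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    isC <- as.integer(ch == "C"); isG <- as.integer(ch == "G")
    iscg <- as.integer(ch[-L] == "C" & ch[-1] == "G")
    csC <- cumsum(c(0L, isC)); csG <- cumsum(c(0L, isG))
    csCG <- cumsum(c(0L, iscg))
    starts <- seq_len(L - window + 1L)           # 1-based window starts
    nc <- csC[starts + window] - csC[starts]
    ng <- csG[starts + window] - csG[starts]
    # dinucleotide starts inside the window: starts .. starts + window - 2
    ncg <- csCG[pmin(starts + window - 1L, L)] - csCG[starts]
    gc_ok <- (nc + ng) / window >= min_gc
    oe <- ifelse(nc == 0 | ng == 0, 0, ncg * window / (nc * ng))
    ok <- gc_ok & oe >= min_oe
    r <- rle(ok)
    sum(r$values)
  }, integer(1), USE.NAMES = FALSE)
}
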
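#' @importFrom data.table data.table as.data.table setkey := .N .SD fread fwrite
#' @importFrom stats pbinom p.adjust phyper rnorm rpois rbinom runif pnorm
#'   qnorm qnbinom complete.cases cor pt pchisq setNames
#' @importFrom utils head
NULL

# All genomic intervals inside the package are 0-based half-open [start, end).
# GTF input (1-based closed) is converted on read; BED-like output needs no
# conversion.

#' Read transcript models from a GTF file
#'
#' Parses `transcript`, `CDS` and `three_prime_utr` features and assembles one
#' row per transcript with its TSS, total CDS length and 3'UTR interval.
#' Coordinates are converted to 0-based half-open intervals.
#'
#' @param path Path to a GTF file with `gene_id` and `transcript_id`
#'   attributes.
#' @return A `data.frame` with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `tx_start`, `tx_end`, `tss`, `cds_length`, `utr3_start`,
#'   `utr3_end`, `utr3_length`. `utr3_*` are `NA` for transcripts without an
#'   annotated 3'UTR.
#' @export
read_gtf_transcripts <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- data.table(
    type = as.character(gr$type),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = gr$gene_id,
    transcript_id = gr$transcript_id
  )
  tx <- df[df$type == "transcript", ]
  if (nrow(tx) == 0L) stop("no transcript features in ", path)
  cds <- df[df$type == "CDS",
            list(cds_length = sum(end - start)), by = "transcript_id"]
  utr <- df[df$type == "three_prime_utr",
            list(utr3_start = min(start), utr3_end = max(end),
                 utr3_length = sum(end - start)), by = "transcript_id"]
  out <- data.table(
    transcript_id = tx$transcript_id, gene_id = tx$gene_id,
    chrom = tx$chrom, strand = tx$strand,
    tx_start = tx$start, tx_end = tx$end,
    tss = ifelse(tx$strand == "+", tx$start, tx$end - 1L)
  )
  out <- merge(out, cds, by = "transcript_id", all.x = TRUE)
  out <- merge(out, utr, by = "transcript_id", all.x = TRUE)
  out$cds_length[is.na(out$cds_length)] <- 0L
  as.data.frame(out[order(out$gene_id, out$transcript_id), ])
}

#' Select the major transcript of a gene
#'
#' Deterministic canonical-transcript rule: the transcript with the longest
#' total CDS; ties broken by the longest genomic span, then by the
#' lexicographically smallest `transcript_id`. Invariant to input order.
#'
#' @param transcripts A `data.frame` of transcripts of a single gene (as from
#'   [read_gtf_transcripts()]).
#' @return The selected single-row `data.frame`.
#' @export
select_major_transcript <- function(transcripts) {
  if (is.null(transcripts) || nrow(transcripts) == 0L) stop("no transcripts")
  if (length(unique(transcripts$gene_id)) != 1L)
    stop("transcripts belong to more than one gene")
  span <- transcripts$tx_end - transcripts$tx_start
  o <- order(-transcripts$cds_length, -span, transcripts$transcript_id)
  transcripts[o[1L], , drop = FALSE]
}

#' Promoter window around a TSS
#'
#' Strand-aware window spanning `window_up` bases upstream and `window_down`
#' bases downstream of the TSS (defaults: -1000 to +200). On the plus strand
#' this is `[tss - window_up, tss + window_down)`; on the minus strand the
#' mirror image. Windows running off the contig start (or past `chrom_length`
#' when given) are clipped and flagged.
#'
#' @param tss Integer vector of 0-based TSS positions.
#' @param strand Character vector of "+"/"-".
#' @param window_up,window_down Window extents in bases.
#' @param chrom_length Optional contig length(s) for right clipping.
#' @return `data.frame` with `start`, `end`, `clipped`.
#' @export
promoter_interval <- function(tss, strand, window_up = 1000L,
                              window_down = 200L, chrom_length = NULL) {
  stopifnot(all(tss >= 0L), all(strand %in% c("+", "-")))
  up <- as.integer(window_up); down <- as.integer(window_down)
  start <- ifelse(strand == "+", tss - up, tss - down)
  end <- ifelse(strand == "+", tss + down, tss + up)
  clipped <- start < 0L
  start <- pmax(start, 0L)
  if (!is.null(chrom_length)) {
    clipped <- clipped | end > chrom_length
    end <- pmin(end, chrom_length)
  }
  data.frame(start = as.integer(start), end = as.integer(end),
             clipped = clipped)
}

#' Build per-gene models from a transcript table
#'
#' Selects each gene's major transcript, derives the promoter window around
#' its TSS and carries its 3'UTR interval and length (UL). Genes whose major
#' transcript has no annotated 3'UTR are dropped.
#'
#' @param transcripts `data.frame` from [read_gtf_transcripts()].
#' @inheritParams promoter_interval
#' @param chrom_lengths Optional named integer vector of contig lengths.
#' @return `data.frame` with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `tss`, `major_transcript`, `promoter_start`, `promoter_end`,
#'   `promoter_clipped`, `utr3_start`, `utr3_end`, `ul`.
#' @export
build_gene_models <- function(transcripts, window_up = 1000L,
                              window_down = 200L, chrom_lengths = NULL) {
  dt <- as.data.table(transcripts)
  major <- data.table::rbindlist(
    lapply(split(dt, by = "gene_id", sorted = TRUE),
           select_major_transcript))
  major <- major[!is.na(major$utr3_length) & major$utr3_length >= 1L, ]
  clen <- if (is.null(chrom_lengths)) NULL else
    unname(chrom_lengths[major$chrom])
  pr <- promoter_interval(major$tss, major$strand, window_up, window_down,
                          chrom_length = clen)
  data.frame(
    gene_id = major$gene_id, chrom = major$chrom, strand = major$strand,
    tss = major$tss, major_transcript = major$transcript_id,
    promoter_start = pr$start, promoter_end = pr$end,
    promoter_clipped = pr$clipped,
    utr3_start = major$utr3_start, utr3_end = major$utr3_end,
    ul = major$utr3_length,
    stringsAsFactors = FALSE
  )
}

reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- pmax(0L, pmin(e1, e2) - pmax(s1, s2))
  pmin(ov / (e1 - s1), ov / (e2 - s2))
}

#' Drop genes with ambiguous TSS or 3'UTR annotation
#'
#' A gene is retained iff (a) every alternative transcript's TSS lies within
#' `tss_tolerance` bases (absolute genomic distance) of the major TSS, and
#' (b) all annotated 3'UTR intervals of its transcripts are mutually
#' consistent: every pair has reciprocal overlap of at least
#' `min_utr_overlap` and agrees on strand. Transcripts without an annotated
#' 3'UTR do not participate in check (b). The result is a subset of the input
#' and the filter is idempotent.
#'
#' @param gene_models `data.frame` from [build_gene_models()].
#' @param transcripts The full transcript table the models came from.
#' @param tss_tolerance Maximum allowed TSS distance in bases (default 200).
#' @param min_utr_overlap Minimum pairwise reciprocal 3'UTR overlap
#'   (default 0.8).
#' @return The filtered `gene_models`.
#' @export
filter_unambiguous_genes <- function(gene_models, transcripts,
                                     tss_tolerance = 200L,
                                     min_utr_overlap = 0.8) {
  if (nrow(gene_models) == 0L) return(gene_models)
  tx <- as.data.table(transcripts)
  keep <- vapply(seq_len(nrow(gene_models)), function(i) {
    g <- gene_models[i, ]
    t <- tx[tx$gene_id == g$gene_id, ]
    if (any(abs(t$tss - g$tss) > tss_tolerance)) return(FALSE)
    u <- t[!is.na(t$utr3_start), ]
    if (nrow(u) >= 2L) {
      if (length(unique(u$strand)) > 1L) return(FALSE)
      idx <- utils::combn(nrow(u), 2L)
      ro <- reciprocal_overlap(u$utr3_start[idx[1, ]], u$utr3_end[idx[1, ]],
                               u$utr3_start[idx[2, ]], u$utr3_end[idx[2, ]])
      if (any(ro < min_utr_overlap)) return(FALSE)
    }
    TRUE
  }, logical(1))
  gene_models[keep, , drop = FALSE]
}

#' Write / read gene models as BED6+ text
#'
#' Tab-separated BED6 (promoter interval, gene_id as name, strand) plus
#' extra columns `tss`, `ul`, `clipped`, `utr3_start`, `utr3_end`.
#'
#' @param gene_models `data.frame` from [build_gene_models()].
#' @param path Output (input) file path.
#' @export
write_gene_models <- function(gene_models, path) {
  out <- data.frame(
    chrom = gene_models$chrom, start = gene_models$promoter_start,
    end = gene_models$promoter_end, name = gene_models$gene_id,
    score = 0L, strand = gene_models$strand, tss = gene_models$tss,
    ul = gene_models$ul, clipped = as.integer(gene_models$promoter_clipped),
    utr3_start = gene_models$utr3_start, utr3_end = gene_models$utr3_end
  )
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_gene_models
#' @export
read_gene_models <- function(path) {
  d <- as.data.frame(fread(path))
  data.frame(
    gene_id = d$name, chrom = d$chrom, strand = d$strand, tss = d$tss,
    promoter_start = d$start, promoter_end = d$end,
    promoter_clipped = as.logical(d$clipped),
    utr3_start = d$utr3_start, utr3_end = d$utr3_end,
    ul = d$ul, stringsAsFactors = FALSE
  )
}
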
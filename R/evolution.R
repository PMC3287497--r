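# 3'UTR evolutionary rates: Kimura two-parameter substitution distance on
# aligned ortholog pairs and focal-lineage indel rates from multiple
# alignments.

TRANSITIONS <- c(A = "G", G = "A", C = "T", T = "C")

#' Kimura two-parameter distance of an aligned pair
#'
#' Over ungapped, non-N columns of a pairwise alignment, computes the
#' transition proportion P (A<->G, C<->T) and transversion proportion Q and
#' the K2P distance `K = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q))` in
#' substitutions per site. When either logarithm argument is non-positive
#' the distance is saturated and reported missing.
#'
#' @param seq_a,seq_b Equal-length gapped nucleotide strings
#'   (characters ACGTN and `-`).
#' @return List with `k3u`, `p_transition`, `q_transversion`, `n_sites`.
#' @export
k2p_distance <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(seq_b), "", fixed = TRUE)[[1]]
  if (length(a) != length(b)) stop("sequences differ in aligned length")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  n <- sum(ok)
  if (n == 0L) stop("no comparable sites")
  a <- a[ok]; b <- b[ok]
  diff <- a != b
  ts <- diff & TRANSITIONS[a] == b
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  k <- if (arg1 <= 0 || arg2 <= 0) NA_real_ else
    -0.5 * log(arg1 * sqrt(arg2))
  list(k3u = k, p_transition = P, q_transversion = Q, n_sites = n)
}

#' K2P distances for a table of aligned pairs
#'
#' @param pairs `data.frame` with `gene_id`, `seq_a`, `seq_b`.
#' @return `data.frame` with `gene_id`, `k3u`, `p_transition`,
#'   `q_transversion`, `n_sites`.
#' @export
k2p_table <- function(pairs) {
  res <- lapply(seq_len(nrow(pairs)),
                function(i) k2p_distance(pairs$seq_a[i], pairs$seq_b[i]))
  data.frame(gene_id = pairs$gene_id,
             k3u = vapply(res, `[[`, numeric(1), "k3u"),
             p_transition = vapply(res, `[[`, numeric(1), "p_transition"),
             q_transversion = vapply(res, `[[`, numeric(1),
                                     "q_transversion"),
             n_sites = vapply(res, `[[`, integer(1), "n_sites"),
             stringsAsFactors = FALSE)
}

#' Read aligned ortholog pairs from FASTA
#'
#' Records are named `<gene_id>|<species>`; each gene must have exactly two
#' records. The first species (alphabetically, or `focal` when given) is
#' returned as `seq_a`.
#'
#' @param path FASTA path (gapped sequences allowed).
#' @param focal Optional species tag to use as `seq_a`.
#' @return `data.frame` with `gene_id`, `seq_a`, `seq_b`.
#' @export
read_alignment_pairs <- function(path, focal = NULL) {
  ss <- Biostrings::readBStringSet(path)
  parts <- strsplit(names(ss), "|", fixed = TRUE)
  gene <- vapply(parts, `[[`, character(1), 1L)
  sp <- vapply(parts, `[[`, character(1), 2L)
  seqs <- as.character(ss)
  out <- lapply(split(seq_along(gene), gene), function(ix) {
    if (length(ix) != 2L) stop("gene without exactly two records: ",
                               gene[ix[1L]])
    if (!is.null(focal) && sp[ix[2L]] == focal) ix <- rev(ix)
    else if (is.null(focal)) ix <- ix[order(sp[ix])]
    list(gene_id = gene[ix[1L]], seq_a = unname(seqs[ix[1L]]),
         seq_b = unname(seqs[ix[2L]]))
  })
  data.frame(gene_id = vapply(out, `[[`, character(1), "gene_id"),
             seq_a = vapply(out, `[[`, character(1), "seq_a"),
             seq_b = vapply(out, `[[`, character(1), "seq_b"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read a MAF-like multiple alignment file
#'
#' Parses alignment blocks (`a` lines) and their `s` rows. The species of a
#' row is the prefix of the `src` field before the first dot; the remainder
#' is kept as `src_suffix` (used here to key blocks by gene).
#'
#' @param path MAF file path.
#' @return `data.frame` with `block`, `species`, `src_suffix`, `text`.
#' @export
read_maf <- function(path) {
  lines <- readLines(path)
  block <- 0L
  rows <- list()
  for (ln in lines) {
    if (startsWith(ln, "a")) block <- block + 1L
    else if (startsWith(ln, "s ")) {
      f <- strsplit(trimws(ln), "[ \t]+")[[1]]
      src <- f[2L]
      dot <- regexpr(".", src, fixed = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        block = block,
        species = if (dot > 0) substr(src, 1L, dot - 1L) else src,
        src_suffix = if (dot > 0) substr(src, dot + 1L, nchar(src)) else "",
        text = f[7L], stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) stop("no s-lines in ", path)
  do.call(rbind, rows)
}

#' Focal-lineage indel rates from one alignment block
#'
#' Strict unanimity parsimony: a maximal run of columns where the focal row
#' is gapped while every non-focal row has a base is a focal-specific
#' deletion; a run where the focal row has bases while every non-focal row
#' is gapped is a focal-specific insertion. Columns where non-focal rows
#' disagree are not counted and break runs. Rates are total event lengths
#' divided by the total number of aligned columns.
#'
#' @param block `data.frame` with `species` and `text` (equal-length rows).
#' @param focal Focal species tag.
#' @return List with `insertion_rate`, `deletion_rate`, `aligned_length`,
#'   `n_insertion_events`, `n_deletion_events`.
#' @export
indel_rates <- function(block, focal) {
  if (!focal %in% block$species) stop("focal species absent from block")
  others <- block[block$species != focal, , drop = FALSE]
  if (nrow(others) < 2L) stop("cannot polarize")
  if (length(unique(nchar(block$text))) != 1L)
    stop("alignment rows differ in length")
  mat <- do.call(rbind, strsplit(toupper(block$text), "", fixed = TRUE))
  foc <- mat[match(focal, block$species), ]
  oth <- mat[block$species != focal, , drop = FALSE]
  foc_gap <- foc == "-"
  oth_gap <- oth == "-"
  all_oth_base <- colSums(oth_gap) == 0L
  all_oth_gap <- colSums(!oth_gap) == 0L
  del <- foc_gap & all_oth_base
  ins <- !foc_gap & all_oth_gap
  L <- length(foc)
  r_del <- rle(del); r_ins <- rle(ins)
  list(insertion_rate = sum(ins) / L, deletion_rate = sum(del) / L,
       aligned_length = L,
       n_insertion_events = sum(r_ins$values),
       n_deletion_events = sum(r_del$values))
}

#' Per-gene focal-lineage indel rates from a MAF table
#'
#' Blocks are grouped by gene (the `src_suffix` of the rows) and
#' concatenated per gene before rate computation.
#'
#' @param maf `data.frame` from [read_maf()].
#' @param focal Focal species tag.
#' @return `data.frame` with `gene_id`, `insertion_rate`, `deletion_rate`,
#'   `aligned_length`.
#' @export
indel_table <- function(maf, focal) {
  genes <- split(maf, maf$src_suffix)
  res <- lapply(genes, function(g) {
    sp <- split(g, g$species)
    cat_rows <- data.frame(
      species = names(sp),
      text = vapply(sp, function(d) paste(d$text[order(d$block)],
                                          collapse = ""), character(1)),
      stringsAsFactors = FALSE)
    indel_rates(cat_rows, focal)
  })
  data.frame(gene_id = names(genes),
             insertion_rate = vapply(res, `[[`, numeric(1),
                                     "insertion_rate"),
             deletion_rate = vapply(res, `[[`, numeric(1), "deletion_rate"),
             aligned_length = vapply(res, `[[`, numeric(1),
                                     "aligned_length"),
             stringsAsFactors = FALSE, row.names = NULL)
}
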
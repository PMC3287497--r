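# Synthetic-genome generator: a complete toy data set (genome, annotation,
# two methylomes, target tables, expression matrices, ortholog alignments,
# cancer labels) whose statistical couplings are controlled by a Gaussian
# copula at configurable effect sizes.

#' Simulation configuration
#'
#' Effect-size defaults are the headline couplings the analysis is designed
#' to detect: Spearman -0.29 between promoter methylation and target count,
#' -0.47 between methylation and expression, +0.37 between promoter CpG O/E
#' and germline expression, +0.15 between methylation and the 3'UTR
#' substitution rate. All are configuration, not constants.
#'
#' @param n_genes Number of genes.
#' @param n_chromosomes Number of contigs the genes are spread over.
#' @param seed Integer seed; the whole bundle is a deterministic function of
#'   the configuration.
#' @param rho_meth_targets Population Spearman between promoter methylation
#'   propensity and miRNA target-site count.
#' @param rho_meth_expression Spearman between methylation propensity and
#'   cell-line expression.
#' @param rho_expression_targets Spearman between expression and target
#'   count (the mediated component picked up by partial correlation).
#' @param rho_cpgoe_expression_germline Spearman between promoter CpG O/E
#'   and mean germline-tissue expression.
#' @param rho_meth_k3u Spearman between methylation propensity and the true
#'   3'UTR K2P rate.
#' @param cpgoe_meth_loading Latent loading of CpG O/E on (minus) the
#'   methylation propensity.
#' @param dmr_count,dmr_effect Number of planted DMRs and the methylation
#'   uplift applied to cell line B inside them.
#' @param pmd_count,pmd_length,pmd_mean_meth Planted PMDs in cell line B:
#'   count, length (bases), per-site methylation probability inside.
#' @param coverage_mean Mean per-site read coverage (Poisson).
#' @param read_error Per-read bisulfite error rate.
#' @param background_meth Per-site methylation probability outside promoters.
#' @param background_cpg_spacing Spacing (bases, even) of background CpGs.
#' @param n_tissues_germline,n_tissues_somatic Tissue panel sizes.
#' @param eb_threshold Intensity threshold used for expression broadness.
#' @param nb_size,nt_mean,np_mean Negative-binomial shape and means of the
#'   two target-count sources.
#' @param mirna_pool Number of distinct miRNA identifiers.
#' @param cancer_fraction,dominant_fraction,ambiguous_count Cancer-gene
#'   label frequencies.
#' @param alt_transcript_fraction Fraction of genes given a benign second
#'   transcript (TSS within tolerance, same 3'UTR).
#' @param distant_tss_fraction Fraction given a distant alternative TSS
#'   (these genes should be removed by the ambiguity filter).
#' @param ambiguous_utr_fraction Fraction given an inconsistent 3'UTR
#'   (also removed by the filter).
#' @param k3u_min,k3u_range True K2P rates are
#'   `k3u_min + k3u_range * pnorm(latent)`.
#' @param insertion_rate,deletion_rate Mean focal-lineage indel rates in the
#'   3'UTR alignments.
#' @param locus_length Bases reserved per gene locus.
#' @return A validated config list of class `methmir_config`.
#' @export
simulation_config <- function(n_genes = 5000L, n_chromosomes = 4L, seed = 1L,
                              rho_meth_targets = -0.29,
                              rho_meth_expression = -0.47,
                              rho_expression_targets = 0.25,
                              rho_cpgoe_expression_germline = 0.37,
                              rho_meth_k3u = 0.15,
                              cpgoe_meth_loading = 0.8,
                              dmr_count = 20L, dmr_effect = 0.6,
                              pmd_count = 5L, pmd_length = 50000L,
                              pmd_mean_meth = 0.4,
                              coverage_mean = 20, read_error = 0.01,
                              background_meth = 0.95,
                              background_cpg_spacing = 20L,
                              n_tissues_germline = 20L,
                              n_tissues_somatic = 59L,
                              eb_threshold = 200,
                              nb_size = 5, nt_mean = 15, np_mean = 12,
                              mirna_pool = 300L,
                              cancer_fraction = 0.02,
                              dominant_fraction = 0.8,
                              ambiguous_count = 5L,
                              alt_transcript_fraction = 0.25,
                              distant_tss_fraction = 0.05,
                              ambiguous_utr_fraction = 0.03,
                              k3u_min = 0.03, k3u_range = 0.4,
                              insertion_rate = 0.02, deletion_rate = 0.03,
                              locus_length = 6000L) {
  cfg <- as.list(environment())
  rhos <- cfg[grep("^rho_", names(cfg))]
  stopifnot(all(abs(unlist(rhos)) < 1),
            n_genes >= 10L, n_chromosomes >= 1L,
            pmd_mean_meth > 0, pmd_mean_meth < 1,
            background_meth > 0, background_meth < 1,
            background_cpg_spacing >= 4L,
            background_cpg_spacing %% 2L == 0L,
            coverage_mean > 0, locus_length >= 6000L)
  class(cfg) <- "methmir_config"
  cfg
}

# Map a target Spearman correlation between a continuous latent and a count
# channel (qnbinom of the copula normal) to the latent Pearson correlation,
# correcting the tie-induced attenuation by Monte Carlo.
calibrate_count_coupling <- function(target, size, mu, n_mc = 100000L) {
  if (target == 0) return(0)
  z1 <- rnorm(n_mc); z0 <- rnorm(n_mc)
  realized <- function(r) {
    z2 <- r * z1 + sqrt(1 - r^2) * z0
    cor(z1, qnbinom(pnorm(z2), size = size, mu = mu), method = "spearman")
  }
  r <- 2 * sin(pi * target / 6)
  for (i in 1:3) {
    s <- realized(r)
    r <- r * target / s
    if (abs(r) > 0.995) {
      bound <- realized(sign(r) * 0.995)
      if (abs(target) > abs(bound))
        stop(sprintf(paste0("copula calibration infeasible: |rho| = %.3f ",
                            "requested, at most %.3f achievable for this ",
                            "count distribution"), abs(target), abs(bound)))
      r <- sign(r) * 0.995
    }
  }
  r
}

clipv <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# background repeat unit: one CpG at offset 0, AT filler; never ends in C
bg_unit <- function(spacing) paste0("CG", strrep("TA", (spacing - 2L) %/% 2L))

bg_string <- function(len, cache) substr(cache, 1L, len)

# Promoter sequence with an exact composition: length 1200, 300 C, 300 G,
# exactly k CpG dinucleotides, assembled from 2-mers that can never create a
# CpG across a junction.
build_promoter <- function(k) {
  tok <- c(rep("CG", k), rep("CT", 300L - k), rep("GA", 300L - k),
           sample(c("TA", "AT"), k, replace = TRUE))
  tok <- sample(tok)
  list(seq = paste(tok, collapse = ""),
       cpg_offsets = 2L * (which(tok == "CG") - 1L))
}

UTR_TOKENS <- c("CT", "CA", "GA", "GT", "TA", "AT", "AA", "TT")

build_utr <- function(len) {
  paste(sample(UTR_TOKENS, len %/% 2L, replace = TRUE), collapse = "")
}

# Evolve a sequence under the Kimura two-parameter process with total
# distance k and transition/transversion rate ratio 2 (alpha*t = k/2,
# beta*t = k/4).
evolve_k2p <- function(seq, k) {
  A <- exp(-k); B <- exp(-1.5 * k)
  p_same <- 0.25 + 0.25 * A + 0.5 * B
  p_ts <- 0.25 + 0.25 * A - 0.5 * B
  p_tv <- 0.25 - 0.25 * A            # per transversion target
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  cat <- sample.int(4L, n, replace = TRUE,
                    prob = c(p_same, p_ts, p_tv, p_tv))
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv1 <- c(A = "C", G = "C", C = "A", T = "A")
  tv2 <- c(A = "T", G = "T", C = "G", T = "G")
  out <- ch
  out[cat == 2L] <- ts_map[ch[cat == 2L]]
  out[cat == 3L] <- tv1[ch[cat == 3L]]
  out[cat == 4L] <- tv2[ch[cat == 4L]]
  paste(out, collapse = "")
}

#' Generate a synthetic bundle
#'
#' Draws per-gene latents from a Gaussian copula with the configured
#' couplings, then materialises every pipeline input: a genome with
#' composition-controlled promoters, a GTF annotation (with benign and
#' pathological alternative transcripts), two single-base methylome call
#' sets with planted DMRs and PMDs, probe-level tissue expression and
#' cell-line RPKM tables, two miRNA target tables, 3'UTR ortholog
#' alignments (pairwise for K2P, three-species MAF for indels), cancer-gene
#' labels, and a per-gene ground-truth table.
#'
#' @param config A [simulation_config()].
#' @return A list of class `methmir_bundle`; see the package vignette for
#'   the component inventory.
#' @export
simulate_bundle <- function(config = simulation_config()) {
  stopifnot(inherits(config, "methmir_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_genes

  ## ---- latent couplings -------------------------------------------------
  r_me <- 2 * sin(pi * cfg$rho_meth_expression / 6)
  r_mt <- calibrate_count_coupling(cfg$rho_meth_targets, cfg$nb_size,
                                   cfg$nt_mean)
  r_et <- calibrate_count_coupling(cfg$rho_expression_targets, cfg$nb_size,
                                   cfg$nt_mean)
  r_mp <- calibrate_count_coupling(cfg$rho_meth_targets, cfg$nb_size,
                                   cfg$np_mean)
  r_ep <- calibrate_count_coupling(cfg$rho_expression_targets, cfg$nb_size,
                                   cfg$np_mean)
  count_loadings <- function(r_mx, r_ex) {
    a <- (r_mx - r_me * r_ex) / (1 - r_me^2)
    b <- (r_ex - r_me * r_mx) / (1 - r_me^2)
    g2 <- 1 - a^2 - b^2 - 2 * a * b * r_me
    if (g2 < 0) stop("infeasible latent correlation structure")
    c(a, b, sqrt(g2))
  }
  lt <- count_loadings(r_mt, r_et)
  lp <- count_loadings(r_mp, r_ep)

  z_m <- rnorm(n)
  m_star <- pnorm(z_m)
  a_oe <- cfg$cpgoe_meth_loading
  z_oe <- -a_oe * z_m + sqrt(1 - a_oe^2) * rnorm(n)
  z_e <- r_me * z_m + sqrt(1 - r_me^2) * rnorm(n)
  z_t <- lt[1] * z_m + lt[2] * z_e + lt[3] * rnorm(n)
  z_p <- lp[1] * z_m + lp[2] * z_e + lp[3] * rnorm(n)
  d_g <- 2 * sin(pi * cfg$rho_cpgoe_expression_germline / 6)
  z_g <- d_g * z_oe + sqrt(1 - d_g^2) * rnorm(n)
  k_m <- 2 * sin(pi * cfg$rho_meth_k3u / 6)
  z_k <- k_m * z_m + sqrt(1 - k_m^2) * rnorm(n)

  nt <- qnbinom(pnorm(z_t), size = cfg$nb_size, mu = cfg$nt_mean)
  np <- qnbinom(pnorm(z_p), size = cfg$nb_size, mu = cfg$np_mean)
  oe_target <- 0.2 + 1.1 * pnorm(z_oe)
  k_cpg <- clipv(as.integer(round(75 * oe_target)), 5L, 140L)
  ul <- as.integer(round(25 * (nt + 2) * exp(0.25 * rnorm(n))))
  ul <- clipv(ul, pmax(60L, nt + 8L), 1500L)
  ul <- 2L * (ul %/% 2L)
  cds_len <- as.integer(3 * round(clipv(rnorm(n, 900, 300), 300, 2400) / 3))
  k3u_true <- cfg$k3u_min + cfg$k3u_range * pnorm(z_k)

  ## ---- genome layout ----------------------------------------------------
  gene_id <- sprintf("gene_%05d", seq_len(n))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  chrom_idx <- rep(seq_len(cfg$n_chromosomes), length.out = n)
  chrom_idx <- sort(chrom_idx)
  chrom <- sprintf("chr%d", chrom_idx)
  locus_idx <- stats::ave(seq_len(n), chrom_idx, FUN = seq_along) - 1L
  L0 <- cfg$locus_length
  locus_start <- locus_idx * L0
  tx_len <- 200L + cds_len + ul

  tss <- ifelse(strand == "+", locus_start + 1200L,
                locus_start + (L0 - 1200L))
  prom_start <- ifelse(strand == "+", tss - 1000L, tss - 200L)
  prom_end <- prom_start + 1200L
  tx_start <- ifelse(strand == "+", tss, tss + 1L - tx_len)
  tx_end <- ifelse(strand == "+", tss + tx_len, tss + 1L)
  utr_start <- ifelse(strand == "+", tx_end - ul, tx_start)
  utr_end <- utr_start + ul
  cds_start <- ifelse(strand == "+", tx_start + 200L, utr_end)
  cds_end <- cds_start + cds_len

  sp <- as.integer(cfg$background_cpg_spacing)
  bg_cache <- strrep(bg_unit(sp), ceiling(L0 / sp) + 1L)
  locus_seq <- character(n)
  prom_cpg <- vector("list", n)
  utr_seq <- character(n)
  for (i in seq_len(n)) {
    pr <- build_promoter(k_cpg[i])
    utr_seq[i] <- build_utr(ul[i])
    if (strand[i] == "+") {
      seg <- c(bg_string(200L, bg_cache), pr$seq,
               bg_string(cds_len[i], bg_cache), utr_seq[i],
               bg_string(L0 - 1400L - cds_len[i] - ul[i], bg_cache))
    } else {
      lead <- (tx_start[i] - locus_start[i])
      gap <- cds_len[i] - 1L
      seg <- c(bg_string(lead, bg_cache), utr_seq[i],
               bg_string(gap, bg_cache), pr$seq,
               bg_string(200L, bg_cache))
    }
    locus_seq[i] <- paste(seg, collapse = "")
    prom_cpg[[i]] <- prom_start[i] + pr$cpg_offsets
  }
  chroms <- vapply(split(locus_seq, chrom_idx), paste, character(1),
                   collapse = "")
  names(chroms) <- sprintf("chr%d", sort(unique(chrom_idx)))
  genome <- Biostrings::DNAStringSet(chroms)
  chrom_lengths <- setNames(Biostrings::width(genome), names(genome))

  ## ---- CpG site inventory ----------------------------------------------
  bg_offsets <- function(len) {
    if (len >= 2L) seq(0L, len - 2L, by = sp) else integer(0)
  }
  site_list <- vector("list", n)
  for (i in seq_len(n)) {
    s0 <- locus_start[i]
    if (strand[i] == "+") {
      bg <- c(s0 + bg_offsets(200L),
              s0 + 1400L + bg_offsets(cds_len[i]),
              s0 + 1400L + cds_len[i] + ul[i] +
                bg_offsets(L0 - 1400L - cds_len[i] - ul[i]))
    } else {
      lead <- tx_start[i] - locus_start[i]
      bg <- c(s0 + bg_offsets(lead),
              utr_end[i] + bg_offsets(cds_len[i] - 1L),
              s0 + L0 - 200L + bg_offsets(200L))
    }
    site_list[[i]] <- data.table(
      chrom = chrom[i],
      pos = c(prom_cpg[[i]], as.integer(bg)),
      gene_idx = c(rep(i, length(prom_cpg[[i]])),
                   rep(NA_integer_, length(bg))))
  }
  sites <- data.table::rbindlist(site_list)
  sites[, pos := as.integer(pos)]
  p_base <- ifelse(is.na(sites$gene_idx), cfg$background_meth,
                   m_star[sites$gene_idx])

  ## ---- planted regions --------------------------------------------------
  pmd_truth <- plant_pmds(cfg, chrom_lengths)
  in_pmd_site <- region_member(sites$chrom, sites$pos, pmd_truth)
  gene_in_pmd <- region_overlap(chrom, prom_start, prom_end, pmd_truth)

  # DMRs are planted at CpG-rich hypomethylated promoters (mirroring
  # CGI-associated developmental DMRs), away from planted PMDs
  dmr_eligible <- which(m_star < 0.35 & k_cpg >= 40L & !gene_in_pmd)
  if (length(dmr_eligible) < cfg$dmr_count)
    stop("not enough hypomethylated genes to plant the requested DMRs")
  dmr_genes <- sort(sample(dmr_eligible, cfg$dmr_count))
  dmr_truth <- data.frame(
    chrom = chrom[dmr_genes],
    start = (prom_start[dmr_genes] %/% 1000L) * 1000L,
    end = ((prom_end[dmr_genes] + 999L) %/% 1000L) * 1000L,
    gene_id = gene_id[dmr_genes], stringsAsFactors = FALSE)
  in_dmr_site <- region_member(sites$chrom, sites$pos, dmr_truth)
  gene_in_dmr <- region_overlap(chrom, prom_start, prom_end, dmr_truth)

  p_a <- p_base
  p_b <- p_base
  p_b[in_pmd_site] <- cfg$pmd_mean_meth
  p_b[in_dmr_site] <- clipv(p_base[in_dmr_site] + cfg$dmr_effect, 0, 0.95)

  calls_a <- draw_calls(sites, p_a, cfg)
  calls_b <- draw_calls(sites, p_b, cfg)

  ## ---- annotation -------------------------------------------------------
  tx_class <- sample(c("none", "benign", "distant", "ambiguous"), n,
                     replace = TRUE,
                     prob = c(1 - cfg$alt_transcript_fraction -
                                cfg$distant_tss_fraction -
                                cfg$ambiguous_utr_fraction,
                              cfg$alt_transcript_fraction,
                              cfg$distant_tss_fraction,
                              cfg$ambiguous_utr_fraction))
  ann <- build_annotation(gene_id, chrom, strand, tss, tx_start, tx_end,
                          cds_start, cds_end, utr_start, utr_end, tx_class)

  ## ---- expression -------------------------------------------------------
  n_tis <- cfg$n_tissues_germline + cfg$n_tissues_somatic
  tis_labels <- c(sprintf("germline_%02d", seq_len(cfg$n_tissues_germline)),
                  sprintf("somatic_%02d", seq_len(cfg$n_tissues_somatic)))
  tissue_classes <- data.frame(
    label = tis_labels,
    class = rep(c("germline", "somatic"),
                c(cfg$n_tissues_germline, cfg$n_tissues_somatic)),
    stringsAsFactors = FALSE)
  th <- cfg$eb_threshold
  ad <- matrix(0, n, n_tis, dimnames = list(gene_id, tis_labels))
  for (j in seq_len(cfg$n_tissues_germline)) {
    ad[, j] <- th * exp(0.9 * (0.9 * z_g + sqrt(1 - 0.81) * rnorm(n)))
  }
  for (j in seq_len(cfg$n_tissues_somatic)) {
    ad[, cfg$n_tissues_germline + j] <-
      th * exp(0.9 * (0.5 * z_e + sqrt(0.75) * rnorm(n)) - 0.15)
  }
  probes <- build_probe_matrix(ad, gene_id)
  rpkm <- data.frame(gene_id = gene_id,
                     H1 = 10 * exp(1.1 * z_e),
                     IMR90 = 10 * exp(1.1 * (z_e + 0.15 * rnorm(n))),
                     stringsAsFactors = FALSE)

  ## ---- miRNA target tables ---------------------------------------------
  pool <- sprintf("miR-%03d", seq_len(cfg$mirna_pool))
  targets_mt2 <- build_site_table(gene_id, nt, ul, pool, "mirtarget2")
  pic <- lapply(seq_len(n), function(i) {
    if (np[i] == 0L) return(NULL)
    data.table(gene_id = gene_id[i],
               mirna_id = sample(pool, min(np[i], length(pool))),
               source = "pictar")
  })
  targets_pictar <- as.data.frame(data.table::rbindlist(pic))

  ## ---- 3'UTR evolution --------------------------------------------------
  mouse_utr <- vapply(seq_len(n),
                      function(i) evolve_k2p(utr_seq[i], k3u_true[i]),
                      character(1))
  pairs <- data.frame(gene_id = gene_id, seq_a = utr_seq, seq_b = mouse_utr,
                      stringsAsFactors = FALSE)
  maf <- build_maf(gene_id, utr_seq, cfg)

  ## ---- cancer labels ----------------------------------------------------
  n_cancer <- max(2L, round(cfg$cancer_fraction * n))
  score <- (rank(-m_star) + rank(nt)) / (2 * n)
  cancer_idx <- sample(n, n_cancer + cfg$ambiguous_count,
                       prob = exp(3 * score))
  amb_idx <- cancer_idx[seq_len(cfg$ambiguous_count)]
  main_idx <- setdiff(cancer_idx, amb_idx)
  n_dom <- round(cfg$dominant_fraction * length(main_idx))
  lab <- rep("recessive", length(main_idx))
  lab[seq_len(n_dom)] <- "dominant"
  cancer_labels <- data.frame(
    gene_id = c(gene_id[main_idx], gene_id[amb_idx]),
    label = c(lab, rep("ambiguous", length(amb_idx))),
    stringsAsFactors = FALSE)
  cancer_labels <- cancer_labels[order(cancer_labels$gene_id), ]
  row.names(cancer_labels) <- NULL

  truth <- data.frame(
    gene_id = gene_id, chrom = chrom, strand = strand, tss = tss,
    m_star = m_star, cpg_oe_true = k_cpg / 75, n_promoter_cpg = k_cpg,
    nt_true = nt, np_true = np, ul = ul,
    expr_latent = z_e, germline_latent = z_g, k3u_true = k3u_true,
    ins_rate_true = maf$truth$insertion_rate,
    del_rate_true = maf$truth$deletion_rate,
    in_dmr = gene_in_dmr, in_pmd = gene_in_pmd,
    cancer_label = ifelse(gene_id %in% cancer_labels$gene_id,
                          cancer_labels$label[match(gene_id,
                                                    cancer_labels$gene_id)],
                          "none"),
    tx_class = tx_class,
    filtered_expected = tx_class %in% c("distant", "ambiguous"),
    stringsAsFactors = FALSE)

  structure(list(
    config = cfg, genome = genome, chrom_lengths = chrom_lengths,
    transcripts = ann$transcripts, gtf_lines = ann$gtf_lines,
    calls_a = calls_a, calls_b = calls_b,
    probe_matrix = probes$matrix, probe_map = probes$map,
    tissue_classes = tissue_classes, rpkm = rpkm,
    targets_mirtarget2 = targets_mt2, targets_pictar = targets_pictar,
    utr_pairs = pairs, maf = maf$maf, maf_lines = maf$maf_lines,
    cancer_labels = cancer_labels,
    dmr_truth = dmr_truth, pmd_truth = pmd_truth, truth = truth
  ), class = "methmir_bundle")
}

plant_pmds <- function(cfg, chrom_lengths) {
  if (cfg$pmd_count == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  per <- data.frame(chrom = names(chrom_lengths),
                    len = as.integer(chrom_lengths))
  out <- list()
  grid <- 10000L
  placed <- 0L
  ci <- 1L
  occupied <- lapply(per$chrom, function(x) integer(0))
  names(occupied) <- per$chrom
  guard <- 0L
  while (placed < cfg$pmd_count && guard < 1000L) {
    guard <- guard + 1L
    row <- per[ci, ]
    ci <- ci %% nrow(per) + 1L
    nwin <- row$len %/% grid
    need <- ceiling(cfg$pmd_length / grid)
    if (nwin <= need + 2L) next
    w0 <- sample(nwin - need - 1L, 1L)
    wins <- w0:(w0 + need - 1L)
    if (any(wins %in% occupied[[row$chrom]])) next
    occupied[[row$chrom]] <- c(occupied[[row$chrom]],
                               (w0 - 1L):(w0 + need))
    out[[length(out) + 1L]] <- data.frame(
      chrom = row$chrom, start = (w0 - 1L) * grid,
      end = (w0 - 1L + need) * grid, stringsAsFactors = FALSE)
    placed <- placed + 1L
  }
  if (placed < cfg$pmd_count) stop("could not place the requested PMDs")
  do.call(rbind, out)
}

region_member <- function(chrom, pos, regions) {
  out <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(regions))) {
    out <- out | (chrom == regions$chrom[i] & pos >= regions$start[i] &
                    pos < regions$end[i])
  }
  out
}

region_overlap <- function(chrom, start, end, regions) {
  out <- rep(FALSE, length(start))
  for (i in seq_len(nrow(regions))) {
    out <- out | (chrom == regions$chrom[i] & start < regions$end[i] &
                    end > regions$start[i])
  }
  out
}

draw_calls <- function(sites, p, cfg) {
  ns <- nrow(sites)
  state <- rbinom(ns, 1L, p)
  tot <- rpois(ns, cfg$coverage_mean)
  keep <- tot >= 1L
  mc <- integer(ns)
  mc[keep] <- rbinom(sum(keep), tot[keep],
                     ifelse(state[keep] == 1L, 1 - cfg$read_error,
                            cfg$read_error))
  data.frame(chrom = sites$chrom[keep], pos = sites$pos[keep],
             strand = "+", context = "CG", mc_reads = mc[keep],
             total_reads = tot[keep], stringsAsFactors = FALSE)
}

build_annotation <- function(gene_id, chrom, strand, tss, tx_start, tx_end,
                             cds_start, cds_end, utr_start, utr_end,
                             tx_class) {
  n <- length(gene_id)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    t1 <- paste0(gene_id[i], ".t1")
    main <- data.frame(
      transcript_id = t1, gene_id = gene_id[i], chrom = chrom[i],
      strand = strand[i], feature = c("transcript", "CDS",
                                      "three_prime_utr"),
      start = c(tx_start[i], cds_start[i], utr_start[i]),
      end = c(tx_end[i], cds_end[i], utr_end[i]), stringsAsFactors = FALSE)
    if (tx_class[i] != "none") {
      t2 <- paste0(gene_id[i], ".t2")
      delta <- switch(tx_class[i],
                      benign = sample(0:150, 1L),
                      distant = sample(300:800, 1L),
                      ambiguous = 0L)
      if (strand[i] == "+") {
        a_tx_start <- tx_start[i] + delta; a_tx_end <- tx_end[i]
      } else {
        a_tx_start <- tx_start[i]; a_tx_end <- tx_end[i] - delta
      }
      a_cds <- c(cds_start[i] + 90L, cds_end[i] - 90L)
      a_utr <- c(utr_start[i], utr_end[i])
      if (tx_class[i] == "ambiguous") {
        ulen <- utr_end[i] - utr_start[i]
        shift <- max(1L, as.integer(round(0.6 * ulen)))
        if (strand[i] == "+") a_utr <- a_utr - shift else a_utr <- a_utr +
            shift
      }
      alt <- data.frame(
        transcript_id = t2, gene_id = gene_id[i], chrom = chrom[i],
        strand = strand[i], feature = c("transcript", "CDS",
                                        "three_prime_utr"),
        start = c(a_tx_start, a_cds[1L], a_utr[1L]),
        end = c(a_tx_end, a_cds[2L], a_utr[2L]), stringsAsFactors = FALSE)
      main <- rbind(main, alt)
    }
    rows[[i]] <- main
  }
  feat <- do.call(rbind, rows)
  gtf_lines <- sprintf(
    "%s\tmethmir_sim\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    feat$chrom, feat$feature, feat$start + 1L, feat$end, feat$strand,
    feat$gene_id, feat$transcript_id)

  # transcript table in the reader's output format
  dt <- as.data.table(feat)
  tx <- dt[dt$feature == "transcript", ]
  cds <- dt[dt$feature == "CDS",
            list(cds_length = sum(end - start)), by = "transcript_id"]
  utr <- dt[dt$feature == "three_prime_utr",
            list(utr3_start = min(start), utr3_end = max(end),
                 utr3_length = sum(end - start)), by = "transcript_id"]
  out <- data.table(transcript_id = tx$transcript_id, gene_id = tx$gene_id,
                    chrom = tx$chrom, strand = tx$strand,
                    tx_start = tx$start, tx_end = tx$end,
                    tss = ifelse(tx$strand == "+", tx$start, tx$end - 1L))
  out <- merge(out, cds, by = "transcript_id", all.x = TRUE)
  out <- merge(out, utr, by = "transcript_id", all.x = TRUE)
  out$cds_length[is.na(out$cds_length)] <- 0L
  transcripts <- as.data.frame(out[order(out$gene_id, out$transcript_id), ])
  list(transcripts = transcripts, gtf_lines = gtf_lines)
}

build_probe_matrix <- function(ad, gene_id) {
  n <- nrow(ad)
  has_b <- runif(n) < 0.2
  decoy <- runif(n) < 0.1
  decoy_sfx <- sample(c("_x_at", "_s_at"), n, replace = TRUE)
  mats <- list(ad)
  ids <- list(sprintf("p%05d_at", seq_len(n)))
  genes <- list(gene_id)
  if (any(has_b)) {
    noise <- matrix(exp(0.05 * rnorm(sum(has_b) * ncol(ad))), sum(has_b))
    mats[[2]] <- ad[has_b, , drop = FALSE] * noise
    ids[[2]] <- sprintf("p%05db_at", which(has_b))
    genes[[2]] <- gene_id[has_b]
  }
  if (any(decoy)) {
    k <- length(mats) + 1L
    mats[[k]] <- ad[decoy, , drop = FALSE] * 8
    ids[[k]] <- sprintf("p%05d%s", which(decoy), decoy_sfx[decoy])
    genes[[k]] <- gene_id[decoy]
  }
  m <- do.call(rbind, mats)
  rownames(m) <- unlist(ids)
  # replicate columns for the first three tissues
  reps <- m[, 1:3, drop = FALSE] *
    matrix(exp(0.05 * rnorm(nrow(m) * 3L)), nrow(m))
  colnames(reps) <- colnames(m)[1:3]
  m <- cbind(m, reps)
  list(matrix = m,
       map = data.frame(probe_id = unlist(ids), gene_id = unlist(genes),
                        stringsAsFactors = FALSE))
}

build_site_table <- function(gene_id, nt, ul, pool, source) {
  n <- length(gene_id)
  rows <- lapply(seq_len(n), function(i) {
    if (nt[i] == 0L) return(NULL)
    data.table(gene_id = gene_id[i],
               mirna_id = sample(pool, nt[i], replace = TRUE),
               source = source,
               position = sort(sample.int(ul[i] - 7L, nt[i]) - 1L))
  })
  tab <- as.data.frame(data.table::rbindlist(rows))
  if (nrow(tab) > 1L) {
    dup <- tab[sample(nrow(tab), max(1L, round(0.02 * nrow(tab)))), ]
    tab <- rbind(tab, dup)
    tab <- tab[order(tab$gene_id, tab$position), ]
    row.names(tab) <- NULL
  }
  tab
}

build_maf <- function(gene_id, utr_seq, cfg) {
  n <- length(gene_id)
  lines_out <- vector("list", n)
  ins_rate <- numeric(n); del_rate <- numeric(n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    h <- strsplit(utr_seq[i], "", fixed = TRUE)[[1]]
    ulen <- length(h)
    ins_len <- round(cfg$insertion_rate * ulen * exp(0.4 * rnorm(1)))
    del_len <- round(cfg$deletion_rate * ulen * exp(0.4 * rnorm(1)))
    ins_len <- min(ins_len, ulen %/% 4L)
    del_len <- min(del_len, ulen %/% 4L)
    # insertion: a run of focal bases absent from the others
    ins_at <- if (ins_len > 0L) sample(ulen - ins_len, 1L) else 0L
    # deletion: gap columns in the focal row, inserted between two bases
    del_at <- sample(ulen - 1L, 1L)
    if (ins_len > 0L && del_at >= ins_at && del_at < ins_at + ins_len)
      del_at <- ins_at + ins_len   # keep events disjoint
    ncol_aln <- ulen + del_len
    hrow <- append(h, rep("-", del_len), after = del_at)
    oth <- h
    oth_mut <- sample(ulen, max(0L, round(0.02 * ulen)))
    oth[oth_mut] <- sample(c("A", "C", "G", "T"), length(oth_mut),
                           replace = TRUE)
    if (ins_len > 0L) oth[ins_at:(ins_at + ins_len - 1L)] <- "-"
    fill <- sample(c("A", "C", "G", "T"), del_len, replace = TRUE)
    orow1 <- append(oth, fill, after = del_at)
    oth2 <- oth
    oth2_mut <- sample(ulen, max(0L, round(0.02 * ulen)))
    keepb <- oth2[oth2_mut] != "-"
    oth2[oth2_mut[keepb]] <- sample(c("A", "C", "G", "T"), sum(keepb),
                                    replace = TRUE)
    orow2 <- append(oth2, fill, after = del_at)
    texts <- c(paste(hrow, collapse = ""), paste(orow1, collapse = ""),
               paste(orow2, collapse = ""))
    sp <- c("hsa", "ptr", "mml")
    ins_rate[i] <- ins_len / ncol_aln
    del_rate[i] <- del_len / ncol_aln
    sizes <- nchar(gsub("-", "", texts, fixed = TRUE))
    lines_out[[i]] <- c(sprintf("a score=%d", i),
                        sprintf("s %s.%s 0 %d + %d %s", sp, gene_id[i],
                                sizes, sizes, texts), "")
    rows[[i]] <- data.frame(block = i, species = sp,
                            src_suffix = gene_id[i], text = texts,
                            stringsAsFactors = FALSE)
  }
  list(maf = do.call(rbind, rows),
       maf_lines = c("##maf version=1", unlist(lines_out)),
       truth = data.frame(gene_id = gene_id, insertion_rate = ins_rate,
                          deletion_rate = del_rate,
                          stringsAsFactors = FALSE))
}

#' Ground-truth report for a synthetic bundle
#'
#' Per-gene latents, planted-region memberships and labels for test
#' assertions; one row per emitted gene.
#'
#' @param bundle A `methmir_bundle`.
#' @return The ground-truth `data.frame`.
#' @export
ground_truth_report <- function(bundle) {
  stopifnot(inherits(bundle, "methmir_bundle"))
  bundle$truth
}
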
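# Pipeline orchestration: join all per-gene measures into the gene feature
# table and run the correlation / group-comparison battery.

join_feature <- function(base, df, name) {
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in input '", name, "'")
  merge(base, df, by = "gene_id", all.x = TRUE, sort = TRUE)
}

#' Build the per-gene feature table
#'
#' Left-joins every per-gene measure onto the filtered gene set (genes
#' failing the annotation filters are absent, not null-rowed). Any input
#' with a duplicated `gene_id` raises an error naming that input.
#'
#' @param gene_models Filtered `data.frame` from [build_gene_models()] /
#'   [filter_unambiguous_genes()].
#' @param inputs Named list of `data.frame`s, each with a `gene_id` column;
#'   every other column is carried into the table.
#' @return One row per gene; missingness is explicit (`NA`).
#' @export
build_feature_table <- function(gene_models, inputs) {
  base <- gene_models[, c("gene_id", "chrom", "strand", "ul")]
  for (nm in names(inputs)) base <- join_feature(base, inputs[[nm]], nm)
  base
}

battery_pair <- function(features, meth_col, burden_col, covariate_col) {
  for (cl in c(meth_col, burden_col, covariate_col))
    if (!cl %in% names(features)) stop("missing column '", cl, "'")
  x <- features[[meth_col]]; y <- features[[burden_col]]
  z <- features[[covariate_col]]
  ok <- complete.cases(x, y)
  if (sum(ok) >= 3L && stats::var(y[ok]) == 0)
    stop("zero variance in column '", burden_col, "'")
  if (sum(ok) >= 3L && stats::var(x[ok]) == 0)
    stop("zero variance in column '", meth_col, "'")
  raw <- spearman_cor(x[ok], y[ok])
  ok3 <- complete.cases(x, y, z)
  part <- partial_spearman(x[ok3], y[ok3], z[ok3],
                           conditioned_on = covariate_col)
  data.frame(meth = meth_col, burden = burden_col,
             rho = raw$rho, n = raw$n, p_value = raw$p_value,
             partial_rho = part$rho, partial_n = part$n,
             partial_p = part$p_value, covariate = covariate_col,
             stringsAsFactors = FALSE)
}

#' Correlation battery over methylation measures and burden measures
#'
#' For every methylation measure (mCG/CG per cell line, CpG O/E) crossed
#' with every target-burden measure (Nt, Np, UL): the raw Spearman
#' correlation and the first-order partial Spearman correlation given an
#' expression covariate. The covariate defaults to the same cell line's
#' expression for the mCG/CG rows and to mean germline expression for the
#' CpG O/E row.
#'
#' @param features Gene feature table from [build_feature_table()].
#' @param meth_cols Named character vector: methylation column ->
#'   covariate column.
#' @param burden_cols Burden column names.
#' @return `data.frame`, one row per (methylation, burden) pair.
#' @export
table1_battery <- function(features,
                           meth_cols = c(mcg_cg_h1 = "rpkm_h1",
                                         mcg_cg_imr90 = "rpkm_imr90",
                                         cpg_oe = "mean_germline_ad"),
                           burden_cols = c("nt", "np", "ul")) {
  rows <- list()
  for (m in names(meth_cols)) for (b in burden_cols) {
    rows[[length(rows) + 1L]] <- battery_pair(features, m, b, meth_cols[[m]])
  }
  do.call(rbind, rows)
}

#' Compare genes inside vs outside a region set
#'
#' Group means of promoter methylation and target count for genes whose
#' promoter lies in the flagged regions vs all other genes, with two-sided
#' Mann-Whitney p-values.
#'
#' @param features Gene feature table with a logical membership column.
#' @param flag_col Name of the membership column (e.g. `"in_dmr"`).
#' @param meth_col,burden_col Measure columns (defaults `"mcg_cg_h1"`,
#'   `"nt"`).
#' @return `data.frame` with one row per measure: group means, sizes, p.
#' @export
region_comparison <- function(features, flag_col, meth_col = "mcg_cg_h1",
                              burden_col = "nt") {
  flag <- features[[flag_col]]
  if (is.null(flag)) stop("missing column '", flag_col, "'")
  rows <- lapply(c(meth_col, burden_col), function(cl) {
    v <- features[[cl]]
    vin <- v[flag & !is.na(v)]; vout <- v[!flag & !is.na(v)]
    if (length(vin) == 0L || length(vout) == 0L) stop("empty group")
    mw <- mann_whitney(vin, vout, alternative = "two.sided")
    data.frame(measure = cl, mean_in = mean(vin), mean_out = mean(vout),
               n_in = length(vin), n_out = length(vout),
               p_value = mw$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cancer-gene comparison report
#'
#' Group means (all cancer genes, dominant, recessive, others) of target
#' count, promoter methylation, CpG O/E and promoter CGI count;
#' Mann-Whitney tests of cancer vs others on each continuous measure; and a
#' chi-square test on promoter CGI occurrence (at least one island vs none)
#' between dominant and recessive genes. Genes with an ambiguous label are
#' kept in the all-cancer group but excluded from the dominant/recessive
#' rows. A label class with no genes is omitted with a warning.
#'
#' @param features Gene feature table with a `cancer_label` column
#'   (`dominant` / `recessive` / `ambiguous` / `none`).
#' @param measures Continuous measure columns.
#' @return List with `summary` (group x measure means and sizes), `tests`
#'   (cancer vs others Mann-Whitney) and `cgi_chi2`.
#' @export
cancer_comparison <- function(features,
                              measures = c("nt", "mcg_cg_h1", "cpg_oe",
                                           "cgi_count")) {
  lab <- features$cancer_label
  if (is.null(lab)) stop("missing column 'cancer_label'")
  lab[is.na(lab)] <- "none"
  groups <- list(cancer = lab != "none",
                 dominant = lab == "dominant",
                 recessive = lab == "recessive",
                 others = lab == "none")
  present <- vapply(groups, any, logical(1))
  if (!all(present)) {
    warning("label class absent: ",
            paste(names(groups)[!present], collapse = ", "))
    groups <- groups[present]
  }
  summary <- do.call(rbind, lapply(names(groups), function(g) {
    sel <- groups[[g]]
    do.call(rbind, lapply(measures, function(cl) {
      v <- features[[cl]][sel]
      data.frame(group = g, measure = cl, mean = mean(v, na.rm = TRUE),
                 n = sum(!is.na(v)), stringsAsFactors = FALSE)
    }))
  }))
  tests <- NULL
  if (all(c("cancer", "others") %in% names(groups))) {
    tests <- do.call(rbind, lapply(measures, function(cl) {
      a <- features[[cl]][groups$cancer]
      b <- features[[cl]][groups$others]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      mw <- mann_whitney(a, b, alternative = "two.sided")
      data.frame(measure = cl, mean_cancer = mean(a), mean_others = mean(b),
                 p_value = mw$p_value, stringsAsFactors = FALSE)
    }))
  }
  cgi_chi2 <- NULL
  if (all(c("dominant", "recessive") %in% names(groups)) &&
      "cgi_count" %in% names(features)) {
    cg <- features$cgi_count
    tab <- rbind(dominant = c(sum(cg[groups$dominant] >= 1, na.rm = TRUE),
                              sum(cg[groups$dominant] == 0, na.rm = TRUE)),
                 recessive = c(sum(cg[groups$recessive] >= 1, na.rm = TRUE),
                               sum(cg[groups$recessive] == 0,
                                   na.rm = TRUE)))
    colnames(tab) <- c("cgi", "no_cgi")
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0))
      cgi_chi2 <- chi_square_2x2(tab)
  }
  list(summary = summary, tests = tests, cgi_chi2 = cgi_chi2)
}

#' Run the full analysis pipeline on a bundle
#'
#' Annotation filtering, promoter methylation (both cell lines), promoter
#' composition (CpG O/E, CGI count), expression summaries, target counts,
#' 3'UTR evolutionary rates, optional DMR/PMD segmentation with gene
#' assignment, the feature-table join and the full statistical battery.
#' Deterministic given the bundle: no randomness is used.
#'
#' @param bundle A `methmir_bundle` (from [simulate_bundle()]) or the list
#'   returned by [read_bundle()].
#' @param call_method Site caller for mCG/CG (default `"binomial"`).
#' @param segment Run DMR/PMD segmentation? (default `TRUE`).
#' @param dmr_window,dmr_fdr,pmd_window,pmd_threshold,pmd_min_length
#'   Segmentation parameters.
#' @param tss_tolerance,min_utr_overlap Annotation-filter parameters.
#' @param min_coverage Minimum site coverage for mCG/CG.
#' @param verbose Log stage-by-stage counts via [message()]?
#' @return List with `gene_models`, `features`, `table1`, `dmr`, `pmd`,
#'   `dmr_comparison`, `pmd_comparison`, `cancer`, `per_tissue`.
#' @export
run_pipeline <- function(bundle, call_method = "binomial", segment = TRUE,
                         dmr_window = 1000L, dmr_fdr = 0.05,
                         pmd_window = 10000L, pmd_threshold = 0.70,
                         pmd_min_length = 10000L,
                         tss_tolerance = 200L, min_utr_overlap = 0.8,
                         min_coverage = 1L, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)

  tx <- bundle$transcripts
  gm <- build_gene_models(tx, chrom_lengths = bundle$chrom_lengths)
  say(nrow(gm), " gene models from ", nrow(tx), " transcripts")
  gm <- filter_unambiguous_genes(gm, tx, tss_tolerance = tss_tolerance,
                                 min_utr_overlap = min_utr_overlap)
  say(nrow(gm), " genes after TSS/3'UTR ambiguity filter")

  cpg <- find_cpg_sites(bundle$genome)
  meth_a_called <- call_methylated_sites(bundle$calls_a,
                                         method = call_method)
  meth_b_called <- call_methylated_sites(bundle$calls_b,
                                         method = call_method)
  ma <- promoter_mcg_cg(gm, cpg, bundle$calls_a, meth_a_called,
                        min_coverage = min_coverage)
  mb <- promoter_mcg_cg(gm, cpg, bundle$calls_b, meth_b_called,
                        min_coverage = min_coverage)
  meth_a <- data.frame(gene_id = ma$gene_id, mcg_cg_h1 = ma$mcg_cg,
                       n_cpg_h1 = ma$n_cpg_covered)
  meth_b <- data.frame(gene_id = mb$gene_id, mcg_cg_imr90 = mb$mcg_cg,
                       n_cpg_imr90 = mb$n_cpg_covered)

  prom_seq <- Biostrings::subseq(bundle$genome[gm$chrom],
                                 start = gm$promoter_start + 1L,
                                 end = gm$promoter_end)
  comp <- cpg_oe(prom_seq)
  comp_df <- data.frame(gene_id = gm$gene_id, cpg_oe = comp$cpg_oe,
                        cgi_count = count_cgis(as.character(prom_seq)))

  collapsed <- collapse_probes(bundle$probe_matrix, bundle$probe_map)
  eb <- expression_broadness(collapsed,
                             threshold = if (!is.null(bundle$config))
                               bundle$config$eb_threshold else 200)
  germ <- bundle$tissue_classes$label[
    bundle$tissue_classes$class == "germline"]
  germ <- intersect(germ, colnames(collapsed))
  eb$mean_germline_ad <- rowMeans(collapsed[, germ, drop = FALSE])[
    match(eb$gene_id, rownames(collapsed))]
  rpkm <- data.frame(gene_id = bundle$rpkm$gene_id,
                     rpkm_h1 = bundle$rpkm[[2L]],
                     rpkm_imr90 = bundle$rpkm[[3L]])

  nt <- count_target_sites(bundle$targets_mirtarget2,
                           source = "mirtarget2", genes = gm$gene_id,
                           genome_wide = TRUE)
  names(nt)[2L] <- "nt"
  np <- count_target_sites(bundle$targets_pictar, source = "pictar",
                           genes = gm$gene_id, genome_wide = TRUE)
  names(np)[2L] <- "np"

  k2p <- k2p_table(bundle$utr_pairs)[, c("gene_id", "k3u")]
  indels <- indel_table(bundle$maf, focal = "hsa")[,
    c("gene_id", "insertion_rate", "deletion_rate")]

  dmr <- NULL; pmd <- NULL
  flags <- data.frame(gene_id = gm$gene_id, in_dmr = FALSE, in_pmd = FALSE)
  if (segment) {
    dmr <- detect_dmrs(bundle$calls_a, bundle$calls_b, window = dmr_window,
                       fdr = dmr_fdr, call_method = call_method)
    pmd <- detect_pmds(bundle$calls_b, window = pmd_window,
                       threshold = pmd_threshold,
                       min_length = pmd_min_length)
    flags$in_dmr <- assign_genes_to_regions(gm, dmr)
    flags$in_pmd <- assign_genes_to_regions(gm, pmd)
    say(nrow(dmr), " DMRs, ", nrow(pmd), " PMDs; ", sum(flags$in_dmr),
        " / ", sum(flags$in_pmd), " genes assigned")
  }

  labels <- data.frame(gene_id = gm$gene_id, cancer_label = "none",
                       stringsAsFactors = FALSE)
  if (!is.null(bundle$cancer_labels)) {
    hit <- match(labels$gene_id, bundle$cancer_labels$gene_id)
    labels$cancer_label[!is.na(hit)] <-
      bundle$cancer_labels$label[hit[!is.na(hit)]]
  }

  features <- build_feature_table(gm, list(
    mcg_cg_h1 = meth_a, mcg_cg_imr90 = meth_b, composition = comp_df,
    expression = eb, rpkm = rpkm, targets_mirtarget2 = nt,
    targets_pictar = np, k2p = k2p, indels = indels, regions = flags,
    cancer = labels))
  say(nrow(features), " rows in the gene feature table")

  table1 <- table1_battery(features)
  dmr_cmp <- if (segment && any(features$in_dmr))
    region_comparison(features, "in_dmr", meth_col = "mcg_cg_h1") else NULL
  pmd_cmp <- if (segment && any(features$in_pmd))
    region_comparison(features, "in_pmd", meth_col = "mcg_cg_imr90")
    else NULL
  cancer <- cancer_comparison(features)
  per_tissue <- per_tissue_correlation(
    setNames(features$cpg_oe, features$gene_id), collapsed,
    bundle$tissue_classes)

  list(gene_models = gm, features = features, table1 = table1,
       dmr = dmr, pmd = pmd, dmr_comparison = dmr_cmp,
       pmd_comparison = pmd_cmp, cancer = cancer,
       per_tissue = per_tissue)
}
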
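# Rank-based statistical battery: Spearman and first-order partial Spearman
# correlation, Mann-Whitney U, Fisher's exact and chi-square tests, and the
# per-tissue correlation profile.

spearman_rho <- function(x, y) {
  cor(rank(x), rank(y))   # midranks; Pearson on ranks
}

fisher_z_ci <- function(rho, n, conf_level = 0.95, n_conditioned = 0L) {
  # Fieller-adjusted Fisher z interval for Spearman's rho
  eff <- n - n_conditioned
  if (eff <= 3 || abs(rho) >= 1) return(c(NA_real_, NA_real_))
  se <- 1.03 / sqrt(eff - 3)
  zq <- qnorm(1 - (1 - conf_level) / 2)
  z <- atanh(rho)
  tanh(c(z - zq * se, z + zq * se))
}

#' Spearman rank correlation with confidence interval
#'
#' Rho is Pearson's correlation of midranks. The p-value uses the
#' t-approximation with n - 2 degrees of freedom; the confidence interval is
#' a Fisher z-transform interval with standard error `1.03 / sqrt(n - 3)`.
#' Pairs with a missing value in either vector are removed first.
#'
#' @param x,y Numeric vectors of equal length.
#' @param conf_level Confidence level (default 0.95).
#' @param conditioned_on Optional label carried into the result.
#' @return One-row `data.frame`: `rho`, `n`, `p_value`, `ci_low`, `ci_high`,
#'   `conditioned_on`.
#' @export
spearman_cor <- function(x, y, conf_level = 0.95, conditioned_on = NA) {
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) stop("zero variance")
  rho <- spearman_rho(x, y)
  p <- rho_t_pvalue(rho, df = n - 2L)
  ci <- fisher_z_ci(rho, n, conf_level)
  data.frame(rho = rho, n = n, p_value = p, ci_low = ci[1L],
             ci_high = ci[2L], conditioned_on = conditioned_on,
             stringsAsFactors = FALSE)
}

rho_t_pvalue <- function(rho, df) {
  if (abs(rho) >= 1) return(0)
  t <- rho * sqrt(df / (1 - rho^2))
  2 * pt(-abs(t), df)
}

#' First-order partial Spearman correlation
#'
#' Partials out `z` from the rank correlation of `x` and `y` with the
#' first-order formula
#' `rho_xy.z = (rho_xy - rho_xz * rho_yz) / sqrt((1 - rho_xz^2) * (1 - rho_yz^2))`
#' on pairwise Spearman correlations; the p-value uses
#' `t = rho * sqrt((n - 3) / (1 - rho^2))` with n - 3 degrees of freedom.
#'
#' @param x,y,z Numeric vectors of equal length (complete cases used,
#'   n >= 4).
#' @param conf_level Confidence level for the Fisher-z interval.
#' @param conditioned_on Label for the covariate (default `"z"`).
#' @return One-row `data.frame` as in [spearman_cor()].
#' @export
partial_spearman <- function(x, y, z, conf_level = 0.95,
                             conditioned_on = "z") {
  stopifnot(length(x) == length(y), length(y) == length(z))
  ok <- complete.cases(x, y, z)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete triples")
  if (stats::var(x) == 0 || stats::var(y) == 0 || stats::var(z) == 0)
    stop("zero variance")
  rxy <- spearman_rho(x, y)
  rxz <- spearman_rho(x, z)
  ryz <- spearman_rho(y, z)
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12)
    stop("degenerate conditioning")
  rho <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  t <- rho * sqrt((n - 3) / (1 - rho^2))
  p <- 2 * pt(-abs(t), n - 3)
  ci <- fisher_z_ci(rho, n, conf_level, n_conditioned = 1L)
  data.frame(rho = rho, n = n, p_value = p, ci_low = ci[1L],
             ci_high = ci[2L], conditioned_on = conditioned_on,
             stringsAsFactors = FALSE)
}

#' Mann-Whitney U test
#'
#' U statistic with midrank ties. The p-value is exact when the smaller
#' sample has at most 8 observations and there are no ties, and uses the
#' normal approximation with tie correction otherwise.
#'
#' @param a,b Numeric samples.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (directions refer to `a` relative to `b`).
#' @return List with `u` and `p_value`.
#' @export
mann_whitney <- function(a, b,
                         alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) > 0L, length(b) > 0L)
  ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- min(length(a), length(b)) <= 8L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = alternative, exact = use_exact,
                       correct = !use_exact))
  list(u = unname(wt$statistic), p_value = wt$p.value)
}

#' Fisher's exact test for a 2x2 table
#'
#' Hypergeometric exact p-value (one- or two-sided). The reported odds
#' ratio is the sample odds ratio `(a*d)/(b*c)`, not the conditional MLE.
#' A table with a zero margin is degenerate: p = 1 by convention, flagged.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @param alternative Passed to [stats::fisher.test()].
#' @return List with `odds_ratio`, `p_value`, `degenerate`.
#' @export
fisher_exact_2x2 <- function(tab, alternative = c("two.sided", "less",
                                                  "greater")) {
  alternative <- match.arg(alternative)
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0), all(tab == round(tab)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(odds_ratio = NA_real_, p_value = 1.0, degenerate = TRUE))
  }
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  p <- stats::fisher.test(tab, alternative = alternative)$p.value
  list(odds_ratio = or, p_value = p, degenerate = FALSE)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Without continuity correction by default (set `correct = TRUE` for the
#' Yates-corrected statistic). Errors when any expected count is zero.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @param correct Apply the continuity correction? (default `FALSE`).
#' @return List with `statistic`, `p_value`, `df`.
#' @export
chi_square_2x2 <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) stop("zero expected cell")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), p_value = ct$p.value, df = 1L)
}

#' Per-tissue correlation profile
#'
#' Spearman correlation (with confidence interval) between a per-gene
#' feature and each tissue's expression column, ordered ascending by rho,
#' with the tissue-class tag attached when supplied.
#'
#' @param feature Named numeric vector (names = gene IDs) or `data.frame`
#'   with `gene_id` and a value column.
#' @param m Gene-by-tissue expression matrix (row names = gene IDs).
#' @param tissue_classes Optional `data.frame` with `label`, `class`.
#' @return `data.frame` with `tissue`, `class`, `rho`, `n`, `p_value`,
#'   `ci_low`, `ci_high`, sorted ascending by `rho`.
#' @export
per_tissue_correlation <- function(feature, m, tissue_classes = NULL) {
  if (is.data.frame(feature)) {
    val_col <- setdiff(names(feature), "gene_id")[1L]
    feature <- setNames(feature[[val_col]], feature$gene_id)
  }
  shared <- intersect(names(feature), rownames(m))
  if (length(shared) == 0L) stop("no shared genes")
  f <- feature[shared]
  mm <- m[shared, , drop = FALSE]
  res <- lapply(seq_len(ncol(mm)),
                function(j) spearman_cor(f, mm[, j]))
  out <- do.call(rbind, res)
  out$conditioned_on <- NULL
  out <- cbind(tissue = colnames(mm), out, stringsAsFactors = FALSE)
  if (!is.null(tissue_classes)) {
    out$class <- tissue_classes$class[match(out$tissue,
                                            tissue_classes$label)]
  } else out$class <- NA_character_
  out <- out[order(out$rho), ]
  row.names(out) <- NULL
  out
}
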
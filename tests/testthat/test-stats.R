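# independent midrank + Pearson-on-ranks oracle, written from the
# definitions rather than rank()/cor()
midranks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) r[i] <- sum(x < x[i]) + (1 + sum(x == x[i])) / 2
  r
}
pearson_sums <- function(a, b) {
  n <- length(a)
  num <- sum(a * b) - sum(a) * sum(b) / n
  den <- sqrt((sum(a^2) - sum(a)^2 / n) * (sum(b^2) - sum(b)^2 / n))
  num / den
}

test_that("Spearman correlation matches the midrank oracle and handles boundaries", {
  expect_equal(spearman_cor(1:3, c(10, 20, 30))$rho, 1)
  expect_equal(spearman_cor(1:3, c(3, 2, 1))$rho, -1)
  set.seed(5)
  for (i in 1:20) {
    x <- sample(1:8, 20, replace = TRUE)   # heavy ties
    y <- sample(1:8, 20, replace = TRUE)
    if (var(x) == 0 || var(y) == 0) next
    got <- spearman_cor(x, y)
    expect_equal(got$rho, pearson_sums(midranks(x), midranks(y)),
                 tolerance = 1e-12)
    expect_true(got$ci_low <= got$rho && got$rho <= got$ci_high)
  }
  expect_error(spearman_cor(rep(1, 5), 1:5), "zero variance")
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
  # complete-case handling reports the n actually used
  r <- spearman_cor(c(1, 2, NA, 4, 5), c(2, NA, 3, 8, 10))
  expect_equal(r$n, 3L)
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(6)
  x <- rnorm(50); y <- rnorm(50)
  base <- spearman_cor(x, y)$rho
  expect_equal(spearman_cor(exp(x), y)$rho, base)
  expect_equal(spearman_cor(x, y^3)$rho, base)
  expect_equal(spearman_cor(rank(x), exp(y / 2))$rho, base)
})

test_that("partial Spearman follows the first-order formula and its limits", {
  set.seed(10)
  # independence limit: conditioning on unrelated z changes nothing much
  x <- rnorm(10000); y <- 0.5 * x + rnorm(10000); z <- rnorm(10000)
  raw <- spearman_cor(x, y)$rho
  part <- partial_spearman(x, y, z)$rho
  expect_lt(abs(part - raw), 0.03)

  # exact identity when sample rank correlations with z are both zero
  x4 <- c(1, 2, 3, 4, 5, 6, 7, 8)
  y4 <- c(2, 1, 4, 3, 6, 5, 8, 7)
  z4 <- c(1, 1, -1, -1, -1, -1, 1, 1)   # symmetric: rho_xz = rho_yz = 0
  expect_equal(partial_spearman(x4, y4, z4)$rho,
               spearman_cor(x4, y4)$rho, tolerance = 1e-12)

  expect_error(partial_spearman(x4, y4, x4), "degenerate conditioning")

  # Monte-Carlo check against the population value of the partial formula
  # applied to the Gaussian-copula rank correlations
  # (Pearson rho_xy = 0.5, rho_xz = rho_yz = 0.6)
  n <- 5000
  sigma <- matrix(c(1, 0.5, 0.6,
                    0.5, 1, 0.6,
                    0.6, 0.6, 1), 3, 3)
  d <- matrix(rnorm(3 * n), n, 3) %*% chol(sigma)
  sp <- function(r) (6 / pi) * asin(r / 2)  # Pearson -> Spearman (normal)
  pop <- (sp(0.5) - sp(0.6)^2) / (1 - sp(0.6)^2)
  got <- partial_spearman(d[, 1], d[, 2], d[, 3])$rho
  expect_lt(abs(got - pop), 0.03)
})

mw_enumeration_p <- function(a, b, alternative) {
  # full enumeration over assignments of ranks to group A (no ties)
  n1 <- length(a); n2 <- length(b)
  vals <- c(a, b)
  stopifnot(!anyDuplicated(vals))
  u_of <- function(av, bv) sum(outer(av, bv, ">")) + 0.5 *
    sum(outer(av, bv, "=="))
  u_obs <- u_of(a, b)
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, function(ix) u_of(vals[ix], vals[-ix]))
  switch(alternative,
         less = mean(us <= u_obs),
         greater = mean(us >= u_obs),
         two.sided = min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs))))
}

test_that("Mann-Whitney matches full enumeration in the exact regime", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(r$p_value, 1 / choose(6, 3))
  expect_equal(r$p_value, 0.05)
  expect_equal(r$u, 0)

  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1.0)

  set.seed(12)
  for (i in 1:15) {
    n1 <- sample(2:5, 1); n2 <- sample(2:7, 1)
    v <- sample(1:50, n1 + n2)
    a <- v[1:n1]; b <- v[-(1:n1)]
    for (alt in c("two.sided", "less", "greater")) {
      expect_equal(mann_whitney(a, b, alt)$p_value,
                   mw_enumeration_p(a, b, alt), tolerance = 1e-12,
                   label = sprintf("n1=%d n2=%d alt=%s", n1, n2, alt))
    }
  }
})

fisher_enumeration_p <- function(tab, alternative) {
  m <- tab[1, 1] + tab[2, 1]; nn <- tab[1, 2] + tab[2, 2]
  k <- tab[1, 1] + tab[1, 2]
  xs <- max(0, k - nn):min(k, m)
  pr <- choose(m, xs) * choose(nn, k - xs) / choose(m + nn, k)
  obs <- tab[1, 1]
  p_obs <- pr[xs == obs]
  switch(alternative,
         less = sum(pr[xs <= obs]),
         greater = sum(pr[xs >= obs]),
         two.sided = sum(pr[pr <= p_obs + 1e-7 * p_obs]))
}

test_that("Fisher's exact test matches hypergeometric enumeration", {
  r <- fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2), "greater")
  expect_equal(r$p_value, 1 / choose(20, 10), tolerance = 1e-12)
  expect_false(r$degenerate)

  sym <- fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))
  expect_equal(sym$p_value, 1.0)
  expect_equal(sym$odds_ratio, 1.0)

  # zero margin: degenerate, p = 1 by convention
  z <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))
  expect_true(z$degenerate)
  expect_equal(z$p_value, 1.0)

  set.seed(19)
  for (i in 1:25) {
    tab <- matrix(sample(0:6, 4, TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    for (alt in c("two.sided", "less", "greater")) {
      expect_equal(fisher_exact_2x2(tab, alt)$p_value,
                   fisher_enumeration_p(tab, alt), tolerance = 1e-9,
                   label = paste(paste(tab, collapse = ","), alt))
    }
  }
})

test_that("chi-square on 2x2 tables matches hand computation", {
  flat <- chi_square_2x2(matrix(c(50, 50, 50, 50), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  # expected counts all 20; sum (O-E)^2/E = 4 * 100/20 = 20
  t2 <- matrix(c(30, 10, 10, 30), 2, byrow = TRUE)
  r <- chi_square_2x2(t2)
  expect_equal(r$statistic, 20)
  expect_equal(r$p_value, pchisq(20, 1, lower.tail = FALSE))

  # continuity-corrected statistic never exceeds the uncorrected one
  set.seed(23)
  for (i in 1:20) {
    tab <- matrix(sample(1:40, 4, TRUE), 2)
    expect_lte(chi_square_2x2(tab, correct = TRUE)$statistic,
               chi_square_2x2(tab, correct = FALSE)$statistic)
  }
  expect_error(chi_square_2x2(matrix(c(0, 0, 1, 2), 2)), "zero expected")
})

test_that("per-tissue correlations are sorted and tagged", {
  set.seed(31)
  genes <- sprintf("g%03d", 1:80)
  feat <- setNames(runif(80), genes)
  m <- cbind(t_mono = exp(2 * feat),           # monotone transform: rho = 1
             t_anti = -feat + 0.001 * rnorm(80),
             t_null = rnorm(80))
  rownames(m) <- genes
  classes <- data.frame(label = colnames(m),
                        class = c("germline", "somatic", "somatic"))
  out <- per_tissue_correlation(feat, m, classes)
  expect_equal(out$rho, sort(out$rho))
  expect_equal(out$tissue[out$rho == 1], "t_mono")
  expect_equal(out$class[out$tissue == "t_mono"], "germline")
  expect_lt(abs(out$rho[out$tissue == "t_null"]), 0.35)

  # shuffled expression: correlations scatter around zero
  shuf <- m[sample(80), , drop = FALSE]
  rownames(shuf) <- genes
  out2 <- per_tissue_correlation(feat, shuf, classes)
  expect_lt(mean(abs(out2$rho)), 0.25)
})
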
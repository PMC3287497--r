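test_that("K2P distance matches closed-form hand calculations to 1e-12", {
  same <- k2p_distance("ACGTACGT", "ACGTACGT")
  expect_equal(same$k3u, 0)

  # one transition in four sites: P = 0.25, Q = 0
  ts <- k2p_distance("GCTA", "GTTA")
  expect_equal(ts$p_transition, 0.25)
  expect_equal(ts$q_transversion, 0)
  expect_equal(ts$k3u, -0.5 * log(0.5), tolerance = 1e-12)

  # one transversion in four sites: P = 0, Q = 0.25
  tv <- k2p_distance("AAAA", "AACA")
  expect_equal(tv$q_transversion, 0.25)
  expect_equal(tv$k3u, -0.5 * log(0.75 * sqrt(0.5)), tolerance = 1e-12)

  # gaps and N excluded from comparable sites
  gap <- k2p_distance("GC-TAN", "GTATAA")
  expect_equal(gap$n_sites, 4L)
  expect_equal(gap$p_transition, 0.25)

  # saturation: log argument <= 0 gives a missing distance
  sat <- k2p_distance("ACACACAC", "CACACACA")
  expect_true(is.na(sat$k3u))

  expect_error(k2p_distance("----", "AAAA"), "no comparable sites")
})

test_that("K2P distance is symmetric in its sequences", {
  set.seed(17)
  for (i in 1:25) {
    a <- random_dna(200)
    b <- random_dna(200)
    ra <- k2p_distance(a, b); rb <- k2p_distance(b, a)
    expect_equal(ra$k3u, rb$k3u)
    expect_equal(ra$p_transition, rb$p_transition)
  }
})

test_that("K2P recovers the true distance of a simulated substitution process", {
  # independent simulator: per-site category probabilities derived in the
  # test from the K2P transition matrix with ts/tv rate ratio 2
  set.seed(99)
  K <- 0.2
  A <- exp(-K); B <- exp(-1.5 * K)
  probs <- c(same = 0.25 + 0.25 * A + 0.5 * B,
             ts = 0.25 + 0.25 * A - 0.5 * B,
             tv1 = 0.25 - 0.25 * A, tv2 = 0.25 - 0.25 * A)
  n <- 10000L
  anc <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  cat <- sample(1:4, n, replace = TRUE, prob = probs)
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv_a <- c(A = "C", G = "C", C = "A", T = "A")
  tv_b <- c(A = "T", G = "T", C = "G", T = "G")
  der <- anc
  der[cat == 2] <- ts_map[anc[cat == 2]]
  der[cat == 3] <- tv_a[anc[cat == 3]]
  der[cat == 4] <- tv_b[anc[cat == 4]]
  est <- k2p_distance(paste(anc, collapse = ""), paste(der, collapse = ""))
  expect_lt(abs(est$k3u - K) / K, 0.05)

  # equal-rate (Jukes-Cantor-like) process: Q approaches 2P and the
  # distance is still recovered
  A2 <- exp(-4 * K / 3)
  probs2 <- c(1 - 3 * (0.25 - 0.25 * A2), rep(0.25 - 0.25 * A2, 3))
  cat2 <- sample(1:4, n, replace = TRUE, prob = probs2)
  der2 <- anc
  der2[cat2 == 2] <- ts_map[anc[cat2 == 2]]
  der2[cat2 == 3] <- tv_a[anc[cat2 == 3]]
  der2[cat2 == 4] <- tv_b[anc[cat2 == 4]]
  est2 <- k2p_distance(paste(anc, collapse = ""),
                       paste(der2, collapse = ""))
  expect_lt(abs(est2$k3u - K) / K, 0.05)
  ratio <- est2$q_transversion / est2$p_transition
  expect_gt(ratio, 1.7); expect_lt(ratio, 2.3)
})

toy_block <- function(h, others) {
  data.frame(species = c("hsa", paste0("sp", seq_along(others))),
             text = c(h, others), stringsAsFactors = FALSE)
}

test_that("focal indel rates follow strict unanimity parsimony", {
  # no gaps anywhere: zero rates
  none <- toy_block("ACGTAC", c("ACGTAC", "ACGTAC"))
  r0 <- indel_rates(none, "hsa")
  expect_equal(c(r0$insertion_rate, r0$deletion_rate), c(0, 0))

  # human bases where all others are gapped: a 2-bp insertion
  ins <- toy_block("ACGTAC", c("AC--AC", "AC--AC"))
  ri <- indel_rates(ins, "hsa")
  expect_equal(ri$insertion_rate, 2 / 6)
  expect_equal(ri$n_insertion_events, 1L)
  expect_equal(ri$deletion_rate, 0)

  # human gapped where all others have bases: a deletion
  del <- toy_block("AC--AC", c("ACGTAC", "ACTTAC"))
  rd <- indel_rates(del, "hsa")
  expect_equal(rd$deletion_rate, 2 / 6)
  expect_equal(rd$insertion_rate, 0)

  # disagreeing non-focal rows break the unanimity rule: not counted
  mix <- toy_block("ACGTAC", c("AC--AC", "ACGTAC"))
  rm <- indel_rates(mix, "hsa")
  expect_equal(c(rm$insertion_rate, rm$deletion_rate), c(0, 0))

  expect_error(indel_rates(toy_block("AC", "AC"), "hsa"), "cannot polarize")
  expect_error(indel_rates(toy_block("AC", c("AC", "ACG")), "hsa"),
               "differ in length")
})

test_that("indel rates are invariant to the order of non-focal rows", {
  set.seed(4)
  for (i in 1:10) {
    h <- paste(sample(c("A", "C", "G", "T", "-"), 60, TRUE,
                      prob = c(rep(0.23, 4), 0.08)), collapse = "")
    o1 <- paste(sample(c("A", "C", "G", "T", "-"), 60, TRUE,
                       prob = c(rep(0.23, 4), 0.08)), collapse = "")
    o2 <- paste(sample(c("A", "C", "G", "T", "-"), 60, TRUE,
                       prob = c(rep(0.23, 4), 0.08)), collapse = "")
    b1 <- toy_block(h, c(o1, o2))
    b2 <- toy_block(h, c(o2, o1))
    expect_equal(indel_rates(b1, "hsa")[1:3], indel_rates(b2, "hsa")[1:3])
  }
})

test_that("MAF parsing and per-gene concatenation reproduce generator truth", {
  b <- simulate_bundle(tiny_config())
  dir <- withr::local_tempdir()
  writeLines(b$maf_lines, file.path(dir, "x.maf"))
  maf <- read_maf(file.path(dir, "x.maf"))
  expect_setequal(unique(maf$species), c("hsa", "ptr", "mml"))
  rates <- indel_table(maf, focal = "hsa")
  tr <- ground_truth_report(b)
  m <- merge(rates, tr, by = "gene_id")
  expect_equal(m$insertion_rate, m$ins_rate_true, tolerance = 1e-12)
  expect_equal(m$deletion_rate, m$del_rate_true, tolerance = 1e-12)
})

test_that("aligned pairs round-trip through FASTA and k2p_table is vectorised", {
  b <- simulate_bundle(tiny_config())
  dir <- withr::local_tempdir()
  f <- file.path(dir, "pairs.fa")
  fa <- Biostrings::BStringSet(setNames(
    c(b$utr_pairs$seq_a, b$utr_pairs$seq_b),
    c(paste0(b$utr_pairs$gene_id, "|hsa"),
      paste0(b$utr_pairs$gene_id, "|mmu"))))
  Biostrings::writeXStringSet(fa, f)
  back <- read_alignment_pairs(f, focal = "hsa")
  back <- back[match(b$utr_pairs$gene_id, back$gene_id), ]
  expect_equal(back$seq_a, b$utr_pairs$seq_a)
  kt <- k2p_table(back)
  expect_equal(kt$k3u[1],
               k2p_distance(back$seq_a[1], back$seq_b[1])$k3u)
  expect_true(all(is.finite(kt$k3u)))
})
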
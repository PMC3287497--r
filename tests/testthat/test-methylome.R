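test_that("CpG O/E matches hand-enumerated compositions", {
  r <- cpg_oe(c("ACGT", "CGCGCG", "AATT"))
  expect_equal(r$n_cpg, c(1L, 3L, 0L))
  expect_equal(r$n_c, c(1L, 3L, 0L))
  expect_equal(r$cpg_oe, c(4.0, 2.0, NA_real_))
  # N positions excluded from counts and length
  rn <- cpg_oe("ACGTNN")
  expect_equal(rn$length, 4L)
  expect_equal(rn$cpg_oe, 4.0)
})

test_that("reverse complementation leaves the CpG count unchanged", {
  set.seed(7)
  for (i in 1:50) {
    s <- random_dna(sample(50:400, 1))
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(cpg_oe(s)$n_cpg, cpg_oe(rc)$n_cpg)
  }
})

test_that("site callers follow their thresholds and the binomial tail", {
  calls <- data.frame(chrom = "c", pos = c(0L, 10L, 20L), strand = "+",
                      context = "CG", mc_reads = c(6L, 4L, 0L),
                      total_reads = c(10L, 10L, 10L))
  f <- call_methylated_sites(calls, method = "fraction", theta = 0.5)
  expect_equal(f, c(TRUE, FALSE, FALSE))

  none <- transform(calls, mc_reads = 0L)
  expect_false(any(call_methylated_sites(none, method = "fraction")))
  expect_false(any(call_methylated_sites(none, method = "binomial")))

  # single site 10/10 at error rate 0.01: p = 0.01^10 = 1e-20
  one <- data.frame(chrom = "c", pos = 0L, strand = "+", context = "CG",
                    mc_reads = 10L, total_reads = 10L)
  p <- pbinom(9, 10, 0.01, lower.tail = FALSE)
  expect_equal(p, 1e-20)
  expect_true(call_methylated_sites(one, method = "binomial"))

  expect_error(call_methylated_sites(calls, method = "bogus"))
})

test_that("promoter mCG/CG matches forced arithmetic and degenerate cases", {
  # 10 promoter CpGs, 4 methylated -> 0.4
  seq <- paste0(strrep("CGT", 10), strrep("AT", 100))
  genome <- c(chr1 = seq)
  sites <- find_cpg_sites(genome)
  expect_equal(nrow(sites), 10L)
  calls <- data.frame(chrom = "chr1", pos = sites$pos, strand = "+",
                      context = "CG", mc_reads = rep(c(10L, 0L), c(4, 6)),
                      total_reads = 10L)
  gm <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                   strand = "+", promoter_start = c(0L, 100L),
                   promoter_end = c(30L, 220L))
  meth <- call_methylated_sites(calls, method = "fraction")
  r <- promoter_mcg_cg(gm, sites, calls, meth)
  expect_equal(r$mcg_cg, c(0.4, NA_real_))
  expect_equal(r$n_cpg_covered, c(10L, 0L))
})

test_that("promoter mCG/CG equals a naive per-base scan on random instances", {
  set.seed(11)
  L <- 20000L
  seq <- random_dna(L)
  genome <- c(chrX = seq)
  sites <- find_cpg_sites(genome)
  covered <- runif(nrow(sites)) < 0.8
  calls <- data.frame(chrom = "chrX", pos = sites$pos[covered],
                      strand = "+", context = "CG",
                      total_reads = sample(1:30, sum(covered), TRUE))
  calls$mc_reads <- rbinom(nrow(calls), calls$total_reads, 0.5)
  meth <- call_methylated_sites(calls, method = "fraction")
  min_cov <- 3L
  n_int <- 1000L
  starts <- sample(0:(L - 1300L), n_int, replace = TRUE)
  gm <- data.frame(gene_id = sprintf("g%04d", seq_len(n_int)),
                   chrom = "chrX", strand = sample(c("+", "-"), n_int, TRUE),
                   promoter_start = starts, promoter_end = starts + 1200L)
  got <- promoter_mcg_cg(gm, sites, calls, meth, min_coverage = min_cov)

  call_idx <- setNames(seq_len(nrow(calls)), calls$pos)
  for (i in seq_len(n_int)) {
    cov <- 0L; mm <- 0L; tot <- 0L
    for (p in gm$promoter_start[i]:(gm$promoter_end[i] - 1L)) {
      if (substr(seq, p + 1L, p + 2L) == "CG") {
        tot <- tot + 1L
        j <- call_idx[as.character(p)]
        if (!is.na(j) && calls$total_reads[j] >= min_cov) {
          cov <- cov + 1L
          if (meth[j]) mm <- mm + 1L
        }
      }
    }
    expect_identical(got$n_cpg_total[i], tot)
    expect_identical(got$n_cpg_covered[i], cov)
    if (cov > 0L) expect_identical(got$mcg_cg[i], mm / cov)
    else expect_true(is.na(got$mcg_cg[i]))
  }
})

test_that("mCG/CG is monotone in the methylated set and 1.0 when all sites are called", {
  set.seed(3)
  seq <- random_dna(5000L)
  genome <- c(c1 = seq)
  sites <- find_cpg_sites(genome)
  calls <- data.frame(chrom = "c1", pos = sites$pos, strand = "+",
                      context = "CG", mc_reads = 5L, total_reads = 5L)
  gm <- data.frame(gene_id = "g", chrom = "c1", strand = "+",
                   promoter_start = 1000L, promoter_end = 2200L)
  all_m <- rep(TRUE, nrow(calls))
  expect_equal(promoter_mcg_cg(gm, sites, calls, all_m)$mcg_cg, 1.0)
  prev <- 0
  grow <- rep(FALSE, nrow(calls))
  for (f in c(0.2, 0.5, 0.8)) {
    grow[seq_len(floor(f * nrow(calls)))] <- TRUE
    cur <- promoter_mcg_cg(gm, sites, calls, grow)$mcg_cg
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("CpG island counting follows the sliding-window island rule", {
  expect_equal(count_cgis(strrep("AT", 600)), 0L)
  one <- paste0(strrep("AT", 200), strrep("CG", 150), strrep("AT", 200))
  expect_equal(count_cgis(one), 1L)
  # two dense blocks separated by > 100 bp of AT: two islands
  two <- paste0(strrep("AT", 100), strrep("CG", 150), strrep("AT", 75),
                strrep("CG", 150), strrep("AT", 100))
  expect_equal(count_cgis(two), 2L)
  # separation of 60 bp bridges into a single island
  bridged <- paste0(strrep("AT", 100), strrep("CG", 150), strrep("AT", 30),
                    strrep("CG", 150), strrep("AT", 100))
  expect_equal(count_cgis(bridged), 1L)
  # shorter than one window: no island
  expect_equal(count_cgis(strrep("CG", 80)), 0L)
})

test_that("methylation calls round-trip through the TSV reader with validation", {
  b <- simulate_bundle(tiny_config())
  dir <- withr::local_tempdir()
  f <- file.path(dir, "calls.tsv")
  data.table::fwrite(data.table::as.data.table(b$calls_a), f, sep = "\t")
  back <- read_methylation_calls(f)
  expect_equal(back$pos, b$calls_a$pos)
  expect_equal(back$mc_reads, b$calls_a$mc_reads)

  bad <- b$calls_a
  bad$mc_reads[1] <- bad$total_reads[1] + 1L
  data.table::fwrite(data.table::as.data.table(bad), f, sep = "\t")
  expect_error(read_methylation_calls(f), "invariant")
})
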
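test_that("EM equals direct gamete counting when phase is unambiguous", {
  # 20 AB|AB, 5 Ab|Ab, 5 aB|aB, 20 ab|ab individuals: no double
  # heterozygotes, so p(AB) = 40/100 = 0.4 exactly
  g1 <- rep(c(2, 2, 0, 0), c(20, 5, 5, 20))
  g2 <- rep(c(2, 0, 2, 0), c(20, 5, 5, 20))
  em <- em_haplotype_freqs(g1, g2)
  expect_equal(unname(em$freqs),
               c(0.4, 0.1, 0.1, 0.4), tolerance = 1e-9)

  # a SNP against itself: only the two concordant haplotypes exist
  set.seed(3)
  g <- sample(0:2, 120, replace = TRUE)
  em_self <- em_haplotype_freqs(g, g)
  expect_equal(unname(em_self$freqs[2] + em_self$freqs[3]), 0,
               tolerance = 1e-7)
  expect_equal(unname(em_self$freqs[1] + em_self$freqs[4]), 1,
               tolerance = 1e-9)
})

test_that("EM attains the likelihood-grid maximum on random tables", {
  set.seed(1234)
  worst <- 0
  for (rep in 1:100) {
    p <- as.numeric(stats::rgamma(4, 1)); p <- p / sum(p)
    n <- 50
    hap1 <- sample(1:4, n, replace = TRUE, prob = p)
    hap2 <- sample(1:4, n, replace = TRUE, prob = p)
    a <- c(0, 0, 1, 1); b <- c(0, 1, 0, 1)
    g1 <- a[hap1] + a[hap2]; g2 <- b[hap1] + b[hap2]
    if (length(unique(g1)) == 1 || length(unique(g2)) == 1) next
    em <- em_haplotype_freqs(g1, g2)
    ll_em <- geno_loglik(geno_table(g1, g2), em$freqs)
    ll_grid <- em_grid_oracle(g1, g2)
    worst <- max(worst, ll_grid - ll_em)
  }
  # EM on the full simplex can only beat a grid constrained to sample
  # allele frequencies, up to grid resolution
  expect_lt(worst, 1e-3)
})

test_that("LD statistics match hand-computed values", {
  s <- ld_stats(c(h00 = 0.4, h01 = 0.1, h10 = 0.1, h11 = 0.4))
  expect_equal(s$D, 0.15)
  expect_equal(s$Dprime, 0.6)
  expect_equal(s$r2, 0.36)

  perfect <- ld_stats(c(0.5, 0, 0, 0.5))
  expect_equal(perfect$Dprime, 1)
  expect_equal(perfect$r2, 1)

  indep <- ld_stats(c(0.42, 0.18, 0.28, 0.12)) # p11 = pA * pB = 0.4*0.3
  expect_equal(indep$D, 0, tolerance = 1e-12)
  expect_equal(indep$r2, 0, tolerance = 1e-12)

  mono <- ld_stats(c(0.6, 0.4, 0, 0))
  expect_true(mono$monomorphic)
  expect_true(is.na(mono$r2))
})

test_that("r2 and |D'| are invariant to allele-label and locus swaps", {
  set.seed(8)
  for (rep in 1:20) {
    cnt <- as.numeric(stats::rmultinom(1, 200, stats::rgamma(4, 1)))
    s <- ld_stats(cnt)
    if (s$monomorphic) next
    swapA <- ld_stats(cnt[c(3, 4, 1, 2)])   # relabel locus-1 alleles
    swapB <- ld_stats(cnt[c(2, 1, 4, 3)])   # relabel locus-2 alleles
    locus <- ld_stats(cnt[c(1, 3, 2, 4)])   # swap the two loci
    expect_equal(abs(swapA$Dprime), abs(s$Dprime))
    expect_equal(swapA$r2, s$r2)
    expect_equal(abs(swapB$Dprime), abs(s$Dprime))
    expect_equal(swapB$r2, s$r2)
    expect_equal(locus$r2, s$r2)
  }
  # r2 = 1 iff |D'| = 1 with matched allele frequencies
  eq_freq <- ld_stats(c(0.3, 0, 0, 0.7))
  expect_equal(eq_freq$r2, 1)
  mismatch <- ld_stats(c(0.3, 0.2, 0, 0.5))  # nested: D' = 1, pA != pB
  expect_equal(abs(mismatch$Dprime), 1)
  expect_lt(mismatch$r2, 1)
})

test_that("D' confidence bounds behave at the canonical extremes", {
  # perfect coupling, balanced freqs: lik(d) prop to (1+d)^n_gametes, so
  # the 5% mass point on the 0.001 grid is 0.971 at 200 gametes and 0.986
  # at 400 (closed-form oracle)
  perfect <- dprime_ci(c(h00 = 100, h01 = 0, h10 = 0, h11 = 100))
  expect_equal(perfect$ci_low, 0.971)
  expect_equal(perfect$ci_high, 1)
  perfect4 <- dprime_ci(c(h00 = 200, h01 = 0, h10 = 0, h11 = 200))
  expect_equal(perfect4$ci_low, 0.986)

  one_ind <- dprime_ci(c(1, 0, 0, 1))      # a single individual
  expect_lt(one_ind$ci_low, 0.2)
  expect_gt(one_ind$ci_high, 0.95)

  equil <- dprime_ci(c(250, 250, 250, 250))
  expect_lt(equil$ci_high, 0.9)            # "strong recombination"

  mono <- dprime_ci(c(10, 10, 0, 0))
  expect_true(mono$monomorphic)
})

test_that("block finding recovers constructed LD structure", {
  # all pairs in perfect LD: one block covering the whole panel
  pop1 <- make_pop(rbind(rep(0, 6), rep(1, 6)))
  g1 <- simulate_haplotypes(pop1, 120, seed = 51)
  b1 <- haplotype_blocks(g1)
  expect_equal(nrow(b1), 1L)
  expect_equal(c(b1$start_index, b1$end_index), c(1L, 6L))

  # two perfect-LD clusters separated by an equilibrium boundary
  combos <- expand.grid(left = 0:1, right = 0:1)
  haps2 <- cbind(matrix(combos$left, 4, 3), matrix(combos$right, 4, 3))
  g2 <- simulate_haplotypes(make_pop(haps2), 250, seed = 52)
  b2 <- haplotype_blocks(g2)
  expect_equal(nrow(b2), 2L)
  expect_equal(b2$start_index, c(1L, 4L))
  expect_equal(b2$end_index, c(3L, 6L))

  # independent SNPs everywhere: no blocks
  haps3 <- matrix(as.integer(stats::runif(64 * 5) < 0.5), 64, 5)
  set.seed(53)
  haps3 <- haps3[, apply(haps3, 2, stats::var) > 0, drop = FALSE]
  g3 <- simulate_haplotypes(make_pop(haps3), 250, seed = 53)
  b3 <- haplotype_blocks(g3)
  expect_equal(nrow(b3), 0L)
})

test_that("NE-like pool yields longer blocks than SA-like pool", {
  g_ne <- simulate_haplotypes(pop_ne_like(), 250, seed = 61)
  g_sa <- simulate_haplotypes(pop_sa_like(), 250, seed = 62)
  b_ne <- haplotype_blocks(g_ne)
  b_sa <- haplotype_blocks(g_sa)
  expect_gt(nrow(b_ne), 0L)
  expect_gt(nrow(b_sa), 0L)
  expect_gt(mean(b_ne$n_snps), mean(b_sa$n_snps))
  expect_gt(max(b_ne$span_bp), max(b_sa$span_bp))
})

test_that("greedy tagging covers every MAF-passing SNP", {
  # one perfect-LD cluster: a single tag suffices
  pop1 <- make_pop(rbind(rep(0, 5), rep(1, 5)))
  g1 <- simulate_haplotypes(pop1, 100, seed = 71)
  expect_length(tag_snps(g1), 1L)

  # mutually unlinked SNPs: every SNP tags itself
  haps <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  g2 <- simulate_haplotypes(make_pop(haps), 400, seed = 72)
  expect_length(tag_snps(g2, r2_threshold = 0.3), 3L)

  # random panels: coverage verified exhaustively against the r2 matrix
  set.seed(73)
  for (rep in 1:5) {
    hp <- matrix(as.integer(stats::runif(40 * 12) < stats::runif(12, .2, .8)),
                 40, 12, byrow = FALSE)
    g <- simulate_haplotypes(make_pop(hp), 150)
    f <- maf(g)
    eligible <- names(f)[f >= 0.05]
    tags <- tag_snps(g, r2_threshold = 0.8)
    covered <- vapply(eligible, function(s) {
      any(vapply(tags, function(t) {
        if (t == s) return(TRUE)
        i <- match(s, g$snps$snp_id); j <- match(t, g$snps$snp_id)
        r2 <- ld_stats(aeqtl:::hap_pair_counts(g, i, j))$r2
        !is.na(r2) && r2 > 0.8
      }, logical(1)))
    }, logical(1))
    expect_true(all(covered))
  }

  # force-include is respected
  g4 <- simulate_haplotypes(pop1, 100, seed = 74)
  t4 <- tag_snps(g4, force_include = "S03")
  expect_true("S03" %in% t4)
})
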
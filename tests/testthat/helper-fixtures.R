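# Shared fixture builders and independent oracles.

make_panel <- function(m, start = 1000L, step = 1000L) {
  data.frame(snp_id = sprintf("S%02d", seq_len(m)), chrom = "chr16",
             pos = as.integer(start + step * (seq_len(m) - 1L)),
             ref = "A", alt = "G")
}

make_pop <- function(haps, freqs = NULL, panel = NULL, name = "test") {
  haps <- as.matrix(haps)
  if (is.null(freqs)) freqs <- rep(1 / nrow(haps), nrow(haps))
  if (is.null(panel)) panel <- make_panel(ncol(haps))
  population_spec(name, panel, haps, freqs)
}

# genotypes built directly from explicit haplotype rows
make_geno <- function(h1, h2, panel = NULL) {
  h1 <- as.matrix(h1); h2 <- as.matrix(h2)
  if (is.null(panel)) panel <- make_panel(ncol(h1))
  phased_genotypes(h1, h2, panel)
}

# --- independent oracles ----------------------------------------------------

# Holm step-down by literal enumeration of the definition
holm_oracle <- function(p, m = length(p)) {
  ord <- order(p)
  adj <- numeric(length(p))
  for (i in seq_along(p)) {
    best <- 0
    for (j in seq_len(i))
      best <- max(best, min(1, (m - j + 1) * p[ord[j]]))
    adj[ord[i]] <- best
  }
  adj
}

# Fisher combined p for even df via the closed-form chi-square survival
# function exp(-x/2) * sum_{k<K} (x/2)^k / k!
fisher_oracle <- function(p) {
  x <- -2 * sum(log(p))
  K <- length(p)
  exp(-x / 2) * sum((x / 2)^seq(0, K - 1) / factorial(seq(0, K - 1)))
}

# two-locus genotype-table log-likelihood under HWE given hap freqs
# (order h00 h01 h10 h11)
geno_loglik <- function(tab, p) {
  haps <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  ll <- 0
  for (gA in 0:2) for (gB in 0:2) {
    n <- tab[gA + 1, gB + 1]
    if (n == 0) next
    prob <- 0
    for (h in 1:4) for (k in 1:4) {
      if (haps[h, 1] + haps[k, 1] == gA && haps[h, 2] + haps[k, 2] == gB)
        prob <- prob + p[h] * p[k]
    }
    ll <- ll + n * log(prob)
  }
  ll
}

geno_table <- function(g1, g2) {
  tab <- matrix(0, 3, 3)
  for (i in seq_along(g1)) tab[g1[i] + 1, g2[i] + 1] <-
    tab[g1[i] + 1, g2[i] + 1] + 1
  tab
}

# likelihood grid over the one free haplotype frequency (p11), allele
# frequencies fixed at their sample values
em_grid_oracle <- function(g1, g2, step = 0.001) {
  tab <- geno_table(g1, g2)
  pA <- mean(g1) / 2; pB <- mean(g2) / 2
  lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
  grid <- seq(lo, hi, by = step)
  best <- -Inf
  for (p11 in grid) {
    p <- c(1 - pA - pB + p11, pB - p11, pA - p11, p11)
    if (any(p < 0)) next
    ll <- geno_loglik(tab, p)
    if (ll > best) best <- ll
  }
  best
}
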
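#' Two-locus EM haplotype frequency estimation
#'
#' Estimates the four two-locus haplotype frequencies from unphased 0/1/2
#' dosages by EM over the double-heterozygote phase ambiguity. When no
#' double heterozygotes are present the estimates equal direct gamete
#' counts.
#'
#' @param g1,g2 integer vectors of alt-allele dosages (0/1/2); pairs with a
#'   missing value are dropped.
#' @param tol convergence tolerance on the max frequency change.
#' @param max_iter iteration cap.
#' @return list with `freqs` (named `h00`, `h01`, `h10`, `h11`; order is
#'   allele at locus 1 then locus 2), `n` (individuals used), `iterations`,
#'   and `monomorphic` flag (r2 undefined downstream when TRUE).
#' @export
em_haplotype_freqs <- function(g1, g2, tol = 1e-8, max_iter = 1000L) {
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- as.integer(g1[keep]); g2 <- as.integer(g2[keep])
  if (!length(g1)) stop("at least one individual with complete data required")
  if (!all(g1 %in% 0:2) || !all(g2 %in% 0:2))
    stop("dosages must be coded 0/1/2")
  n <- length(g1)
  tab <- matrix(0, 3, 3)
  for (i in seq_len(n)) tab[g1[i] + 1L, g2[i] + 1L] <-
    tab[g1[i] + 1L, g2[i] + 1L] + 1
  mono <- length(unique(g1)) == 1L && g1[1] != 1L ||
          length(unique(g2)) == 1L && g2[1] != 1L

  # known gamete counts contributed by the eight unambiguous cells
  # (indices: [dosage1+1, dosage2+1]); h order: 00, 01, 10, 11
  base <- c(
    h00 = 2 * tab[1, 1] + tab[1, 2] + tab[2, 1],
    h01 = 2 * tab[1, 3] + tab[1, 2] + tab[2, 3],
    h10 = 2 * tab[3, 1] + tab[2, 1] + tab[3, 2],
    h11 = 2 * tab[3, 3] + tab[2, 3] + tab[3, 2])
  ndh <- tab[2, 2]                      # double heterozygotes
  p <- rep(0.25, 4)
  it <- 0L
  repeat {
    it <- it + 1L
    cis <- p[1] * p[4]                  # 00/11 resolution
    trans <- p[2] * p[3]                # 01/10 resolution
    w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    cnt <- base + ndh * c(w, 1 - w, 1 - w, w)
    p_new <- cnt / sum(cnt)
    if (max(abs(p_new - p)) < tol || it >= max_iter) { p <- p_new; break }
    p <- p_new
  }
  list(freqs = stats::setNames(p, c("h00", "h01", "h10", "h11")), n = n,
       iterations = it, monomorphic = mono)
}

# gamete counts for a SNP pair from phased haplotypes (EM not needed)
hap_pair_counts <- function(geno, i, j) {
  a <- c(geno$h1[, i], geno$h2[, i])
  b <- c(geno$h1[, j], geno$h2[, j])
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  c(h00 = sum(a == 0 & b == 0), h01 = sum(a == 0 & b == 1),
    h10 = sum(a == 1 & b == 0), h11 = sum(a == 1 & b == 1))
}

#' Pairwise LD statistics from haplotype frequencies
#'
#' D is the haplotype-frequency covariance `p11 - pA*pB`; D' normalizes D by
#' its maximum attainable magnitude given the allele frequencies; r2 is the
#' squared allelic correlation `D^2 / (pA pa pB pb)`.
#'
#' @param freqs numeric 4-vector of haplotype frequencies in order
#'   `h00, h01, h10, h11` (alleles locus1-locus2), or a 4-vector of gamete
#'   counts (normalized internally).
#' @return list with `D`, `Dprime` (signed), `r2`, allele frequencies
#'   `pA`/`pB` (alt at locus 1/2), and `monomorphic` flag (D'/r2 are NA
#'   when either locus is monomorphic).
#' @export
ld_stats <- function(freqs) {
  if (length(freqs) != 4L || any(freqs < 0) || sum(freqs) <= 0)
    stop("freqs must be 4 non-negative values with positive sum")
  p <- as.numeric(freqs) / sum(freqs)
  pA <- p[3] + p[4]; pB <- p[2] + p[4]
  D <- p[4] - pA * pB
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    return(list(D = D, Dprime = NA_real_, r2 = NA_real_, pA = pA, pB = pB,
                monomorphic = TRUE))
  dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  dprime <- if (D == 0) 0 else D / dmax
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  list(D = D, Dprime = dprime, r2 = r2, pA = pA, pB = pB, monomorphic = FALSE)
}

#' One-sided 90% confidence bounds on |D'|
#'
#' Likelihood of the observed gamete counts is evaluated over |D'| on a
#' 0.001-step grid in [0, 1], with allele frequencies fixed at their point
#' estimates and the sign of D fixed at its estimate. The bounds are the
#' grid points below and above which 5% of the normalized likelihood mass
#' lies (the Gabriel/Haploview convention).
#'
#' @param counts gamete counts `h00, h01, h10, h11` (phased data).
#' @param step grid step (default 0.001).
#' @return list with `ci_low`, `ci_high` and `monomorphic` flag (bounds NA
#'   when a locus is monomorphic).
#' @export
dprime_ci <- function(counts, step = 0.001) {
  if (sum(counts) < 1) stop("at least one gamete required")
  s <- ld_stats(counts)
  if (s$monomorphic)
    return(list(ci_low = NA_real_, ci_high = NA_real_, monomorphic = TRUE))
  sgn <- if (s$D >= 0) 1 else -1
  dmax <- if (sgn > 0) min(s$pA * (1 - s$pB), (1 - s$pA) * s$pB)
          else min(s$pA * s$pB, (1 - s$pA) * (1 - s$pB))
  grid <- seq(0, 1, by = step)
  D <- sgn * grid * dmax
  p11 <- s$pA * s$pB + D
  p10 <- s$pA - p11
  p01 <- s$pB - p11
  p00 <- 1 - s$pA - s$pB + p11
  P <- cbind(p00, p01, p10, p11)
  P[P < 0 & P > -1e-12] <- 0            # clamp numeric dust at the boundary
  n <- as.numeric(counts)               # order h00 h01 h10 h11
  invalid <- rowSums(P < 0) > 0
  P[P < 0] <- 0
  ll <- numeric(length(grid))
  for (j in 1:4) if (n[j] > 0) ll <- ll + n[j] * log(P[, j])
  ll[invalid] <- -Inf
  if (all(!is.finite(ll)))
    return(list(ci_low = NA_real_, ci_high = NA_real_, monomorphic = FALSE))
  lik <- exp(ll - max(ll[is.finite(ll)]))
  lik[!is.finite(lik)] <- 0
  mass <- lik / sum(lik)
  lo_cum <- cumsum(mass)
  hi_cum <- rev(cumsum(rev(mass)))
  ci_low <- grid[which(lo_cum > 0.05)[1]]
  ci_high <- grid[max(which(hi_cum > 0.05))]
  list(ci_low = ci_low, ci_high = ci_high, monomorphic = FALSE)
}

#' All-pairs LD table for a phased cohort
#'
#' Gametes are counted directly from the phased haplotypes (no EM).
#'
#' @param geno a `phased_genotypes` cohort.
#' @param ci compute D' confidence bounds (needed for block finding)?
#' @return data.frame of class `ld_table`: `snp1`, `snp2` (panel ids,
#'   `i < j` in panel order), `D`, `Dprime`, `r2`, `ci_low`, `ci_high`.
#'   Monomorphic pairs carry NA statistics.
#' @export
ld_table <- function(geno, ci = TRUE) {
  m <- nrow(geno$snps)
  ids <- geno$snps$snp_id
  pairs <- utils::combn(m, 2)
  out <- data.frame(snp1 = ids[pairs[1, ]], snp2 = ids[pairs[2, ]],
                    D = NA_real_, Dprime = NA_real_, r2 = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_)
  for (k in seq_len(ncol(pairs))) {
    cnt <- hap_pair_counts(geno, pairs[1, k], pairs[2, k])
    s <- ld_stats(cnt)
    out$D[k] <- s$D; out$Dprime[k] <- s$Dprime; out$r2[k] <- s$r2
    if (ci && !s$monomorphic) {
      b <- dprime_ci(cnt)
      out$ci_low[k] <- b$ci_low; out$ci_high[k] <- b$ci_high
    }
  }
  attr(out, "snp_ids") <- ids
  class(out) <- c("ld_table", "data.frame")
  out
}

#' r2 of every panel SNP with one reference SNP
#' @param geno a `phased_genotypes` cohort.
#' @param snp reference SNP id.
#' @return named numeric vector over the panel (1 at the reference; NA for
#'   monomorphic SNPs).
#' @export
r2_with <- function(geno, snp) {
  ids <- geno$snps$snp_id
  j <- match(snp, ids)
  if (is.na(j)) stop("SNP not in panel: ", snp)
  vapply(seq_along(ids), function(i) {
    if (i == j) return(1)
    ld_stats(hap_pair_counts(geno, i, j))$r2
  }, numeric(1)) |> stats::setNames(ids)
}

#' Confidence-interval haplotype blocks
#'
#' Gabriel-style classification from the one-sided 90% |D'| bounds: a pair
#' is in strong LD if `ci_low >= 0.70` and `ci_high >= 0.98`, shows strong
#' recombination if `ci_high < 0.90`, and is otherwise uninformative. A
#' candidate block is a panel interval whose outermost pair is in strong LD
#' and in which at least 95% of informative pairs are in strong LD;
#' candidates are accepted greedily, longest first (SNP count, then bp
#' span), discarding overlaps.
#'
#' @param geno a `phased_genotypes` cohort, or an `ld_table` built with
#'   `ci = TRUE` (then `snps` must be supplied).
#' @param snps panel data.frame when `geno` is an `ld_table`.
#' @param strong_low,strong_high,recomb_high classification thresholds.
#' @param inform_frac minimum strong-LD fraction among informative pairs.
#' @return data.frame of class `haplotype_blocks`: `start_index`,
#'   `end_index` (1-based, inclusive), `start_snp`, `end_snp`, `n_snps`,
#'   `start_pos`, `end_pos`, `span_bp`; SNP id lists in attribute
#'   `snp_ids`.
#' @export
haplotype_blocks <- function(geno, snps = NULL, strong_low = 0.70,
                             strong_high = 0.98, recomb_high = 0.90,
                             inform_frac = 0.95) {
  if (inherits(geno, "phased_genotypes")) {
    snps <- geno$snps
    lt <- ld_table(geno, ci = TRUE)
  } else {
    lt <- geno
    if (is.null(snps)) stop("snps panel required with an ld_table input")
  }
  m <- nrow(snps)
  idx <- stats::setNames(seq_len(m), snps$snp_id)
  SL <- SR <- matrix(FALSE, m, m)
  i <- idx[lt$snp1]; j <- idx[lt$snp2]
  strong <- !is.na(lt$ci_low) & lt$ci_low >= strong_low &
    lt$ci_high >= strong_high
  recomb <- !is.na(lt$ci_high) & lt$ci_high < recomb_high
  SL[cbind(i, j)] <- strong; SL[cbind(j, i)] <- strong
  SR[cbind(i, j)] <- recomb; SR[cbind(j, i)] <- recomb

  cand <- list()
  for (a in seq_len(m - 1)) for (b in seq((a + 1), m)) {
    if (!SL[a, b]) next
    sub <- a:b
    nsl <- sum(SL[sub, sub]) / 2
    nsr <- sum(SR[sub, sub]) / 2
    ninf <- nsl + nsr
    if (ninf > 0 && nsl / ninf >= inform_frac)
      cand[[length(cand) + 1L]] <- c(a, b)
  }
  blocks <- data.frame(start_index = integer(), end_index = integer())
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    len <- cand[, 2] - cand[, 1] + 1
    bp <- snps$pos[cand[, 2]] - snps$pos[cand[, 1]]
    ord <- order(-len, -bp, cand[, 1])
    cand <- cand[ord, , drop = FALSE]
    taken <- rep(FALSE, m)
    keep <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      sub <- cand[k, 1]:cand[k, 2]
      if (!any(taken[sub])) { keep[k] <- TRUE; taken[sub] <- TRUE }
    }
    cand <- cand[keep, , drop = FALSE]
    cand <- cand[order(cand[, 1]), , drop = FALSE]
    blocks <- data.frame(start_index = cand[, 1], end_index = cand[, 2])
  }
  blocks$start_snp <- snps$snp_id[blocks$start_index]
  blocks$end_snp <- snps$snp_id[blocks$end_index]
  blocks$n_snps <- blocks$end_index - blocks$start_index + 1L
  blocks$start_pos <- snps$pos[blocks$start_index]
  blocks$end_pos <- snps$pos[blocks$end_index]
  blocks$span_bp <- blocks$end_pos - blocks$start_pos
  attr(blocks, "snp_ids") <- lapply(seq_len(nrow(blocks)), function(k)
    snps$snp_id[blocks$start_index[k]:blocks$end_index[k]])
  class(blocks) <- c("haplotype_blocks", "data.frame")
  blocks
}

#' Greedy pairwise tag-SNP selection
#'
#' SNPs passing the MAF filter are covered when some tag exceeds the r2
#' threshold with them (a tag covers itself). Tags are picked iteratively as
#' the SNP covering the most uncovered SNPs, ties broken by lower panel
#' index; force-included SNPs are seeded first.
#'
#' @param geno a `phased_genotypes` cohort.
#' @param r2_threshold coverage requires `r2 > r2_threshold` (strict).
#' @param maf_min minimum minor allele frequency to enter tagging.
#' @param force_include SNP ids always kept as tags.
#' @return character vector of tag SNP ids, in selection order.
#' @export
tag_snps <- function(geno, r2_threshold = 0.8, maf_min = 0.05,
                     force_include = NULL) {
  ids <- geno$snps$snp_id
  f <- maf(geno)
  eligible <- which(!is.na(f) & f >= maf_min)
  if (!length(eligible)) stop("no SNP passes the MAF filter")
  m <- length(eligible)
  R <- diag(1, m)
  if (m > 1) for (a in 1:(m - 1)) for (b in (a + 1):m) {
    r2 <- ld_stats(hap_pair_counts(geno, eligible[a], eligible[b]))$r2
    R[a, b] <- R[b, a] <- if (is.na(r2)) 0 else r2
  }
  covers <- R > r2_threshold
  diag(covers) <- TRUE
  covered <- rep(FALSE, m)
  tags <- integer()
  for (fi in force_include) {
    k <- match(match(fi, ids), eligible)
    if (is.na(k)) next
    tags <- c(tags, k); covered <- covered | covers[k, ]
  }
  while (!all(covered)) {
    gain <- colSums(covers[!covered, , drop = FALSE])
    gain[tags] <- -1
    k <- which.max(gain)                 # which.max takes the first tie
    tags <- c(tags, k)
    covered <- covered | covers[k, ]
  }
  ids[eligible[tags]]
}
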
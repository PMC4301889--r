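#' Phased genotype container
#'
#' Stores ordered haplotype pairs for n individuals typed at m biallelic SNPs.
#' Alleles are coded 0 (ref) and 1 (alt); haplotype order (h1, h2) is the
#' phase truth and is preserved by all I/O. Missing genotypes are NA in both
#' haplotype slots.
#'
#' @param h1,h2 integer matrices (individuals x SNPs) of 0/1/NA; columns
#'   named by SNP id.
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`; rows in panel order matching the matrix columns.
#' @param ids character vector of individual ids (defaults to `ind_<row>`).
#' @return An object of class `phased_genotypes`.
#' @export
phased_genotypes <- function(h1, h2, snps, ids = NULL) {
  h1 <- as.matrix(h1); h2 <- as.matrix(h2)
  storage.mode(h1) <- "integer"; storage.mode(h2) <- "integer"
  if (!identical(dim(h1), dim(h2)))
    stop("h1 and h2 must have identical dimensions")
  if (ncol(h1) != nrow(snps))
    stop("panel size mismatch: ", ncol(h1), " columns vs ", nrow(snps), " SNPs")
  if (is.unsorted(snps$pos, strictly = TRUE))
    stop("SNP positions must be strictly increasing")
  ok <- c(h1, h2) %in% c(0L, 1L, NA)
  if (!all(ok)) stop("haplotype alleles must be 0, 1 or NA")
  if (is.null(ids)) ids <- paste0("ind_", seq_len(nrow(h1)))
  colnames(h1) <- colnames(h2) <- snps$snp_id
  rownames(h1) <- rownames(h2) <- ids
  structure(list(h1 = h1, h2 = h2, snps = as.data.frame(snps), ids = ids),
            class = "phased_genotypes")
}

#' @export
print.phased_genotypes <- function(x, ...) {
  cat("Phased genotypes:", length(x$ids), "individuals x",
      nrow(x$snps), "SNPs\n")
  cat("Region:", x$snps$chrom[1], paste0(min(x$snps$pos), "-", max(x$snps$pos)),
      "\n")
  invisible(x)
}

#' @export
dim.phased_genotypes <- function(x) c(length(x$ids), nrow(x$snps))

#' Alt-allele dosage matrix (0/1/2)
#' @param geno a `phased_genotypes` object
#' @return integer matrix individuals x SNPs
#' @export
dosage <- function(geno) geno$h1 + geno$h2

#' Alt-allele frequency per SNP
#' @param geno a `phased_genotypes` object
#' @return named numeric vector
#' @export
allele_freq <- function(geno) {
  (colMeans(geno$h1, na.rm = TRUE) + colMeans(geno$h2, na.rm = TRUE)) / 2
}

#' Minor allele frequency per SNP
#' @param geno a `phased_genotypes` object
#' @return named numeric vector
#' @export
maf <- function(geno) pmin(allele_freq(geno), 1 - allele_freq(geno))

#' Population specification: SNP panel plus haplotype pool
#'
#' A population is a pool of haplotypes with sampling probabilities over a
#' fixed SNP panel. Cohorts are simulated by drawing two pool haplotypes per
#' individual, so the pool's gametic structure fixes the population's LD.
#'
#' @param name cohort label.
#' @param snps panel data.frame (`snp_id`, `chrom`, `pos`, `ref`, `alt`).
#' @param haps matrix (pool haplotypes x SNPs) of 0/1.
#' @param freqs sampling probability per pool haplotype; must sum to 1
#'   within 1e-9.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(name, snps, haps, freqs) {
  haps <- as.matrix(haps); storage.mode(haps) <- "integer"
  if (nrow(haps) == 0L) stop("invalid population spec: empty haplotype pool")
  if (length(freqs) != nrow(haps))
    stop("one frequency per pool haplotype required")
  if (any(freqs < 0) || sum(freqs) <= 0)
    stop("invalid population spec: frequencies must be non-negative and sum > 0")
  if (abs(sum(freqs) - 1) > 1e-9)
    stop("haplotype frequencies must sum to 1 (tolerance 1e-9)")
  if (ncol(haps) != nrow(snps))
    stop("pool haplotype length must equal panel size")
  if (is.unsorted(snps$pos, strictly = TRUE))
    stop("SNP positions must be strictly increasing")
  if (!all(haps %in% c(0L, 1L))) stop("pool haplotypes must be 0/1")
  colnames(haps) <- snps$snp_id
  structure(list(name = name, snps = as.data.frame(snps), haps = haps,
                 freqs = as.numeric(freqs)),
            class = "population_spec")
}

#' @export
print.population_spec <- function(x, ...) {
  cat("Population", shQuote(x$name), "-", nrow(x$haps), "pool haplotypes,",
      nrow(x$snps), "SNPs\n")
  invisible(x)
}

read_pool_file <- function(pool_file, panel) {
  pool <- utils::read.delim(pool_file, check.names = FALSE)
  freqs <- pool$freq
  haps <- as.matrix(pool[, panel$snp_id, drop = FALSE])
  list(haps = haps, freqs = freqs)
}

#' Default 65-SNP panel
#'
#' The panel spans ~300 kb of chromosome 16q22.3 at roughly 4.8 kb spacing,
#' with a tighter cluster around the transcript-A marker. Three SNPs carry
#' their field names: `rs10852515` (transcribed, specific to isoform A),
#' `rs740178` (transcribed in both isoforms) and `rs8060701` (intronic).
#'
#' @return data.frame with columns `snp_id`, `chrom`, `pos`, `ref`, `alt`.
#' @export
default_panel <- function() {
  utils::read.delim(system.file("extdata", "panel_snps.tsv", package = "aeqtl"))
}

#' Built-in long-LD population (NE-like)
#'
#' A pool of 100 haplotypes built from few, long ancestry segments, giving
#' extended LD and long haplotype blocks, as typical of a north-European
#' cohort.
#' @return a `population_spec`
#' @export
pop_ne_like <- function() {
  panel <- default_panel()
  p <- read_pool_file(system.file("extdata", "pool_ne.tsv", package = "aeqtl"),
                      panel)
  population_spec("NE", panel, p$haps, p$freqs)
}

#' Built-in short-LD population (SA-like)
#'
#' A pool of 100 haplotypes with many short ancestry segments (a refinement
#' of the NE-like segment boundaries), giving rapidly decaying LD as typical
#' of an admixed African cohort. Used as the second cohort for trans-ethnic
#' fine-mapping.
#' @return a `population_spec`
#' @export
pop_sa_like <- function() {
  panel <- default_panel()
  p <- read_pool_file(system.file("extdata", "pool_sa.tsv", package = "aeqtl"),
                      panel)
  population_spec("SA", panel, p$haps, p$freqs)
}

#' Draw a phased cohort from a haplotype pool
#'
#' Each individual receives two haplotypes drawn independently from the pool
#' with the pool's frequencies; the draw order is recorded as the phase.
#'
#' @param pop a `population_spec`.
#' @param n number of individuals.
#' @param seed optional integer; if given, `set.seed(seed)` is called first
#'   so the draw is bit-reproducible.
#' @return a `phased_genotypes` object (n x panel size).
#' @export
simulate_haplotypes <- function(pop, n, seed = NULL) {
  stopifnot(inherits(pop, "population_spec"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(pop$haps)
  i1 <- sample.int(k, n, replace = TRUE, prob = pop$freqs)
  i2 <- sample.int(k, n, replace = TRUE, prob = pop$freqs)
  phased_genotypes(pop$haps[i1, , drop = FALSE], pop$haps[i2, , drop = FALSE],
                   pop$snps)
}
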
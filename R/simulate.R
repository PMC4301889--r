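#' Cis-regulatory architecture
#'
#' A set of cis-acting effects, each attached to a panel SNP. `beta` is the
#' natural-log allelic fold change: a haplotype carrying the alt allele of
#' the causal SNP expresses `exp(beta)`-fold more (or less, if negative)
#' transcript than one carrying the ref allele. `target` selects which
#' transcript pool the effect acts on: `"A"` affects only the isoform-A
#' assay; `"both"` affects both isoforms and hence also total expression.
#'
#' @param snp_id causal SNP ids.
#' @param target `"A"` or `"both"`, recycled.
#' @param beta natural-log fold change per alt allele, recycled.
#' @return data.frame of class `cis_architecture`.
#' @export
cis_architecture <- function(snp_id = character(), target = character(),
                             beta = numeric()) {
  eff <- data.frame(snp_id = as.character(snp_id),
                    target = as.character(target),
                    beta = as.numeric(beta))
  if (nrow(eff) && !all(eff$target %in% c("A", "both")))
    stop("effect target must be \"A\" or \"both\"")
  if (nrow(eff) && !all(is.finite(eff$beta))) stop("beta must be finite")
  class(eff) <- c("cis_architecture", "data.frame")
  eff
}

#' Simulation configuration
#'
#' Noise magnitudes and assay layout for the expression simulator. All
#' standard deviations are on the natural-log scale. Defaults are calibrated
#' so that total expression spans up to roughly an order of magnitude across
#' individuals and the cis share of its variance is a few percent.
#'
#' @param markers named character vector: names are marker SNP ids, values
#'   their transcript tag (`"A"` or `"both"`).
#' @param sigma_trans sd of the shared per-individual (trans) log factor.
#' @param sigma_allele sd of the per-haplotype residual cis log noise.
#' @param sigma_aer_meas sd of AER measurement noise (log scale).
#' @param n_plates number of PCR plates for total expression.
#' @param sigma_plate sd of per-plate log offsets.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(markers = c(rs10852515 = "A", rs740178 = "both"),
                       sigma_trans = 0.6, sigma_allele = 0.08,
                       sigma_aer_meas = 0.10, n_plates = 8,
                       sigma_plate = 0.15) {
  sds <- c(sigma_trans, sigma_allele, sigma_aer_meas, sigma_plate)
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  if (n_plates < 1) stop("n_plates must be >= 1")
  if (length(markers) && !all(markers %in% c("A", "both")))
    stop("marker tags must be \"A\" or \"both\"")
  structure(list(markers = markers, sigma_trans = sigma_trans,
                 sigma_allele = sigma_allele, sigma_aer_meas = sigma_aer_meas,
                 n_plates = as.integer(n_plates), sigma_plate = sigma_plate),
            class = "sim_config")
}

# Per-haplotype cis log-level for one assay tag; `haps` is an n x m 0/1
# matrix. Tag "A" sees target-A and target-both effects; tag "both" and the
# total-expression pool see target-both effects only.
cis_log_level <- function(haps, arch, tag, snp_ids) {
  keep <- if (tag == "A") arch$target %in% c("A", "both")
          else arch$target == "both"
  eff <- arch[keep, , drop = FALSE]
  out <- numeric(nrow(haps))
  for (k in seq_len(nrow(eff))) {
    j <- match(eff$snp_id[k], snp_ids)
    a <- haps[, j]
    a[is.na(a)] <- 0L
    out <- out + eff$beta[k] * a
  }
  out
}

#' Simulate total expression and allelic expression ratios
#'
#' Generative model: each haplotype h of individual i expresses
#' `e_h = exp(t_i + c(h) + eta_h)` where `t_i ~ N(0, sigma_trans^2)` is the
#' shared trans factor, `c(h)` the summed cis effects carried by the
#' haplotype, and `eta_h ~ N(0, sigma_allele^2)` residual cis noise. Total
#' expression is `(e_h1 + e_h2) * exp(plate offset)`. For individuals
#' heterozygous at a transcribed marker, the observed log allelic expression
#' ratio is the log level of the marker-alt-carrying haplotype minus that of
#' the marker-ref-carrying haplotype, plus `N(0, sigma_aer_meas^2)`
#' measurement noise; the trans factor cancels exactly. Marker homozygotes
#' contribute no AER row.
#'
#' @param geno a `phased_genotypes` cohort.
#' @param arch a `cis_architecture`.
#' @param cfg a `sim_config`.
#' @param seed optional integer seed.
#' @return list with `expression` (data.frame `individual_id`, `value`,
#'   `plate`; linear scale), `aer` (named list per marker of data.frames
#'   `individual_id`, `marker_snp_id`, `log_aer`), and `truth` (per-assay
#'   per-haplotype cis log-levels, for parameter-recovery tests).
#' @export
simulate_expression <- function(geno, arch, cfg, seed = NULL) {
  stopifnot(inherits(geno, "phased_genotypes"),
            inherits(arch, "cis_architecture"), inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  snp_ids <- geno$snps$snp_id
  miss <- setdiff(c(arch$snp_id, names(cfg$markers)), snp_ids)
  if (length(miss)) stop("SNPs absent from panel: ", paste(miss, collapse = ", "))
  n <- length(geno$ids)

  t_i <- stats::rnorm(n, 0, cfg$sigma_trans)
  eta1 <- stats::rnorm(n, 0, cfg$sigma_allele)
  eta2 <- stats::rnorm(n, 0, cfg$sigma_allele)
  plate <- sample.int(cfg$n_plates, n, replace = TRUE)
  plate_off <- stats::rnorm(cfg$n_plates, 0, cfg$sigma_plate)

  c_both1 <- cis_log_level(geno$h1, arch, "both", snp_ids)
  c_both2 <- cis_log_level(geno$h2, arch, "both", snp_ids)
  c_a1 <- cis_log_level(geno$h1, arch, "A", snp_ids)
  c_a2 <- cis_log_level(geno$h2, arch, "A", snp_ids)

  total <- (exp(t_i + c_both1 + eta1) + exp(t_i + c_both2 + eta2)) *
    exp(plate_off[plate])
  expression <- data.frame(individual_id = geno$ids, value = total,
                           plate = paste0("plate_", plate))

  aer <- list()
  for (m in names(cfg$markers)) {
    tag <- cfg$markers[[m]]
    j <- match(m, snp_ids)
    a1 <- geno$h1[, j]; a2 <- geno$h2[, j]
    het <- which(!is.na(a1) & !is.na(a2) & a1 + a2 == 1L)
    if (!length(het)) {
      warning("marker ", m, " has no heterozygotes; empty AER table")
      aer[[m]] <- data.frame(individual_id = character(),
                             marker_snp_id = character(), log_aer = numeric())
      next
    }
    u1 <- (if (tag == "A") c_a1 else c_both1) + eta1
    u2 <- (if (tag == "A") c_a2 else c_both2) + eta2
    # orient to the marker alt allele: alt-carrying minus ref-carrying
    lr <- ifelse(a1[het] == 1L, u1[het] - u2[het], u2[het] - u1[het])
    lr <- lr + stats::rnorm(length(het), 0, cfg$sigma_aer_meas)
    aer[[m]] <- data.frame(individual_id = geno$ids[het], marker_snp_id = m,
                           log_aer = lr)
  }

  truth <- list(arch = arch, cfg = cfg,
                cis_log_h1 = data.frame(both = c_both1, A = c_a1 + c_both1),
                cis_log_h2 = data.frame(both = c_both2, A = c_a2 + c_both2))
  list(expression = expression, aer = aer, truth = truth)
}

#' Simulate a complete cohort (genotypes + expression)
#'
#' @param pop a `population_spec`.
#' @param arch a `cis_architecture`.
#' @param cfg a `sim_config`.
#' @param n cohort size.
#' @param seed optional integer seed covering both draws.
#' @return list with `geno` plus the `simulate_expression` components.
#' @export
simulate_cohort <- function(pop, arch, cfg, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  geno <- simulate_haplotypes(pop, n)
  c(list(geno = geno), simulate_expression(geno, arch, cfg))
}

#' True cis share of total log-expression variance
#'
#' Under the generative model (small effects), the per-haplotype cis
#' log-variance is `s2c = sigma_allele^2 + Var_pool(c_both(h))` and its
#' contribution to Var(log total) is `s2c / 2`, so the true proportion is
#' `(s2c/2) / (sigma_trans^2 + s2c/2)` (plate variance excluded, matching
#' the plate-adjusted estimator).
#'
#' @param pop a `population_spec` (supplies pool haplotype frequencies).
#' @param arch a `cis_architecture`.
#' @param cfg a `sim_config`.
#' @return list with `var_allele` (s2c), `var_total`, `proportion`.
#' @export
cis_truth <- function(pop, arch, cfg) {
  cb <- cis_log_level(pop$haps, arch, "both", pop$snps$snp_id)
  w <- pop$freqs / sum(pop$freqs)
  var_geno <- sum(w * cb^2) - sum(w * cb)^2
  s2c <- cfg$sigma_allele^2 + var_geno
  var_total <- cfg$sigma_trans^2 + s2c / 2
  list(var_allele = s2c, var_total = var_total,
       proportion = (s2c / 2) / var_total)
}

#' Solve sigma_allele for a target cis-variance proportion
#'
#' Returns the per-haplotype residual cis sd such that, with no genotypic
#' cis effects on total expression beyond `var_cis_geno`, the true cis share
#' of Var(log total) equals `target`.
#'
#' @param target desired cis proportion in (0, 1).
#' @param sigma_trans trans sd (default matches `sim_config`).
#' @param var_cis_geno pool variance of genotypic cis log-levels on the
#'   total-expression pool (0 for a null architecture).
#' @return sigma_allele (numeric).
#' @export
calibrate_sigma_allele <- function(target, sigma_trans = 0.6,
                                   var_cis_geno = 0) {
  stopifnot(target > 0, target < 1)
  s2c <- 2 * target * sigma_trans^2 / (1 - target)
  v <- s2c - var_cis_geno
  if (v < 0) stop("target proportion unreachable: genotypic cis variance ",
                  "already exceeds it")
  sqrt(v)
}
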
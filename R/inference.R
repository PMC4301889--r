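#' Holm step-down family-wise error correction
#'
#' Sorts the p-values ascending, multiplies the i-th smallest by
#' `m - i + 1`, enforces monotonicity, caps at 1, and maps back to the
#' input order. With `m` equal to the number of p-values this is the
#' classical Holm procedure (delegated to [stats::p.adjust()]); `m` may be
#' larger when some of the family's tests produced no p-value (untestable
#' SNPs) but must still be counted.
#'
#' @param p raw p-values, all in (0, 1].
#' @param m family size (default `length(p)`).
#' @return corrected p-values in input order.
#' @export
holm_correct <- function(p, m = length(p)) {
  if (!length(p)) return(numeric())
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  if (m < length(p)) stop("family size m cannot be smaller than length(p)")
  if (m == length(p)) return(stats::p.adjust(p, method = "holm"))
  ord <- order(p)
  adj <- pmin(1, (m - seq_along(p) + 1) * p[ord])
  adj <- cummax(adj)
  out <- numeric(length(p))
  out[ord] <- adj
  out
}

#' Fisher's method for combining independent p-values
#'
#' `chi2 = -2 * sum(log(p))` referred to a chi-square upper tail with
#' `2K` degrees of freedom, K the number of cohorts combined.
#'
#' @param p per-cohort p-values for one test, all in (0, 1].
#' @return list of class `meta_result`: `chi2`, `df`, `p_combined`.
#' @export
fisher_combine <- function(p) {
  if (!length(p)) stop("no p-values to combine")
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  chi2 <- -2 * sum(log(p))
  df <- 2L * length(p)
  structure(list(chi2 = chi2, df = df,
                 p_combined = stats::pchisq(chi2, df, lower.tail = FALSE)),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Fisher combination: chi2 = %.3f on %d df, p = %.3g\n",
              x$chi2, x$df, x$p_combined))
  invisible(x)
}

#' Cross-cohort meta-analysis of association scans
#'
#' Combines per-SNP raw p-values across cohorts by Fisher's method, then
#' applies Holm's correction over the family of SNPs. Effect directions are
#' compared across cohorts; discordant-direction SNPs are flagged, not
#' dropped.
#'
#' @param scans named list of `qtl_scan` objects over the same panel.
#' @param n_tests Holm family size (default: SNPs with a combined p).
#' @return data.frame of class `meta_scan`: `snp_id`, `pos`, one `p_<cohort>`
#'   column per cohort, `chi2`, `df`, `p_combined`, `p_holm`,
#'   `direction_consistent`.
#' @export
meta_analyse <- function(scans, n_tests = NULL) {
  stopifnot(length(scans) >= 1, !is.null(names(scans)))
  base <- scans[[1]][, c("snp_id", "pos")]
  pmat <- sapply(scans, function(s) s$p_raw[match(base$snp_id, s$snp_id)])
  bmat <- sapply(scans, function(s) s$beta[match(base$snp_id, s$snp_id)])
  pmat <- matrix(pmat, nrow = nrow(base)); bmat <- matrix(bmat, nrow = nrow(base))
  out <- base
  for (k in seq_along(scans)) out[[paste0("p_", names(scans)[k])]] <- pmat[, k]
  comb <- apply(pmat, 1, function(pp) {
    pp <- pp[!is.na(pp)]
    if (!length(pp)) return(c(NA_real_, NA_real_, NA_real_))
    f <- fisher_combine(pp)
    c(f$chi2, f$df, f$p_combined)
  })
  out$chi2 <- comb[1, ]; out$df <- comb[2, ]; out$p_combined <- comb[3, ]
  out$direction_consistent <- apply(bmat, 1, function(bb) {
    bb <- bb[!is.na(bb) & bb != 0]
    if (length(bb) < 2) return(NA)
    all(sign(bb) == sign(bb[1]))
  })
  tested <- which(!is.na(out$p_combined))
  m <- if (is.null(n_tests)) length(tested) else n_tests
  out$p_holm <- NA_real_
  if (length(tested))
    out$p_holm[tested] <- holm_correct(out$p_combined[tested], m = m)
  structure(out, class = c("meta_scan", "data.frame"), n_tests = m)
}

#' Cis share of expression variance from AER dispersion
#'
#' The AER of a marker heterozygote contrasts two haplotypes of the same
#' individual, so trans influences cancel and
#' `Var(log AER) = 2 * s2c + sigma_aer_meas^2` with `s2c` the per-haplotype
#' cis log-variance. The estimator inverts this:
#' `s2c_hat = (Var(log AER) - sigma_aer_meas^2) / 2`. Under the
#' small-effect log-additive model the cis contribution to the variance of
#' log total expression is `s2c / 2` (the two haplotype deviations
#' average), so the cis proportion is `(s2c_hat / 2) / Var(log total)`,
#' with the total-expression variance taken after plate adjustment.
#'
#' A negative `s2c_hat` (measurement noise exceeding the observed AER
#' dispersion) is flagged and reported alongside a clamped-at-zero copy.
#'
#' @param aer AER data.frame for one marker (`log_aer` column).
#' @param expression expression data.frame (`value`, `plate`).
#' @param sigma_aer_meas known/assumed sd of AER measurement noise (log
#'   scale). If `aer` carries a `replicate` column, set
#'   `sigma_aer_meas = NULL` to estimate it from within-individual
#'   replicate scatter.
#' @return list of class `cis_variance`: `var_allele` (raw s2c_hat),
#'   `var_allele_clamped`, `var_total`, `proportion`,
#'   `proportion_clamped`, `flagged`, `sigma_aer_meas`, `n_aer`, `n_expr`.
#' @export
cis_variance <- function(aer, expression, sigma_aer_meas) {
  if (nrow(aer) < 10L) stop("at least 10 AER observations required")
  if (nrow(expression) < 10L) stop("at least 10 expression observations required")
  if (is.null(sigma_aer_meas)) {
    if (!"replicate" %in% names(aer))
      stop("sigma_aer_meas = NULL requires a replicate column in aer")
    # pooled within-individual replicate variance
    sp <- stats::aggregate(log_aer ~ individual_id, aer,
                           function(v) c(var = stats::var(v), n = length(v)))
    v <- sp$log_aer[, "var"]; nn <- sp$log_aer[, "n"]
    ok <- nn > 1
    if (!any(ok)) stop("no replicated individuals to estimate sigma_aer_meas")
    sigma_aer_meas <- sqrt(sum(v[ok] * (nn[ok] - 1)) / sum(nn[ok] - 1))
    la <- stats::aggregate(log_aer ~ individual_id, aer, mean)$log_aer
    v_aer <- stats::var(la) - sigma_aer_meas^2 / mean(nn)
  } else {
    v_aer <- stats::var(aer$log_aer) - sigma_aer_meas^2
  }
  y <- log(expression$value)
  if (length(unique(expression$plate)) > 1L) {
    fit <- stats::lm(y ~ factor(plate), data = expression)
    v_tot <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
  } else {
    v_tot <- stats::var(y)
  }
  s2c <- v_aer / 2
  flagged <- s2c < 0
  s2c_cl <- max(s2c, 0)
  structure(list(var_allele = s2c, var_allele_clamped = s2c_cl,
                 var_total = v_tot, proportion = (s2c / 2) / v_tot,
                 proportion_clamped = (s2c_cl / 2) / v_tot,
                 flagged = flagged, sigma_aer_meas = sigma_aer_meas,
                 n_aer = nrow(aer), n_expr = nrow(expression)),
            class = "cis_variance")
}

#' @export
print.cis_variance <- function(x, ...) {
  cat(sprintf("Cis variance: %.1f%% of log total-expression variance",
              100 * x$proportion_clamped))
  if (x$flagged) cat(" (raw estimate negative, clamped)")
  cat(sprintf("\n  per-haplotype cis variance %.4g, total log variance %.4g",
              x$var_allele, x$var_total))
  cat(sprintf("\n  n(AER) = %d, n(expression) = %d\n", x$n_aer, x$n_expr))
  invisible(x)
}

#' Trans-ethnic fine-mapping comparison
#'
#' For each cohort scan, collects the SNPs with Holm-corrected p below
#' `alpha`, their count and genomic span, the per-cohort lead SNP (minimum
#' raw p among testable SNPs), and the cross-cohort intersection of
#' significant sets. A cohort with shorter-range LD localizes the signal to
#' a narrower span; the shared causal variant should sit in the
#' intersection.
#'
#' @param scans named list of `qtl_scan` objects over a shared panel.
#' @param alpha family-wise significance threshold on `p_holm`.
#' @return list of class `fine_map`: `per_cohort` data.frame (`cohort`,
#'   `n_significant`, `span_bp`, `lead`), `significant` (named list of SNP
#'   id vectors), `intersection`, `alpha`.
#' @export
fine_map <- function(scans, alpha = 0.05) {
  stopifnot(length(scans) >= 1, !is.null(names(scans)))
  sig <- lapply(scans, function(s)
    s$snp_id[s$testable & !is.na(s$p_holm) & s$p_holm < alpha])
  per <- do.call(rbind, lapply(names(scans), function(nm) {
    s <- scans[[nm]]
    ids <- sig[[nm]]
    pos <- s$pos[match(ids, s$snp_id)]
    lead <- if (any(s$testable))
      s$snp_id[which.min(s$p_raw)] else NA_character_
    data.frame(cohort = nm, n_significant = length(ids),
               span_bp = if (length(ids) >= 2) max(pos) - min(pos) else 0,
               lead = lead)
  }))
  structure(list(per_cohort = per, significant = sig,
                 intersection = Reduce(intersect, sig), alpha = alpha),
            class = "fine_map")
}

#' @export
print.fine_map <- function(x, ...) {
  cat("Fine-mapping comparison (family-wise alpha =", x$alpha, ")\n")
  print(x$per_cohort, row.names = FALSE)
  cat("Intersection:",
      if (length(x$intersection)) paste(x$intersection, collapse = ", ")
      else "(empty)", "\n")
  invisible(x)
}

#' Association strength versus LD with the lead SNP
#'
#' Regresses -log10(raw p) of the testable SNPs on their r2 with a lead
#' SNP. A positive slope indicates that association strength tracks LD with
#' the lead, as expected when the lead is (or tags) the causal variant.
#'
#' @param scan a `qtl_scan`.
#' @param r2 named numeric vector of r2 with the lead SNP (e.g. from
#'   [r2_with()]).
#' @return list of class `signal_ld`: `slope`, `correlation`, `p`, `n`,
#'   `flagged` (TRUE when r2 has zero variance; statistics then NA).
#' @export
signal_vs_ld <- function(scan, r2) {
  ok <- scan$testable & !is.na(scan$p_raw)
  ids <- scan$snp_id[ok]
  r2v <- r2[ids]
  keep <- !is.na(r2v)
  ids <- ids[keep]; r2v <- as.numeric(r2v[keep])
  y <- -log10(scan$p_raw[match(ids, scan$snp_id)])
  if (length(y) < 3L) stop("at least 3 testable SNPs required")
  if (stats::var(r2v) == 0)
    return(structure(list(slope = NA_real_, correlation = NA_real_,
                          p = NA_real_, n = length(y), flagged = TRUE),
                     class = "signal_ld"))
  fit <- stats::lm(y ~ r2v)
  sm <- summary(fit)$coefficients
  structure(list(slope = sm["r2v", "Estimate"],
                 correlation = stats::cor(r2v, y),
                 p = sm["r2v", "Pr(>|t|)"], n = length(y), flagged = FALSE),
            class = "signal_ld")
}

#' @export
print.signal_ld <- function(x, ...) {
  if (x$flagged) cat("signal vs LD: undefined (zero variance in r2)\n")
  else cat(sprintf(
    "signal vs LD: slope %.3f, r = %.3f, p = %.3g over %d SNPs\n",
    x$slope, x$correlation, x$p, x$n))
  invisible(x)
}
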
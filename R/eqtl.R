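#' Total-expression eQTL scan
#'
#' Ordinary least squares of log expression on the additive alt-allele
#' dosage (0/1/2, no dominance), with PCR plate as a categorical covariate;
#' two-sided t-test on the dosage coefficient and Holm correction over the
#' scan. With a single plate the plate term is dropped (noted by message).
#'
#' @param expression data.frame (`individual_id`, `value` on the linear
#'   scale, `plate`).
#' @param geno a `phased_genotypes` cohort covering those individuals.
#' @param snps SNP ids to test (default: the whole panel).
#' @param n_tests Holm correction size (default: tests with a p-value).
#' @return a `qtl_scan` data.frame (see [aeqtl_scan()]); `fold_minor` is
#'   the per-minor-allele-dose fold change. Monomorphic SNPs are flagged
#'   untestable.
#' @export
eqtl_scan <- function(expression, geno, snps = NULL, n_tests = NULL) {
  stopifnot(inherits(geno, "phased_genotypes"))
  if (any(expression$value <= 0)) stop("expression values must be positive")
  if (is.null(snps)) snps <- geno$snps$snp_id
  rows <- match(expression$individual_id, geno$ids)
  if (anyNA(rows)) stop("expression table contains unknown individual ids")
  n_plates <- length(unique(expression$plate))
  if (nrow(expression) < n_plates + 2L)
    stop("need at least n_plates + 2 observations")
  if (n_plates == 1L)
    message("single plate: plate covariate dropped")
  y <- log(expression$value)
  covar <- if (n_plates > 1L) {
    mm <- stats::model.matrix(~ factor(plate), data = expression)
    mm[, -1, drop = FALSE]               # plate indicators, no intercept col
  } else NULL
  dos <- dosage(geno)[rows, , drop = FALSE]
  af <- allele_freq(geno)

  out <- do.call(rbind, lapply(snps, function(s) {
    g <- as.numeric(dos[, s])
    ok <- !is.na(g)
    mono <- length(unique(g[ok])) <= 1L
    if (mono) {
      r <- list(beta = NA_real_, se = NA_real_, p = NA_real_, n = sum(ok),
                n_informative = 0L, testable = FALSE,
                reason = "monomorphic SNP")
    } else {
      r <- ols_assoc_dosage(y, g, covar)
    }
    data.frame(snp_id = s, pos = geno$snps$pos[match(s, geno$snps$snp_id)],
               beta = r$beta, se = r$se,
               fold_minor = fold_minor_allele(r$beta, af[[s]]),
               n = r$n, n_informative = r$n_informative, p_raw = r$p,
               p_holm = NA_real_, testable = r$testable, reason = r$reason)
  }))
  tested <- which(!is.na(out$p_raw))
  m <- if (is.null(n_tests)) length(tested) else n_tests
  if (length(tested))
    out$p_holm[tested] <- holm_correct(out$p_raw[tested], m = m)
  structure(out, class = c("qtl_scan", "data.frame"), type = "eQTL",
            marker = NULL, covariates = character(), n_tests = m)
}

# dosage OLS with intercept (+ plate columns); dosage always varies here
ols_assoc_dosage <- function(y, g, covar = NULL) {
  keep <- !is.na(g) & !is.na(y)
  y <- y[keep]; g <- g[keep]
  X <- cbind(`(Intercept)` = 1, x = g)
  if (!is.null(covar)) X <- cbind(X, covar[keep, , drop = FALSE])
  n <- length(y)
  df <- n - qr(X)$rank
  if (qr(X)$rank < ncol(X) || df < 1L)
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_, n = n,
                n_informative = sum(g != 0), testable = FALSE,
                reason = "deficient design"))
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  XtXinv <- solve(crossprod(X))
  se <- sqrt(rss / df * XtXinv["x", "x"])
  beta <- fit$coefficients[["x"]]
  p <- if (se == 0) { if (beta != 0) .Machine$double.xmin else 1 } else
    max(2 * stats::pt(abs(beta / se), df, lower.tail = FALSE),
        .Machine$double.xmin)
  list(beta = beta, se = se, p = p, n = n,
       n_informative = sum(g != 0), testable = TRUE, reason = "")
}

#' Plate-adjusted fold range of expression
#'
#' Maximum over minimum expression after removing plate effects: log values
#' are residualized on plate (when more than one plate is present) and the
#' residual range re-exponentiated. With one plate this is simply
#' max(value)/min(value).
#'
#' @param expression data.frame (`individual_id`, `value`, `plate`).
#' @return numeric fold range (>= 1).
#' @export
fold_range <- function(expression) {
  if (!nrow(expression)) stop("empty expression table")
  if (nrow(expression) < 2L) return(1)
  if (any(expression$value <= 0)) stop("expression values must be positive")
  y <- log(expression$value)
  if (length(unique(expression$plate)) > 1L)
    y <- stats::residuals(stats::lm(y ~ factor(plate), data = expression))
  exp(diff(range(y)))
}
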
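#' Phase-based design code for aeQTL regression
#'
#' For an individual heterozygous at the transcribed marker, the design
#' value for a candidate SNP is the candidate alt-allele count on the
#' haplotype carrying the marker alt allele minus that on the haplotype
#' carrying the marker ref allele: +1 when the candidate alt travels with
#' the marker alt, -1 when it travels with the marker ref, 0 when the
#' candidate is homozygous. The candidate's cis effect then enters the log
#' AER with coefficient equal to this code.
#'
#' @param geno a `phased_genotypes` cohort.
#' @param marker marker SNP id; every scored individual must be
#'   heterozygous at it.
#' @param candidate candidate SNP id.
#' @param individuals ids to score (default: all marker heterozygotes).
#' @return named integer vector in -1/0/+1 (NA where the candidate genotype
#'   is missing).
#' @export
phase_design_code <- function(geno, marker, candidate, individuals = NULL) {
  ids <- geno$snps$snp_id
  jm <- match(marker, ids); jc <- match(candidate, ids)
  if (is.na(jm)) stop("marker not in panel: ", marker)
  if (is.na(jc)) stop("candidate not in panel: ", candidate)
  rows <- if (is.null(individuals)) seq_along(geno$ids)
          else match(individuals, geno$ids)
  if (anyNA(rows)) stop("unknown individual id")
  m1 <- geno$h1[rows, jm]; m2 <- geno$h2[rows, jm]
  if (is.null(individuals)) {
    het <- !is.na(m1) & !is.na(m2) & m1 + m2 == 1L
    rows <- rows[het]; m1 <- m1[het]
  } else if (any(is.na(m1) | is.na(m2) | m1 + m2 != 1L)) {
    stop("individual not heterozygous at marker ", marker)
  }
  c1 <- geno$h1[rows, jc]; c2 <- geno$h2[rows, jc]
  x <- ifelse(m1 == 1L, c1 - c2, c2 - c1)
  stats::setNames(as.integer(x), geno$ids[rows])
}

# orient beta to the cohort minor allele of a SNP and exponentiate
fold_minor_allele <- function(beta, alt_freq) {
  if (is.na(alt_freq)) return(NA_real_)
  exp(if (alt_freq <= 0.5) beta else -beta)
}

# one OLS test of y on x (+ optional covariate columns). A constant
# covariate column (e.g. conditioning on the marker itself, phase code +1
# everywhere) carries only a mean shift and is absorbed by the intercept.
# A constant nonzero x (the marker self-test) replaces the intercept; it is
# only untestable when the conditioning SNP was itself marker-equivalent.
ols_assoc <- function(y, x, covar = NULL) {
  keep <- !is.na(x) & !is.na(y)
  if (!is.null(covar)) keep <- keep & stats::complete.cases(covar)
  y <- y[keep]; x <- x[keep]
  n_dropped <- sum(!keep)
  dropped_const_covar <- FALSE
  if (!is.null(covar)) {
    covar <- covar[keep, , drop = FALSE]
    keep_cols <- apply(covar, 2, function(v) stats::var(v) > 0)
    dropped_const_covar <- any(!keep_cols)
    covar <- covar[, keep_cols, drop = FALSE]
    if (!ncol(covar)) covar <- NULL
  }
  n <- length(y)
  res <- list(beta = NA_real_, se = NA_real_, p = NA_real_, n = n,
              n_informative = sum(x != 0), testable = FALSE, reason = "",
              n_dropped = n_dropped)
  if (n < 3L || all(x == 0)) {
    res$reason <- if (n < 3L) "fewer than 3 observations" else
      "all design codes zero"
    return(res)
  }
  const_x <- stats::var(x) == 0
  if (const_x && dropped_const_covar) {
    # the conditioning SNP was itself marker-equivalent (constant code):
    # a constant-code candidate is indistinguishable from it
    res$reason <- "collinear design (candidate in perfect LD with covariate)"
    return(res)
  }
  # a constant nonzero design (marker self-test) takes the intercept's seat
  X <- if (const_x) cbind(x = x) else cbind(`(Intercept)` = 1, x = x)
  if (!is.null(covar)) X <- cbind(X, covar)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    res$reason <- "collinear design (candidate in perfect LD with covariate)"
    return(res)
  }
  fit <- stats::lm.fit(X, y)
  df <- n - ncol(X)
  if (df < 1L) { res$reason <- "no residual degrees of freedom"; return(res) }
  rss <- sum(fit$residuals^2)
  XtXinv <- solve(crossprod(X))
  k <- match("x", colnames(X))
  se <- sqrt(rss / df * XtXinv[k, k])
  beta <- fit$coefficients[["x"]]
  res$beta <- beta; res$se <- se
  if (se == 0) {
    # exactly-deterministic data (simulations with all noise switched off)
    res$p <- if (beta != 0) .Machine$double.xmin else 1
  } else {
    # floor at the smallest representable double: pt underflows for
    # extreme t, and downstream corrections require p > 0
    res$p <- max(2 * stats::pt(abs(beta / se), df, lower.tail = FALSE),
                 .Machine$double.xmin)
  }
  res$testable <- TRUE
  res
}

#' Phase-aware allelic-expression QTL scan
#'
#' Regresses the log allelic expression ratio at one transcribed marker on
#' the phase design code of each candidate SNP (ordinary least squares,
#' two-sided t-test on the candidate coefficient). The per-individual trans
#' factor cancels in the AER, so the scan is specific for cis effects.
#' Conditioning SNPs enter as additional phase-coded covariates.
#' Family-wise error is controlled by Holm's step-down correction over the
#' scan.
#'
#' @param aer AER data.frame (`individual_id`, `marker_snp_id`, `log_aer`)
#'   for a single marker.
#' @param geno a `phased_genotypes` cohort covering those individuals.
#' @param candidates candidate SNP ids (default: the whole panel).
#' @param covariates SNP ids to condition on (phase-coded covariates).
#' @param n_tests number of tests for the Holm correction (default: number
#'   of candidates with a computed p-value).
#' @return data.frame of class `qtl_scan` with columns `snp_id`, `pos`,
#'   `beta`, `se`, `fold_minor`, `n`, `n_informative`, `p_raw`, `p_holm`,
#'   `testable`, `reason`. `fold_minor` is `exp(beta)` oriented to the
#'   cohort minor allele. Untestable SNPs carry NA statistics and a reason,
#'   never p = 1.
#' @export
aeqtl_scan <- function(aer, geno, candidates = NULL, covariates = character(),
                       n_tests = NULL) {
  stopifnot(inherits(geno, "phased_genotypes"))
  marker <- unique(aer$marker_snp_id)
  if (length(marker) != 1L)
    stop("aer table must contain exactly one marker (got ",
         length(marker), ")")
  if (nrow(aer) < 3L) stop("at least 3 AER observations required")
  if (is.null(candidates)) candidates <- geno$snps$snp_id
  candidates <- setdiff(candidates, covariates)
  af <- allele_freq(geno)

  covx <- NULL
  if (length(covariates)) {
    covx <- vapply(covariates, function(s)
      as.numeric(phase_design_code(geno, marker, s, aer$individual_id)),
      numeric(nrow(aer)))
    covx <- matrix(covx, nrow = nrow(aer),
                   dimnames = list(NULL, covariates))
  }

  rows <- lapply(candidates, function(s) {
    x <- phase_design_code(geno, marker, s, aer$individual_id)
    r <- ols_assoc(aer$log_aer, as.numeric(x), covx)
    if (r$n_dropped > 0)
      message(r$n_dropped, " observation(s) dropped for ", s,
              " (missing genotype)")
    data.frame(snp_id = s, pos = geno$snps$pos[match(s, geno$snps$snp_id)],
               beta = r$beta, se = r$se,
               fold_minor = fold_minor_allele(r$beta, af[[s]]),
               n = r$n, n_informative = r$n_informative, p_raw = r$p,
               p_holm = NA_real_, testable = r$testable, reason = r$reason)
  })
  out <- do.call(rbind, rows)
  tested <- which(!is.na(out$p_raw))
  m <- if (is.null(n_tests)) length(tested) else n_tests
  if (length(tested))
    out$p_holm[tested] <- holm_correct(out$p_raw[tested], m = m)
  structure(out, class = c("qtl_scan", "data.frame"), type = "aeQTL",
            marker = marker, covariates = covariates, n_tests = m)
}

#' Conditional aeQTL scan
#'
#' Re-runs the scan with a lead SNP as a phase-coded covariate; the lead
#' itself is excluded from the results. Used to ask whether any association
#' remains after accounting for the lead (secondary-signal search).
#'
#' @inheritParams aeqtl_scan
#' @param lead SNP id to condition on.
#' @return a `qtl_scan` (see [aeqtl_scan()]).
#' @export
conditional_scan <- function(aer, geno, lead, candidates = NULL,
                             n_tests = NULL) {
  if (is.null(candidates)) candidates <- geno$snps$snp_id
  aeqtl_scan(aer, geno, setdiff(candidates, lead), covariates = lead,
             n_tests = n_tests)
}

#' @export
print.qtl_scan <- function(x, top = 10L, ...) {
  cat(attr(x, "type"), "scan:", sum(x$testable), "of", nrow(x), "SNPs",
      "testable")
  if (!is.null(attr(x, "marker"))) cat(", marker", attr(x, "marker"))
  if (length(attr(x, "covariates")))
    cat(", conditioned on", paste(attr(x, "covariates"), collapse = ", "))
  cat("\n")
  ord <- order(x$p_raw)
  show <- utils::head(ord[!is.na(x$p_raw[ord])], top)
  df <- as.data.frame(x)[show, c("snp_id", "pos", "beta", "fold_minor",
                                 "n", "p_raw", "p_holm")]
  df$p_raw <- signif(df$p_raw, 3); df$p_holm <- signif(df$p_holm, 3)
  df$beta <- round(df$beta, 4); df$fold_minor <- round(df$fold_minor, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.qtl_scan <- function(object, alpha = 0.05, ...) {
  sig <- object$testable & !is.na(object$p_holm) & object$p_holm < alpha
  lead <- if (any(object$testable))
    object$snp_id[which.min(object$p_raw)] else NA_character_
  structure(list(type = attr(object, "type"), n_snps = nrow(object),
                 n_testable = sum(object$testable), n_significant = sum(sig),
                 significant = object$snp_id[sig], lead = lead,
                 span_bp = if (sum(sig) >= 2)
                   diff(range(object$pos[sig])) else 0,
                 alpha = alpha),
            class = "summary.qtl_scan")
}

#' @export
print.summary.qtl_scan <- function(x, ...) {
  cat(x$type, "scan:", x$n_significant, "of", x$n_testable,
      "testable SNPs significant at family-wise alpha =", x$alpha, "\n")
  if (x$n_significant)
    cat("  significant:", paste(x$significant, collapse = ", "),
        sprintf("(span %d bp)\n", x$span_bp))
  cat("  lead SNP:", x$lead, "\n")
  invisible(x)
}
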
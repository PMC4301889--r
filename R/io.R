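#' Read phased genotypes from a VCF file
#'
#' Accepts VCF 4.x with biallelic SNP records and a GT field. Phased
#' entries (`a|b`) preserve haplotype order; unphased entries (`a/b`) are
#' accepted only when homozygous (phase irrelevant) and otherwise abort
#' with an error naming the record. Multi-allelic records are skipped with
#' a warning; missing GT becomes NA.
#'
#' @param path VCF file path (uncompressed text).
#' @return a `phased_genotypes` object.
#' @export
read_phased_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("not a VCF: missing #CHROM header in ", path)
  cols <- strsplit(lines[hdr[1]], "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10) stop("VCF has no sample columns")
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr[1])]
  body <- body[!startsWith(body, "#")]
  recs <- strsplit(body, "\t", fixed = TRUE)

  keep <- vapply(recs, function(f) {
    multi <- grepl(",", f[5], fixed = TRUE)
    if (multi) warning("skipping multi-allelic record at ", f[1], ":", f[2])
    !multi
  }, logical(1))
  recs <- recs[keep]
  if (!length(recs)) stop("no biallelic records in ", path)

  n <- length(samples); m <- length(recs)
  h1 <- h2 <- matrix(NA_integer_, n, m)
  snps <- data.frame(snp_id = character(m), chrom = character(m),
                     pos = integer(m), ref = character(m), alt = character(m))
  for (k in seq_len(m)) {
    f <- recs[[k]]
    snps$chrom[k] <- f[1]; snps$pos[k] <- as.integer(f[2])
    snps$snp_id[k] <- if (f[3] == ".") paste0(f[1], ":", f[2]) else f[3]
    snps$ref[k] <- f[4]; snps$alt[k] <- f[5]
    gt <- sub(":.*$", "", f[-(1:9)])
    phased <- grepl("|", gt, fixed = TRUE)
    al <- strsplit(gt, "[|/]")
    a1 <- suppressWarnings(as.integer(vapply(al, `[`, "", 1)))
    a2 <- suppressWarnings(as.integer(vapply(al, function(v)
      if (length(v) >= 2) v[2] else NA_character_, "")))
    bad <- !phased & !is.na(a1) & !is.na(a2) & a1 != a2
    if (any(bad))
      stop("unphased heterozygote at ", f[1], ":", f[2], " (", snps$snp_id[k],
           "), sample ", samples[which(bad)[1]])
    h1[, k] <- a1; h2[, k] <- a2
  }
  ord <- order(snps$pos)
  phased_genotypes(h1[, ord, drop = FALSE], h2[, ord, drop = FALSE],
                   snps[ord, ], ids = samples)
}

#' Write phased genotypes as VCF 4.2
#'
#' GT entries use the `|` separator; haplotype order is preserved, so a
#' write/read round trip reproduces the object exactly.
#'
#' @param geno a `phased_genotypes` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(geno, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", geno$ids), collapse = "\t")), con)
  for (k in seq_len(nrow(geno$snps))) {
    a1 <- geno$h1[, k]; a2 <- geno$h2[, k]
    gt <- ifelse(is.na(a1) | is.na(a2), ".|.", paste0(a1, "|", a2))
    s <- geno$snps[k, ]
    writeLines(paste(c(s$chrom, s$pos, s$snp_id, s$ref, s$alt, ".", "PASS",
                       ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) utils::read.delim(path, check.names = FALSE)

#' Write a simulated cohort to disk
#'
#' Emits a phased VCF, one TSV per AER marker
#' (`individual_id`, `marker_snp_id`, `log_aer`), an expression TSV
#' (`individual_id`, `value`, `plate`), and a `truth.json` recording the
#' architecture (betas and their fold changes) and the analytic cis
#' variance proportion, for parameter-recovery tests.
#'
#' @param geno a `phased_genotypes` cohort.
#' @param sim result of [simulate_expression()] for that cohort.
#' @param out_dir output directory (created if absent).
#' @param pop the `population_spec` used (for the truth cis proportion);
#'   optional.
#' @return named character vector of file paths.
#' @export
write_fixtures <- function(geno, sim, out_dir, pop = NULL) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  paths <- c(genotypes = file.path(out_dir, "genotypes.vcf"),
             expression = file.path(out_dir, "expression.tsv"),
             truth = file.path(out_dir, "truth.json"))
  write_phased_vcf(geno, paths[["genotypes"]])
  write_tsv(sim$expression, paths[["expression"]])
  for (m in names(sim$aer)) {
    p <- file.path(out_dir, paste0("aer_", m, ".tsv"))
    write_tsv(sim$aer[[m]], p)
    paths[[paste0("aer_", m)]] <- p
  }
  arch <- sim$truth$arch
  truth <- list(effects = data.frame(snp_id = arch$snp_id,
                                     target = arch$target, beta = arch$beta,
                                     fold = exp(arch$beta)),
                sigma = sim$truth$cfg[c("sigma_trans", "sigma_allele",
                                        "sigma_aer_meas", "sigma_plate")])
  if (!is.null(pop))
    truth$cis_proportion <- cis_truth(pop, arch, sim$truth$cfg)$proportion
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  paths
}

#' Export haplotype blocks as BED (0-based half-open)
#' @param blocks a `haplotype_blocks` data.frame.
#' @param chrom chromosome label.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_blocks_bed <- function(blocks, chrom, path) {
  bed <- data.frame(chrom = chrom, start = blocks$start_pos - 1L,
                    end = blocks$end_pos,
                    name = paste0("block_", seq_len(nrow(blocks))))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' End-to-end two-cohort analysis pipeline
#'
#' Simulates (or loads) two cohorts, then runs, per cohort: the
#' total-expression eQTL scan, per-marker aeQTL scans, conditional scans on
#' the configured lead SNPs, LD table and haplotype blocks; then the
#' Fisher/Holm meta-analysis, cis-variance estimation, fine-mapping
#' comparison and the signal-versus-LD regression. All outputs are written
#' under `out_dir` with a plain-text run log; all randomness flows from the
#' single `seed`.
#'
#' @param config list (or path to a YAML file mirroring it; note YAML 1.1
#'   reads a bare `n` key as a boolean, so quote it as `'n'`) with elements:
#'   `cohorts` — named list, each either `list(pop, n)` for simulation
#'   (`pop` a `population_spec` or `"ne_like"`/`"sa_like"`) or
#'   `list(vcf, expression, aer)` file paths; `arch` a `cis_architecture`
#'   (or data.frame coercible to one) used when simulating; `cfg` a
#'   `sim_config`; `leads` SNP ids for conditional scans (default: the
#'   per-marker lead found by the scan); `alpha` (default 0.05); `n_tests`
#'   Holm family size override; `out_dir`; `seed`; optionally `truth`, the
#'   path to a `truth.json` from [write_fixtures()], which adds a
#'   `recovery.json` comparing estimated to true fold changes.
#' @return list of class `aeqtl_pipeline` with all result objects,
#'   invisibly; side effect: TSV/JSON/BED artifacts and `run.log` in
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  cfg <- config$cfg %||% sim_config()
  if (!inherits(cfg, "sim_config")) cfg <- do.call(sim_config, cfg)
  arch <- config$arch %||% cis_architecture()
  if (!inherits(arch, "cis_architecture"))
    arch <- cis_architecture(arch$snp_id, arch$target, arch$beta)
  alpha <- config$alpha %||% 0.05
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- config$seed %||% 1L
  set.seed(seed)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...,
                            "\n", sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("aeqtl ", as.character(utils::packageVersion("aeqtl")),
       " | seed ", seed)

  stage <- "load-cohorts"
  result <- try({
    cohorts <- lapply(names(config$cohorts), function(nm) {
      cc <- config$cohorts[[nm]]
      if (!is.null(cc$vcf)) {
        geno <- read_phased_vcf(cc$vcf)
        aer <- lapply(cc$aer, read_tsv)
        names(aer) <- vapply(aer, function(a) a$marker_snp_id[1], "")
        list(geno = geno, expression = read_tsv(cc$expression), aer = aer)
      } else {
        pop <- cc$pop
        if (identical(pop, "ne_like")) pop <- pop_ne_like()
        if (identical(pop, "sa_like")) pop <- pop_sa_like()
        simulate_cohort(pop, arch, cfg, cc$n)
      }
    })
    names(cohorts) <- names(config$cohorts)
    logf("cohorts: ", paste(names(cohorts), collapse = ", "))

    stage <- "per-cohort-scans"
    per <- lapply(names(cohorts), function(nm) {
      ch <- cohorts[[nm]]
      eq <- eqtl_scan(ch$expression, ch$geno, n_tests = config$n_tests)
      write_tsv(as.data.frame(eq), file.path(out_dir,
                                             paste0("eqtl_", nm, ".tsv")))
      ae <- lapply(names(ch$aer), function(mk) {
        sc <- aeqtl_scan(ch$aer[[mk]], ch$geno, n_tests = config$n_tests)
        write_tsv(as.data.frame(sc),
                  file.path(out_dir, paste0("aeqtl_", nm, "_", mk, ".tsv")))
        lead <- config$leads[[mk]] %||% summary(sc)$lead
        cond <- conditional_scan(ch$aer[[mk]], ch$geno, lead,
                                 n_tests = config$n_tests)
        write_tsv(as.data.frame(cond),
                  file.path(out_dir,
                            paste0("aeqtl_cond_", nm, "_", mk, ".tsv")))
        list(scan = sc, conditional = cond, lead = lead)
      })
      names(ae) <- names(ch$aer)
      lt <- ld_table(ch$geno)
      write_tsv(as.data.frame(lt), file.path(out_dir,
                                             paste0("ld_", nm, ".tsv")))
      bl <- haplotype_blocks(lt, ch$geno$snps)
      write_blocks_bed(bl, ch$geno$snps$chrom[1],
                       file.path(out_dir, paste0("blocks_", nm, ".bed")))
      logf("cohort ", nm, ": n = ", length(ch$geno$ids), ", AER rows = ",
           paste(vapply(ch$aer, nrow, 1L), collapse = "/"))
      list(eqtl = eq, aeqtl = ae, ld = lt, blocks = bl)
    })
    names(per) <- names(cohorts)

    stage <- "meta-analysis"
    markers <- Reduce(intersect, lapply(cohorts, function(ch) names(ch$aer)))
    meta <- lapply(markers, function(mk) {
      scans <- lapply(per, function(p) p$aeqtl[[mk]]$scan)
      ms <- meta_analyse(scans, n_tests = config$n_tests)
      write_tsv(as.data.frame(ms), file.path(out_dir,
                                             paste0("meta_", mk, ".tsv")))
      ms
    })
    names(meta) <- markers

    stage <- "cis-variance"
    cv <- lapply(names(cohorts), function(nm) {
      ch <- cohorts[[nm]]
      if (!length(ch$aer) || nrow(ch$aer[[1]]) < 10) return(NULL)
      cis_variance(ch$aer[[1]], ch$expression, cfg$sigma_aer_meas)
    })
    names(cv) <- names(cohorts)

    stage <- "fine-mapping"
    fm <- lapply(markers, function(mk) {
      scans <- lapply(per, function(p) p$aeqtl[[mk]]$scan)
      f <- fine_map(scans, alpha = alpha)
      for (nm in names(scans)) {
        ids <- f$significant[[nm]]
        if (length(ids)) {
          pos <- scans[[nm]]$pos[match(ids, scans[[nm]]$snp_id)]
          bed <- data.frame(chrom = cohorts[[nm]]$geno$snps$chrom[1],
                            start = min(pos) - 1L, end = max(pos),
                            name = paste0("aeqtl_", mk, "_", nm))
          utils::write.table(bed,
            file.path(out_dir, paste0("region_", mk, "_", nm, ".bed")),
            sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
        }
      }
      f
    })
    names(fm) <- markers

    stage <- "signal-vs-ld"
    svl <- lapply(markers, function(mk) {
      lapply(names(per), function(nm) {
        sc <- per[[nm]]$aeqtl[[mk]]$scan
        lead <- per[[nm]]$aeqtl[[mk]]$lead
        if (is.na(lead)) return(NULL)
        signal_vs_ld(sc, r2_with(cohorts[[nm]]$geno, lead))
      }) |> stats::setNames(names(per))
    })
    names(svl) <- markers

    stage <- "truth-recovery"
    if (!is.null(config$truth)) {
      tr <- jsonlite::read_json(config$truth, simplifyVector = TRUE)
      rec <- do.call(rbind, lapply(seq_len(nrow(tr$effects)), function(k) {
        sid <- tr$effects$snp_id[k]
        est <- vapply(names(per), function(nm) {
          bb <- vapply(per[[nm]]$aeqtl, function(a)
            a$scan$beta[match(sid, a$scan$snp_id)], numeric(1))
          bb <- bb[!is.na(bb)]
          if (length(bb)) exp(bb[which.max(abs(bb))]) else NA_real_
        }, numeric(1))
        data.frame(snp_id = sid, true_fold = tr$effects$fold[k],
                   cohort = names(per), estimated_fold = est)
      }))
      jsonlite::write_json(rec, file.path(out_dir, "recovery.json"),
                           auto_unbox = TRUE, digits = NA,
                           dataframe = "rows")
    }

    report <- list(fine_map = lapply(fm, function(f)
      list(per_cohort = f$per_cohort, intersection = f$intersection)),
      cis_variance = lapply(cv, function(v)
        if (is.null(v)) NULL else unclass(v)))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         force = TRUE)
    logf("done")
    list(cohorts = cohorts, scans = per, meta = meta, cis_variance = cv,
         fine_map = fm, signal_vs_ld = svl, seed = seed, out_dir = out_dir)
  }, silent = TRUE)
  if (inherits(result, "try-error")) {
    logf("FAILED at stage ", stage, ": ",
         conditionMessage(attr(result, "condition")))
    stop("pipeline failed at stage ", stage, ": ",
         conditionMessage(attr(result, "condition")))
  }
  invisible(structure(result, class = "aeqtl_pipeline"))
}

#' @export
print.aeqtl_pipeline <- function(x, ...) {
  cat("aeqtl pipeline run (seed ", x$seed, ") -> ", x$out_dir, "\n", sep = "")
  for (mk in names(x$fine_map)) {
    cat("\nMarker ", mk, ":\n", sep = "")
    print(x$fine_map[[mk]])
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
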
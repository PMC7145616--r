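# Study- and variant-level quality control for GWAS summary statistics.

#' Genomic inflation factor (lambda)
#'
#' The median-based genomic-control estimator: the median of the 1-df
#' chi-square quantiles of the association P-values divided by the median of
#' the chi-square(1) distribution (0.4549364...). Lambda near 1 indicates a
#' well-calibrated study; values well above 1 indicate inflation, e.g. from
#' stratification or from P-value lists truncated at a significance cutoff.
#'
#' @param pvalues numeric vector of P-values in (0, 1].
#' @return the inflation factor, a positive real.
#' @export
genomic_inflation <- function(pvalues) {
  if (!length(pvalues)) stop("need at least one P-value")
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("P-values must lie in (0, 1]")
  chisq <- stats::qchisq(pvalues, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Quality-control configuration
#'
#' Defaults follow the pipeline's published rules: a study must report more
#' than 100,000 variants and have inflation factor at most 1.5; variants
#' with missing rsIDs, minor allele frequency at or below 0.05, on sex
#' chromosomes, or inside the MHC region on chromosome 6 are removed.
#'
#' @param min_variants minimum variant count, exclusive lower bound is
#'   \code{min_variants - 1} (default 100001, i.e. the study needs
#'   > 100000 variants).
#' @param lambda_max maximum allowed inflation factor (default 1.5,
#'   strict: lambda exactly 1.5 passes).
#' @param maf_min_exclusive variants with MAF <= this are removed
#'   (default 0.05).
#' @param mhc_chrom,mhc_start,mhc_end MHC interval (GRCh37 default
#'   chr6:25,000,000-35,000,000).
#' @param autosomes_only drop sex-chromosome and mitochondrial variants
#'   (default TRUE).
#' @param lambda_after_maf compute lambda after (TRUE) or before (FALSE,
#'   default) the MAF filter; the rsID filter always precedes lambda.
#' @param european_ancestry study-level ancestry flag, supplied as metadata;
#'   non-European studies fail QC.
#' @return a list of class \code{qc_config}.
#' @export
qc_config <- function(min_variants = 100001L, lambda_max = 1.5,
                      maf_min_exclusive = 0.05, mhc_chrom = "6",
                      mhc_start = 25e6, mhc_end = 35e6,
                      autosomes_only = TRUE, lambda_after_maf = FALSE,
                      european_ancestry = TRUE) {
  structure(list(min_variants = min_variants, lambda_max = lambda_max,
                 maf_min_exclusive = maf_min_exclusive,
                 mhc_chrom = normalize_chrom(mhc_chrom),
                 mhc_start = mhc_start, mhc_end = mhc_end,
                 autosomes_only = autosomes_only,
                 lambda_after_maf = lambda_after_maf,
                 european_ancestry = european_ancestry),
            class = "qc_config")
}

#' Apply study- and variant-level QC to summary statistics
#'
#' Variant-level filters are applied in order: missing rsID, duplicated
#' rsID (first kept), MAF <= threshold, sex chromosomes, MHC region.
#' Study-level checks (variant count, inflation factor, ancestry flag) are
#' evaluated on the set remaining after the missing-rsID filter; failures
#' are reported, never raised.
#'
#' @param ss a \code{summary_stats} object.
#' @param cfg a [qc_config()].
#' @return list with \code{ss} (the filtered \code{summary_stats}) and
#'   \code{report}, a \code{qc_report} carrying counts in/out, lambda,
#'   per-filter removals, and pass/fail with reasons.
#' @export
apply_study_qc <- function(ss, cfg = qc_config()) {
  rec <- ss$records
  n_in <- nrow(rec)
  filters <- list()
  note <- function(name, removed)
    filters[[length(filters) + 1L]] <<- list(name = name,
                                             n_removed = as.integer(removed))

  miss_id <- is.na(rec$snp_id) | rec$snp_id == "" | rec$snp_id == "."
  note("missing_rsid", sum(miss_id))
  rec <- rec[!miss_id, , drop = FALSE]

  dup <- duplicated(rec$snp_id)
  note("duplicate_rsid", sum(dup))
  rec <- rec[!dup, , drop = FALSE]

  # study-level checks on the post-rsID set
  n_post_rsid <- nrow(rec)
  lambda_pre <- if (n_post_rsid > 0) genomic_inflation(rec$pvalue) else NA_real_

  low_maf <- !is.na(rec$maf) & rec$maf <= cfg$maf_min_exclusive
  note("low_maf", sum(low_maf))
  rec <- rec[!low_maf, , drop = FALSE]

  if (cfg$autosomes_only) {
    sex <- !is_autosome(rec$chrom)
    note("non_autosome", sum(sex))
    rec <- rec[!sex, , drop = FALSE]
  }

  mhc <- rec$chrom == cfg$mhc_chrom &
    rec$pos >= cfg$mhc_start & rec$pos <= cfg$mhc_end
  note("mhc_region", sum(mhc))
  rec <- rec[!mhc, , drop = FALSE]

  lambda_gc <- if (cfg$lambda_after_maf) {
    if (nrow(rec) > 0) genomic_inflation(rec$pvalue) else NA_real_
  } else lambda_pre

  fail <- character(0)
  if (n_post_rsid < cfg$min_variants)
    fail <- c(fail, sprintf("variant count %d not > %d", n_post_rsid,
                            cfg$min_variants - 1L))
  if (!is.na(lambda_gc) && lambda_gc > cfg$lambda_max)
    fail <- c(fail, sprintf("genomic inflation %.4f > %.2f", lambda_gc,
                            cfg$lambda_max))
  if (!isTRUE(cfg$european_ancestry))
    fail <- c(fail, "study not flagged European ancestry")

  report <- structure(list(study_id = ss$study_id,
                           n_variants_in = n_in,
                           n_variants_out = nrow(rec),
                           lambda_gc = lambda_gc,
                           filters_applied = filters,
                           passed = length(fail) == 0L,
                           fail_reasons = fail),
                      class = "qc_report")
  out <- ss
  out$records <- rec
  list(ss = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:", x$study_id, if (x$passed) "[PASSED]" else "[FAILED]", "\n")
  cat("  variants:", x$n_variants_in, "->", x$n_variants_out,
      " lambda:", format(x$lambda_gc, digits = 4), "\n")
  for (f in x$filters_applied)
    cat(sprintf("  - %-16s removed %d\n", f$name, f$n_removed))
  for (r in x$fail_reasons) cat("  ! ", r, "\n")
  invisible(x)
}
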
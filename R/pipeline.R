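# End-to-end study orchestration: QC -> gene scores -> TAG sets -> tissue
# enrichment -> GSEA validation, assembled into a machine-readable report.

#' Percentage formatter used in study reports
#'
#' @param n numerator count.
#' @param d denominator count (> 0).
#' @param digits decimals (default 1).
#' @return numeric percentage rounded to \code{digits} decimals.
#' @export
format_pct <- function(n, d, digits = 1) {
  if (d <= 0) stop("denominator must be positive")
  round(100 * n / d, digits)
}

#' Summation utility used in study reports
#'
#' Sums integer counts, refusing missing values; used wherever a report
#' total must reconcile with its parts.
#'
#' @param ... numeric count vectors.
#' @return the integer total.
#' @export
tally <- function(...) {
  x <- c(...)
  if (any(is.na(x))) stop("tally over missing counts")
  if (any(x < 0)) stop("tally over negative counts")
  as.integer(sum(x))
}

#' Study-level configuration
#'
#' Bundles the thresholds of every pipeline stage with the published
#' defaults.
#'
#' @param qc a [qc_config()].
#' @param gene_score a [gene_score_config()].
#' @param tag_thresholds TAG P-value thresholds.
#' @param tag_min_size,tag_max_size TAG qualification bounds.
#' @param fraction top tissue-specific fraction (default 0.05).
#' @param score_kind "auto", "t" or "z" (see [score_panel()]).
#' @param covariate_names covariates for t-scores.
#' @param n_top_tissues tissues taken to GSEA validation (default 3).
#' @param n_perm GSEA permutations (default 10000).
#' @param seed RNG seed for permutation runs.
#' @return list of class \code{study_config}.
#' @export
study_config <- function(qc = qc_config(),
                         gene_score = gene_score_config(),
                         tag_thresholds = c(0.05, 0.01, 1e-3, 1e-4, 1e-5),
                         tag_min_size = 20L, tag_max_size = 3000L,
                         fraction = 0.05,
                         score_kind = "auto",
                         covariate_names = character(0),
                         n_top_tissues = 3L, n_perm = 10000L, seed = 1L) {
  structure(list(qc = qc, gene_score = gene_score,
                 tag_thresholds = tag_thresholds,
                 tag_min_size = tag_min_size, tag_max_size = tag_max_size,
                 fraction = fraction, score_kind = score_kind,
                 covariate_names = covariate_names,
                 n_top_tissues = n_top_tissues, n_perm = n_perm,
                 seed = seed),
            class = "study_config")
}

#' Run a full study from in-memory objects
#'
#' Stages run in order: study/variant QC, gene scoring, TAG set
#' construction, per-panel tissue enrichment and GSEA validation of the top
#' tissues. A study failing QC, gene-count qualification or TAG
#' qualification yields a report with \code{passed = FALSE} and no
#' enrichment section.
#'
#' @param ss a \code{summary_stats} object.
#' @param genes a \code{gene_annotation}.
#' @param geno a \code{genotype_ref}.
#' @param panels list of \code{expression_panel} objects (at least one).
#' @param cfg a [study_config()].
#' @return object of class \code{study_report}.
#' @export
run_study_objects <- function(ss, genes, geno, panels, cfg = study_config()) {
  if (!length(panels)) stop("at least one expression panel is required")
  if (is.null(names(panels)))
    names(panels) <- vapply(panels, `[[`, "", "panel_id")
  qc <- withCallingHandlers(
    apply_study_qc(ss, cfg$qc),
    error = function(e) stop("[qc] ", conditionMessage(e), call. = FALSE))
  report <- list(schema_version = 1L,
                 study_id = ss$study_id,
                 qc = qc$report,
                 n_variants_removed = tally(vapply(qc$report$filters_applied,
                                                   `[[`, 0L, "n_removed")),
                 passed = qc$report$passed,
                 provenance = list(seed = cfg$seed,
                                   version = as.character(
                                     utils::packageVersion("tseakit"))))
  class(report) <- "study_report"
  if (!qc$report$passed) return(report)

  gs <- tryCatch(score_study(qc$ss, genes, geno, cfg$gene_score),
                 error = function(e) stop("[genescore] ",
                                          conditionMessage(e), call. = FALSE))
  report$n_genes_scored <- nrow(gs$table)
  report$n_genes_success <- gs$n_success
  if (!gs$qualified) {
    report$passed <- FALSE
    report$fail_stage <- "genescore"
    return(report)
  }
  tags <- make_tag_sets(gs, cfg$tag_thresholds, cfg$tag_min_size,
                        cfg$tag_max_size)
  report$tag_summary <- lapply(tags$sets, function(s)
    list(size = length(s$genes), qualified = s$qualified))
  if (tags$excluded) {
    report$passed <- FALSE
    report$fail_stage <- "tag"
    return(report)
  }
  report$gene_scores <- gs
  report$tsea <- lapply(names(panels), function(pid) {
    panel <- panels[[pid]]
    spec <- tryCatch(score_panel(panel, cfg$score_kind, cfg$covariate_names),
                     error = function(e) stop("[panel:", pid, "] ",
                                              conditionMessage(e),
                                              call. = FALSE))
    sets <- top_fraction_sets(spec, cfg$fraction)
    universe <- intersect(gs$table$gene_id[gs$table$status == "ok"],
                          rownames(spec$scores))
    res <- run_tsea(tags, sets, universe)
    top <- select_top_tissues(res, cfg$n_top_tissues)
    gsea <- lapply(top, function(tt) {
      # the TAG set with the smallest enrichment P for this tissue
      best_thr <- names(which.min(res$pvalues[tt, ]))
      tag_genes <- intersect(tags$sets[[best_thr]]$genes, universe)
      spec_col <- spec$scores[universe, tt]
      gsea_validate(spec_col, tag_genes, n_perm = cfg$n_perm,
                    seed = cfg$seed, tissue = tt, study_id = ss$study_id)
    })
    names(gsea) <- top
    list(panel_id = panel$panel_id, result = res, top_tissues = gsea)
  })
  names(report$tsea) <- names(panels)
  report
}

#' Run a full study from input files
#'
#' File-based wrapper around [run_study_objects()]; records input file
#' hashes in the report's provenance.
#'
#' @param gwas_path GWAS summary statistics TSV.
#' @param genes_path gene annotation (BED or GFF, by extension).
#' @param geno_path genotype reference (VCF or dosage TSV, by extension).
#' @param panel_paths list of \code{c(expr = ..., labels = ...)} path pairs.
#' @param cfg a [study_config()].
#' @param column_map column mapping for the GWAS file.
#' @return a \code{study_report}.
#' @export
run_study <- function(gwas_path, genes_path, geno_path, panel_paths,
                      cfg = study_config(),
                      column_map = default_column_map()) {
  ss <- read_summary_stats(gwas_path, column_map)
  fmt <- if (grepl("\\.bed$", genes_path, ignore.case = TRUE)) "bed" else "gff"
  genes <- read_gene_annotation(genes_path, fmt)
  geno <- read_genotype_ref(geno_path)
  panels <- lapply(panel_paths, function(pp)
    read_expression_panel(pp[["expr"]], pp[["labels"]]))
  report <- run_study_objects(ss, genes, geno, panels, cfg)
  inputs <- c(gwas_path, genes_path, geno_path,
              unlist(panel_paths, use.names = FALSE))
  report$provenance$input_md5 <- stats::setNames(
    unname(tools::md5sum(inputs)), basename(inputs))
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report:", x$study_id,
      if (isTRUE(x$passed)) "[PASSED]" else "[FAILED]", "\n")
  cat("  lambda:", format(x$qc$lambda_gc, digits = 4),
      " variants out:", x$qc$n_variants_out, "\n")
  if (!is.null(x$n_genes_success))
    cat("  genes scored:", x$n_genes_scored, " successful:",
        x$n_genes_success, "\n")
  if (!is.null(x$tsea)) for (panel in x$tsea) {
    cat("  panel", panel$panel_id, "- top tissues:",
        paste(names(panel$top_tissues), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize a study report to JSON
#'
#' @param report a \code{study_report}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_study_report <- function(report, path) {
  enc <- rapply(unclass(report), function(x) {
    if (is.matrix(x)) {
      list(rows = rownames(x), cols = colnames(x),
           values = apply(x, 1, as.list, simplify = FALSE))
    } else x
  }, how = "replace", classes = c("matrix", "numeric", "integer",
                                  "character", "logical"))
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE, na = "null")
  invisible(path)
}

#' Export Manhattan-plot coordinates
#'
#' Two tables of (chrom, pos, -log10 P), one per SNP and one per gene (gene
#' position = the midpoint of the gene body), restricted to autosomes and
#' sorted by chromosome and position.
#'
#' @param ss QC-passed \code{summary_stats}.
#' @param gs a \code{gene_score_table} (only status-ok genes exported).
#' @param genes the \code{gene_annotation} the scores were computed on.
#' @return list with data.frames \code{snp} and \code{gene}.
#' @export
export_manhattan_data <- function(ss, gs, genes) {
  rec <- ss$records[is_autosome(ss$records$chrom), , drop = FALSE]
  snp <- data.frame(chrom = rec$chrom, pos = rec$pos,
                    neg_log10_p = -log10(rec$pvalue),
                    stringsAsFactors = FALSE)
  snp <- snp[order(as.integer(snp$chrom), snp$pos), , drop = FALSE]
  rownames(snp) <- NULL
  ok <- gs$table[gs$table$status == "ok", , drop = FALSE]
  ann <- genes[match(ok$gene_id, genes$gene_id), , drop = FALSE]
  keep <- !is.na(ann$gene_id) & ann$autosomal
  gene <- data.frame(chrom = ann$chrom[keep],
                     pos = as.integer((ann$start[keep] + ann$end[keep]) / 2),
                     neg_log10_p = -log10(ok$pvalue[keep]),
                     stringsAsFactors = FALSE)
  gene <- gene[order(as.integer(gene$chrom), gene$pos), , drop = FALSE]
  rownames(gene) <- NULL
  list(snp = snp, gene = gene)
}
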
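# Tissue specificity scoring of an expression panel and derivation of
# top-fraction tissue-specific gene sets. Expression is log2(x + 1)
# transformed before scoring so heavy-tailed raw values do not dominate.

log_expr <- function(panel) log2(panel$expr + 1)

#' Per-gene, per-tissue specificity t-scores
#'
#' For each gene and tissue, a linear model of log2(x + 1) expression on a
#' tissue indicator (sample belongs to the tissue vs all other samples) plus
#' optional covariates is fitted; the score is the indicator coefficient
#' divided by its standard error, i.e. a one-vs-rest t-statistic. Suited to
#' panels with larger per-tissue sample sizes.
#'
#' @param panel an \code{expression_panel}.
#' @param covariate_names character vector of covariate columns to adjust
#'   for; must exist in \code{panel$covariates}.
#' @return object of class \code{specificity_matrix}: list with
#'   \code{panel_id}, \code{score_kind} ("t"), \code{scores} (gene x tissue
#'   matrix), \code{n_samples} (per tissue).
#' @export
tissue_t_scores <- function(panel, covariate_names = character(0)) {
  if (length(covariate_names)) {
    have <- colnames(panel$covariates)
    missing_cov <- setdiff(covariate_names, have)
    if (length(missing_cov))
      stop("covariate(s) not found: ", paste(missing_cov, collapse = ", "))
  }
  y <- t(log_expr(panel))                        # samples x genes
  tissues <- sort(unique(panel$sample_tissue))
  n_by_tissue <- table(panel$sample_tissue)
  if (any(n_by_tissue < 2))
    stop("t-scores need >= 2 samples per tissue; use tissue_z_scores()")
  cov_mat <- if (length(covariate_names)) {
    as.matrix(panel$covariates[, covariate_names, drop = FALSE])
  } else NULL
  scores <- sapply(tissues, function(tt) {
    ind <- as.numeric(panel$sample_tissue == tt)
    x <- cbind(intercept = 1, tissue = ind, cov_mat)
    fit <- stats::lm.fit(x, y)
    df <- nrow(x) - fit$rank
    rss <- colSums(fit$residuals^2)
    sigma2 <- rss / df
    xtx_inv <- chol2inv(chol(crossprod(x)))
    se <- sqrt(sigma2 * xtx_inv[2, 2])
    b <- fit$coefficients[2, ]
    tstat <- ifelse(se > 0, b / se, 0)
    tstat[!is.finite(tstat)] <- 0
    tstat
  })
  rownames(scores) <- rownames(panel$expr)
  # constant genes carry no specificity signal; without this guard,
  # floating-point residual noise turns 0/0 into spurious +-1 statistics
  const <- apply(y, 2, function(v)
    max(abs(v - mean(v))) <= 1e-12 * max(1, abs(mean(v))))
  scores[const, ] <- 0
  structure(list(panel_id = panel$panel_id, score_kind = "t",
                 scores = scores,
                 n_samples = stats::setNames(as.integer(n_by_tissue[tissues]),
                                             tissues)),
            class = "specificity_matrix")
}

#' Per-gene, per-tissue specificity z-scores
#'
#' For each gene, tissue means of log2(x + 1) expression are standardized
#' across tissues (population standard deviation); a gene with zero spread
#' across tissue means gets z = 0 everywhere. Suited to panels with few
#' samples per tissue.
#'
#' @param panel an \code{expression_panel} with at least two tissues.
#' @return a \code{specificity_matrix} with \code{score_kind} "z".
#' @export
tissue_z_scores <- function(panel) {
  tissues <- sort(unique(panel$sample_tissue))
  if (length(tissues) < 2)
    stop("z-scores need at least two tissues")
  le <- log_expr(panel)
  means <- sapply(tissues, function(tt)
    rowMeans(le[, panel$sample_tissue == tt, drop = FALSE]))
  mu <- rowMeans(means)
  sdev <- sqrt(rowMeans((means - mu)^2))   # population convention
  z <- (means - mu) / ifelse(sdev > 0, sdev, Inf)
  z[sdev == 0, ] <- 0
  rownames(z) <- rownames(panel$expr)
  structure(list(panel_id = panel$panel_id, score_kind = "z",
                 scores = z,
                 n_samples = stats::setNames(
                   as.integer(table(panel$sample_tissue)[tissues]), tissues)),
            class = "specificity_matrix")
}

#' Score an expression panel, choosing t- or z-scores
#'
#' With \code{kind = "auto"}, panels in which every tissue has at least 30
#' samples are scored with t-statistics, smaller panels with z-scores.
#'
#' @param panel an \code{expression_panel}.
#' @param kind "auto", "t" or "z".
#' @param covariate_names covariates for the t-score model.
#' @return a \code{specificity_matrix}.
#' @export
score_panel <- function(panel, kind = c("auto", "t", "z"),
                        covariate_names = character(0)) {
  kind <- match.arg(kind)
  if (kind == "auto") {
    kind <- if (min(table(panel$sample_tissue)) >= 30) "t" else "z"
  }
  if (kind == "t") tissue_t_scores(panel, covariate_names)
  else tissue_z_scores(panel)
}

#' @export
print.specificity_matrix <- function(x, ...) {
  cat("Specificity matrix (", x$score_kind, "-scores): ", x$panel_id, " - ",
      nrow(x$scores), " genes x ", ncol(x$scores), " tissues\n", sep = "")
  invisible(x)
}

#' Top-fraction tissue-specific gene sets
#'
#' For each tissue, the \code{floor(fraction * G)} highest-scoring genes are
#' declared tissue-specific (default top 5 percent). Ties at the cutoff are
#' broken by lexicographic gene ID so the sets are deterministic.
#'
#' @param spec a \code{specificity_matrix}.
#' @param fraction fraction of genes per tissue, in (0, 0.5].
#' @return object of class \code{tissue_specific_sets}: list with
#'   \code{panel_id}, \code{fraction}, \code{sets} (tissue -> character
#'   vector of gene IDs).
#' @export
top_fraction_sets <- function(spec, fraction = 0.05) {
  if (fraction <= 0 || fraction > 0.5)
    stop("fraction must lie in (0, 0.5]")
  g <- nrow(spec$scores)
  k <- floor(fraction * g)
  if (k < 1)
    stop("fraction ", fraction, " of ", g, " genes selects no gene")
  ids <- rownames(spec$scores)
  sets <- lapply(colnames(spec$scores), function(tt) {
    s <- spec$scores[, tt]
    ord <- order(-s, ids)
    sort(ids[ord[seq_len(k)]])
  })
  names(sets) <- colnames(spec$scores)
  structure(list(panel_id = spec$panel_id, fraction = fraction, sets = sets),
            class = "tissue_specific_sets")
}

#' Write specificity scores and tissue-specific sets to TSV
#'
#' @param spec a \code{specificity_matrix}.
#' @param sets optional \code{tissue_specific_sets}.
#' @param prefix output path prefix; writes \code{<prefix>_scores.tsv} and,
#'   when sets are given, \code{<prefix>_sets.tsv} (long format).
#' @return written paths, invisibly.
#' @export
write_panel_scores <- function(spec, sets = NULL, prefix) {
  score_path <- paste0(prefix, "_scores.tsv")
  utils::write.table(data.frame(gene_id = rownames(spec$scores),
                                spec$scores, check.names = FALSE),
                     score_path, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- score_path
  if (!is.null(sets)) {
    long <- do.call(rbind, lapply(names(sets$sets), function(tt)
      data.frame(tissue = tt, gene_id = sets$sets[[tt]],
                 stringsAsFactors = FALSE)))
    set_path <- paste0(prefix, "_sets.tsv")
    utils::write.table(long, set_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, set_path)
  }
  invisible(paths)
}
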